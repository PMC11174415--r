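# Peephole LSTM head. The cell follows the printed gate equations of the
# architecture: the input and forget gates read the previous cell state
# and the output gate reads the current cell state (peephole
# connections, implemented as per-unit diagonal weights).

#' Construct peephole LSTM parameters
#'
#' All weights zero unless supplied; shapes are validated against the
#' input size `D` and hidden size `H`.
#'
#' @param D input size per time step.
#' @param H hidden size.
#' @param init `"zero"` or `"glorot"` (uniform Glorot initialization;
#'   draws from the current RNG stream).
#' @return A list of class `lstm_params` with input weights `W_qi`,
#'   `W_qf`, `W_qc`, `W_qo` (D x H), recurrent weights `W_hi`, `W_hf`,
#'   `W_hc`, `W_ho` (H x H), diagonal peephole weights `w_ci`, `w_cf`,
#'   `w_co` (length H) and biases `b_i`, `b_f`, `b_c`, `b_o`.
#' @export
lstm_params <- function(D, H, init = "zero") {
  mk <- function(nr, nc) {
    if (init == "glorot") .glorot(nr, nc) else matrix(0, nr, nc)
  }
  structure(list(
    W_qi = mk(D, H), W_qf = mk(D, H), W_qc = mk(D, H), W_qo = mk(D, H),
    W_hi = mk(H, H), W_hf = mk(H, H), W_hc = mk(H, H), W_ho = mk(H, H),
    w_ci = numeric(H), w_cf = numeric(H), w_co = numeric(H),
    b_i = numeric(H), b_f = numeric(H), b_c = numeric(H), b_o = numeric(H)
  ), class = "lstm_params")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' One peephole LSTM step
#'
#' Gate equations (per unit, with elementwise products):
#' \deqn{i_t = \sigma(x_t W_{qi} + h_{t-1} W_{hi} + w_{ci} c_{t-1} + b_i)}
#' \deqn{f_t = \sigma(x_t W_{qf} + h_{t-1} W_{hf} + w_{cf} c_{t-1} + b_f)}
#' \deqn{c_t = f_t c_{t-1} + i_t \tanh(x_t W_{qc} + h_{t-1} W_{hc} + b_c)}
#' \deqn{o_t = \sigma(x_t W_{qo} + h_{t-1} W_{ho} + w_{co} c_t + b_o)}
#' \deqn{h_t = o_t \tanh(c_t)}
#'
#' @param x_t input, a length-D vector or batch x D matrix.
#' @param h_prev,c_prev previous hidden and cell state (vector or
#'   batch x H matrix).
#' @param params an [lstm_params()] list.
#' @param peephole set `FALSE` for a standard (non-peephole) cell; the
#'   peephole reference is the default.
#' @return List with elements `h` and `c` (same shape as `h_prev`).
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params, peephole = TRUE) {
  vec_in <- is.null(dim(x_t))
  if (vec_in) {
    x_t <- matrix(x_t, 1); h_prev <- matrix(h_prev, 1); c_prev <- matrix(c_prev, 1)
  }
  if (ncol(x_t) != nrow(params$W_qi))
    stop("input size ", ncol(x_t), " does not match W_qi rows ",
         nrow(params$W_qi))
  p <- if (peephole) 1 else 0
  i <- .sigmoid(x_t %*% params$W_qi + h_prev %*% params$W_hi +
                  p * sweep_cols(c_prev, params$w_ci) + rep_row(params$b_i, nrow(x_t)))
  f <- .sigmoid(x_t %*% params$W_qf + h_prev %*% params$W_hf +
                  p * sweep_cols(c_prev, params$w_cf) + rep_row(params$b_f, nrow(x_t)))
  g <- tanh(x_t %*% params$W_qc + h_prev %*% params$W_hc +
              rep_row(params$b_c, nrow(x_t)))
  c_t <- f * c_prev + i * g
  o <- .sigmoid(x_t %*% params$W_qo + h_prev %*% params$W_ho +
                  p * sweep_cols(c_t, params$w_co) + rep_row(params$b_o, nrow(x_t)))
  h_t <- o * tanh(c_t)
  if (vec_in) list(h = drop(h_t), c = drop(c_t))
  else list(h = h_t, c = c_t)
}

sweep_cols <- function(m, v) sweep(m, 2, v, `*`)
rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' Unroll an LSTM over a sequence
#'
#' Left-to-right unroll from a zero initial state; returns the final
#' hidden state.
#'
#' @param xs the input sequence: a list of per-step inputs (vectors or
#'   batch x D matrices), or a batch x T x D array.
#' @param params an [lstm_params()] list.
#' @param peephole see [lstm_step()].
#' @return Final hidden state `h_T` (vector or batch x H matrix).
#' @export
lstm_sequence <- function(xs, params, peephole = TRUE) {
  if (is.array(xs) && length(dim(xs)) == 3L)
    xs <- lapply(seq_len(dim(xs)[2]), function(t) matrix(xs[, t, ], nrow = dim(xs)[1]))
  if (!is.list(xs) || length(xs) == 0) stop("sequence must be non-empty")
  first <- xs[[1]]
  H <- ncol(params$W_hi)
  if (is.null(dim(first))) {
    h <- numeric(H); cc <- numeric(H)
  } else {
    h <- matrix(0, nrow(first), H); cc <- matrix(0, nrow(first), H)
  }
  for (x_t in xs) {
    st <- lstm_step(x_t, h, cc, params, peephole = peephole)
    h <- st$h; cc <- st$c
  }
  h
}

#' Softmax classification head
#'
#' @param h hidden state, length-H vector or batch x H matrix.
#' @param W_out H x C weight matrix.
#' @param b_out length-C bias.
#' @return Probability vector (or batch x C matrix): entries positive,
#'   rows summing to one.
#' @export
classify <- function(h, W_out, b_out) {
  vec_in <- is.null(dim(h))
  if (vec_in) h <- matrix(h, 1)
  if (ncol(h) != nrow(W_out))
    stop("hidden size ", ncol(h), " does not match W_out rows ", nrow(W_out))
  logits <- h %*% W_out + rep_row(b_out, nrow(h))
  p <- .row_softmax(logits)
  if (vec_in) drop(p) else p
}

# ---- training-path forward/backward with caches ------------------------

.lstm_seq_fwd <- function(xs, params, peephole = TRUE) {
  B <- nrow(xs[[1]]); H <- ncol(params$W_hi)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- vector("list", length(xs))
  p <- if (peephole) 1 else 0
  for (t in seq_along(xs)) {
    x_t <- xs[[t]]
    i <- .sigmoid(x_t %*% params$W_qi + h %*% params$W_hi +
                    p * sweep_cols(cc, params$w_ci) + rep_row(params$b_i, B))
    f <- .sigmoid(x_t %*% params$W_qf + h %*% params$W_hf +
                    p * sweep_cols(cc, params$w_cf) + rep_row(params$b_f, B))
    g <- tanh(x_t %*% params$W_qc + h %*% params$W_hc + rep_row(params$b_c, B))
    c_new <- f * cc + i * g
    o <- .sigmoid(x_t %*% params$W_qo + h %*% params$W_ho +
                    p * sweep_cols(c_new, params$w_co) + rep_row(params$b_o, B))
    h_new <- o * tanh(c_new)
    cache[[t]] <- list(x = x_t, h_prev = h, c_prev = cc, i = i, f = f,
                       g = g, o = o, c = c_new)
    h <- h_new; cc <- c_new
  }
  list(h = h, cache = cache, peephole = peephole)
}

.lstm_seq_bwd <- function(fwd, dh_T, params) {
  cache <- fwd$cache
  p <- if (fwd$peephole) 1 else 0
  H <- ncol(params$W_hi)
  gr <- lapply(params, function(w) array(0, dim(w) %||% length(w)))
  dh <- dh_T
  dc <- matrix(0, nrow(dh_T), H)
  dxs <- vector("list", length(cache))
  for (t in rev(seq_along(cache))) {
    s <- cache[[t]]
    tanh_c <- tanh(s$c)
    do <- dh * tanh_c
    dc <- dc + dh * s$o * (1 - tanh_c^2)
    do_pre <- do * s$o * (1 - s$o)
    # output gate peeks at the current cell state
    dc <- dc + p * sweep_cols(do_pre, params$w_co)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    di_pre <- di * s$i * (1 - s$i)
    df_pre <- df * s$f * (1 - s$f)
    dg_pre <- dg * (1 - s$g^2)
    gr$W_qi <- gr$W_qi + crossprod(s$x, di_pre)
    gr$W_qf <- gr$W_qf + crossprod(s$x, df_pre)
    gr$W_qc <- gr$W_qc + crossprod(s$x, dg_pre)
    gr$W_qo <- gr$W_qo + crossprod(s$x, do_pre)
    gr$W_hi <- gr$W_hi + crossprod(s$h_prev, di_pre)
    gr$W_hf <- gr$W_hf + crossprod(s$h_prev, df_pre)
    gr$W_hc <- gr$W_hc + crossprod(s$h_prev, dg_pre)
    gr$W_ho <- gr$W_ho + crossprod(s$h_prev, do_pre)
    if (p == 1) {
      gr$w_ci <- gr$w_ci + colSums(di_pre * s$c_prev)
      gr$w_cf <- gr$w_cf + colSums(df_pre * s$c_prev)
      gr$w_co <- gr$w_co + colSums(do_pre * s$c)
    }
    gr$b_i <- gr$b_i + colSums(di_pre)
    gr$b_f <- gr$b_f + colSums(df_pre)
    gr$b_c <- gr$b_c + colSums(dg_pre)
    gr$b_o <- gr$b_o + colSums(do_pre)
    dxs[[t]] <- di_pre %*% t(params$W_qi) + df_pre %*% t(params$W_qf) +
      dg_pre %*% t(params$W_qc) + do_pre %*% t(params$W_qo)
    dh <- di_pre %*% t(params$W_hi) + df_pre %*% t(params$W_hf) +
      dg_pre %*% t(params$W_hc) + do_pre %*% t(params$W_ho)
    dc <- dc * s$f + p * (sweep_cols(di_pre, params$w_ci) +
                            sweep_cols(df_pre, params$w_cf))
  }
  list(grads = gr, dxs = dxs)
}
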