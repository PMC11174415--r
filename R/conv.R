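# Spatiotemporal stage: 3-D convolution, pseudo-3D factorization,
# partial dot-product attention and average pooling. Tensors are stored
# as batch x N x M x T x C (electrodes, bands, frames, feature maps).

.as_batch5 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be an array")
  if (length(d) == 3L) dim(x) <- c(1L, d, 1L)
  else if (length(d) == 4L) dim(x) <- c(d, 1L)
  else if (length(d) != 5L) stop("input must have 3, 4 or 5 axes")
  x
}

#' 3-D convolution over the (electrode, band, frame) axes
#'
#' Standard 3-D cross-correlation summed over input feature maps, plus a
#' per-output-map bias, then an activation. Output extents follow
#' `floor((size + 2 pad - kernel)/stride) + 1` per axis.
#'
#' @param x input tensor: N x M x T, or batch x N x M x T (x C). A 3- or
#'   4-axis array is promoted to a single-map batch tensor.
#' @param w kernel array P x Q x R x C_in x C_out (a 3-axis kernel is
#'   promoted to one input/output map).
#' @param bias per-output-map bias vector (default zeros).
#' @param stride,pad integer length-3 vectors for the three spatial axes.
#' @param activation `"relu"`, `"tanh"` or `"identity"`.
#' @return batch x N' x M' x T' x C_out array.
#' @export
conv3d <- function(x, w, bias = NULL, stride = c(1L, 1L, 1L),
                   pad = c(0L, 0L, 0L), activation = "identity") {
  x <- .as_batch5(x)
  if (length(dim(w)) == 3L) dim(w) <- c(dim(w), 1L, 1L)
  if (length(dim(w)) != 5L) stop("kernel must have 3 or 5 axes")
  if (dim(w)[4] != dim(x)[5])
    stop("kernel expects ", dim(w)[4], " input maps, got ", dim(x)[5])
  if (is.null(bias)) bias <- numeric(dim(w)[5])
  for (a in 1:3)
    if (dim(x)[a + 1] + 2 * pad[a] < dim(w)[a])
      stop("kernel exceeds padded input extent on axis ", a)
  out <- cpp_conv3d_fwd(as.numeric(x), dim(x), as.numeric(w), dim(w),
                        as.numeric(bias), as.integer(stride), as.integer(pad))
  .activate(out, activation)
}

#' Pseudo-3D (factorized) spatiotemporal convolution block
#'
#' Replaces a full P x Q x R kernel with a spatial P x Q x 1 factor
#' followed by a temporal 1 x 1 x R factor. No nonlinearity sits between
#' the two factors by default (pure factorization); the activation is
#' applied after the temporal factor. The default 3 x 3 x 1 and 1 x 1 x 3
#' kernels with same-padding preserve all three extents.
#'
#' @param x batch tensor (see [conv3d()]).
#' @param w_s spatial kernel P x Q x 1 x C_in x C_out.
#' @param w_t temporal kernel 1 x 1 x R x C_out x C_out.
#' @param bias_s,bias_t per-map biases for the two factors.
#' @param stride length-3 stride applied at the spatial factor.
#' @param pad_s,pad_t paddings for the two factors; `NULL` means
#'   same-padding `floor(kernel/2)`.
#' @param activation final activation (default `"relu"`).
#' @param inner_activation activation between the factors (default
#'   `"identity"`).
#' @return Convolved tensor.
#' @export
pseudo3d_block <- function(x, w_s, w_t, bias_s = NULL, bias_t = NULL,
                           stride = c(1L, 1L, 1L), pad_s = NULL, pad_t = NULL,
                           activation = "relu", inner_activation = "identity") {
  if (is.null(pad_s)) pad_s <- as.integer(dim(w_s)[1:3] %/% 2)
  if (is.null(pad_t)) pad_t <- as.integer(dim(w_t)[1:3] %/% 2)
  h <- conv3d(x, w_s, bias_s, stride = stride, pad = pad_s,
              activation = inner_activation)
  conv3d(h, w_t, bias_t, stride = c(1L, 1L, 1L), pad = pad_t,
         activation = activation)
}

#' Partial dot-product attention over a feature map
#'
#' Scores each position of the map from the map itself through two learned
#' projections and a bias, `S = x M1 M2 + b` (matrix products over the
#' trailing frame/band axes), softmax-normalizes the scores along the
#' frame axis, and gates the input elementwise with the resulting weights.
#' The parameters are shared across feature maps and batch entries.
#'
#' @param x batch x N x M x T x C tensor (3-/4-axis inputs are promoted).
#' @param M1 T x M projection.
#' @param M2 M x T projection.
#' @param b N x M x T additive bias.
#' @return Tensor of the same shape as `x`.
#' @export
partial_dot_attention <- function(x, M1, M2, b) {
  fwd <- .attention_fwd(x, M1, M2, b)
  fwd$out
}

.attention_fwd <- function(x, M1, M2, b) {
  x <- .as_batch5(x)
  d <- dim(x)  # B N M T C
  if (!identical(dim(M1), c(d[4], d[3])))
    stop("M1 must be T x M = ", d[4], " x ", d[3])
  if (!identical(dim(M2), c(d[3], d[4])))
    stop("M2 must be M x T = ", d[3], " x ", d[4])
  if (!identical(dim(b), d[2:4]))
    stop("b must be N x M x T = ", paste(d[2:4], collapse = " x "))
  K <- M1 %*% M2                        # T x T; (x M1) M2 = x (M1 M2)
  xp <- aperm(x, c(1, 2, 3, 5, 4))      # B N M C T
  Xm <- matrix(xp, ncol = d[4])         # (B N M C) x T
  S <- Xm %*% K
  # add b, broadcast over batch and maps
  bm <- matrix(aperm(array(b, c(d[2], d[3], d[4], d[1], d[5])),
                     c(4, 1, 2, 5, 3)), ncol = d[4])
  S <- S + bm
  Wgt <- .row_softmax(S)
  out <- xp * array(Wgt, dim(xp))
  out <- aperm(out, c(1, 2, 3, 5, 4))
  list(out = out, xp = xp, Xm = Xm, Wgt = Wgt, K = K, d = d)
}

.attention_bwd <- function(fwd, dout, M1, M2) {
  d <- fwd$d
  doutp <- aperm(dout, c(1, 2, 3, 5, 4))      # B N M C T
  dWgt <- matrix(doutp * fwd$xp, ncol = d[4]) # rows x T
  Wgt <- fwd$Wgt
  dS <- (dWgt - rowSums(dWgt * Wgt)) * Wgt    # softmax backward, row-wise
  dxp <- doutp * array(Wgt, dim(doutp)) +
    array(dS %*% t(fwd$K), dim(fwd$xp))
  dK <- crossprod(fwd$Xm, dS)                 # T x T
  dM1 <- dK %*% t(M2)
  dM2 <- crossprod(M1, dK)
  # db: sum dS over batch and maps -> N x M x T
  dS_arr <- array(dS, c(d[1], d[2], d[3], d[5], d[4]))
  db <- colSums(aperm(dS_arr, c(1, 4, 2, 3, 5)), dims = 2)
  dx <- aperm(dxp, c(1, 2, 3, 5, 4))
  list(dx = dx, dM1 = dM1, dM2 = dM2, db = db)
}

#' Average pooling over the (electrode, band, frame) axes
#'
#' Non-overlapping window means; trailing partial windows are dropped.
#'
#' @param x batch tensor (see [conv3d()]).
#' @param window length-3 pooling window (default `c(2, 2, 2)`).
#' @param stride length-3 stride (default equal to `window`).
#' @return Pooled batch x N' x M' x T' x C array.
#' @export
avg_pool <- function(x, window = c(2L, 2L, 2L), stride = window) {
  x <- .as_batch5(x)
  d <- dim(x)
  o <- (d[2:4] - window) %/% stride + 1L
  if (any(o < 1)) stop("pooling window exceeds input extent")
  out <- array(0, c(d[1], o, d[5]))
  for (p in seq_len(window[1]) - 1L)
    for (q in seq_len(window[2]) - 1L)
      for (r in seq_len(window[3]) - 1L)
        out <- out + x[, (seq_len(o[1]) - 1L) * stride[1] + 1L + p,
                       (seq_len(o[2]) - 1L) * stride[2] + 1L + q,
                       (seq_len(o[3]) - 1L) * stride[3] + 1L + r, ,
                       drop = FALSE]
  out / prod(window)
}

.avg_pool_bwd <- function(dout, d_in, window = c(2L, 2L, 2L), stride = window) {
  o <- dim(dout)[2:4]
  dx <- array(0, d_in)
  g <- dout / prod(window)
  for (p in seq_len(window[1]) - 1L)
    for (q in seq_len(window[2]) - 1L)
      for (r in seq_len(window[3]) - 1L) {
        i1 <- (seq_len(o[1]) - 1L) * stride[1] + 1L + p
        i2 <- (seq_len(o[2]) - 1L) * stride[2] + 1L + q
        i3 <- (seq_len(o[3]) - 1L) * stride[3] + 1L + r
        dx[, i1, i2, i3, ] <- dx[, i1, i2, i3, , drop = FALSE] + g
      }
  dx
}
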