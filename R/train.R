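# Composed network forward/backward passes and the Adam training loop.
# The backward pass is hand-derived per stage and verified against
# finite differences in the test suite.

.same_pad <- function(kernel) as.integer(kernel %/% 2)

.nn_forward <- function(params, x, config, training = FALSE) {
  d <- dim(x); B <- d[1]; N <- d[2]; M <- d[3]
  act <- config$activation
  stage_dims <- list()
  cache <- list(x_dim = d)

  # ---- per-band spatial stage -----------------------------------------
  # the embedding and graph-convolution GEMMs are batched across samples
  # (rows indexed batch-fastest); only the N x N adjacency work loops
  To <- config$graph_out
  Tn <- d[4]
  sog_out <- array(0, c(B, N, M, To, 1L))
  sog_cache <- vector("list", M)
  for (m in seq_len(M)) {
    Vmat <- matrix(x[, , m, ], B * N, Tn)   # row r = sample b, node n
    if (config$use_sog) {
      Gmat <- tanh(Vmat %*% params$sog$W_embed[[m]])
      Umat <- matrix(0, B * N, Tn)
      samples <- vector("list", B)
      for (i in seq_len(B)) {
        rows <- seq.int(i, by = B, length.out = N)
        G <- Gmat[rows, , drop = FALSE]
        A <- .row_softmax(G %*% t(G))
        mask <- .topk_mask(A, config$k)
        Ak <- A * mask
        Umat[rows, ] <- Ak %*% Vmat[rows, , drop = FALSE]
        samples[[i]] <- list(A = A, mask = mask, Ak = Ak)
      }
      pre <- Umat %*% params$sog$W_gc[[m]]
      sog_cache[[m]] <- list(Vmat = Vmat, Gmat = Gmat, Umat = Umat,
                             pre = pre, samples = samples)
    } else {
      pre <- Vmat %*% params$sog$W_lin[[m]]
      sog_cache[[m]] <- list(Vmat = Vmat, pre = pre)
    }
    sog_out[, , m, , 1] <- array(.activate(pre, act), c(B, N, To))
  }
  cache$sog <- sog_cache
  stage_dims$sog <- dim(sog_out)[2:5]
  cur <- sog_out

  # ---- spatiotemporal stage -------------------------------------------
  if (config$use_conv) {
    pre1 <- cpp_conv3d_fwd(as.numeric(cur), dim(cur),
                           as.numeric(params$conv1$w), dim(params$conv1$w),
                           params$conv1$b, config$conv1_stride,
                           config$conv1_pad)
    cache$conv1 <- list(x = cur, pre = pre1)
    cur <- .activate(pre1, act)
    stage_dims$conv1 <- dim(cur)[2:5]
    pad_s <- .same_pad(config$p3d_spatial)
    pad_t <- .same_pad(config$p3d_temporal)
    one <- c(1L, 1L, 1L)
    for (blk in 1:2) {
      bl <- params[[paste0("block", blk)]]
      s_pre <- cpp_conv3d_fwd(as.numeric(cur), dim(cur), as.numeric(bl$ws),
                              dim(bl$ws), bl$bs, one, pad_s)
      t_pre <- cpp_conv3d_fwd(as.numeric(s_pre), dim(s_pre),
                              as.numeric(bl$wt), dim(bl$wt), bl$bt, one, pad_t)
      cache[[paste0("block", blk)]] <- list(x = cur, s_pre = s_pre,
                                            t_pre = t_pre)
      cur <- .activate(t_pre, act)
      if (config$use_attention) {
        at <- params[[paste0("att", blk)]]
        af <- .attention_fwd(cur, at$M1, at$M2, at$b)
        cache[[paste0("att", blk)]] <- af
        cur <- af$out
      }
      pw <- pmin(config$pool, dim(cur)[2:4])
      cache[[paste0("pool", blk, "_in")]] <- dim(cur)
      cache[[paste0("pool", blk, "_win")]] <- pw
      cur <- avg_pool(cur, pw)
      stage_dims[[paste0("block", blk)]] <- dim(cur)[2:5]
    }
  } else {
    pw <- pmin(config$pool, dim(cur)[2:4])
    cache$pool_in <- dim(cur)
    cache$pool_win <- pw
    cur <- avg_pool(cur, pw)
    stage_dims$pool <- dim(cur)[2:5]
  }
  cache$seq_in_dim <- dim(cur)

  # ---- sequence head ---------------------------------------------------
  dseq <- dim(cur)
  xs <- if (config$lstm_mode == "sequence") {
    lapply(seq_len(dseq[4]), function(t) matrix(cur[, , , t, ], nrow = B))
  } else {
    list(matrix(cur, nrow = B))
  }
  lfwd <- .lstm_seq_fwd(xs, params$lstm, peephole = config$peephole)
  h <- lfwd$h
  mask <- NULL
  if (training && config$dropout > 0) {
    mask <- matrix(stats::rbinom(length(h), 1L, 1 - config$dropout),
                   nrow(h)) / (1 - config$dropout)
    h <- h * mask
  }
  logits <- h %*% params$out$W + rep_row(params$out$b, B)
  probs <- .row_softmax(logits)
  cache$lstm <- lfwd
  cache$h_used <- h
  cache$drop_mask <- mask
  cache$probs <- probs
  list(probs = probs, stage_dims = stage_dims, cache = cache)
}

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like) else p * 0
}

.nn_backward <- function(params, fwd, y_onehot, config) {
  cache <- fwd$cache
  act <- config$activation
  B <- nrow(fwd$probs)
  gr <- .zeros_like(params)

  dlogits <- (fwd$probs - y_onehot) / B
  gr$out$W <- crossprod(cache$h_used, dlogits)
  gr$out$b <- colSums(dlogits)
  dh <- dlogits %*% t(params$out$W)
  if (!is.null(cache$drop_mask)) dh <- dh * cache$drop_mask

  lb <- .lstm_seq_bwd(cache$lstm, dh, params$lstm)
  gr$lstm <- lb$grads

  dseq <- cache$seq_in_dim
  dcur <- array(0, dseq)
  if (config$lstm_mode == "sequence") {
    for (t in seq_len(dseq[4]))
      dcur[, , , t, ] <- array(lb$dxs[[t]], c(B, dseq[2], dseq[3], dseq[5]))
  } else {
    dcur <- array(lb$dxs[[1]], dseq)
  }

  one <- c(1L, 1L, 1L)
  if (config$use_conv) {
    pad_s <- .same_pad(config$p3d_spatial)
    pad_t <- .same_pad(config$p3d_temporal)
    for (blk in 2:1) {
      bl <- params[[paste0("block", blk)]]
      cb <- cache[[paste0("block", blk)]]
      dcur <- .avg_pool_bwd(dcur, cache[[paste0("pool", blk, "_in")]],
                            cache[[paste0("pool", blk, "_win")]])
      if (config$use_attention) {
        at <- params[[paste0("att", blk)]]
        ab <- .attention_bwd(cache[[paste0("att", blk)]], dcur, at$M1, at$M2)
        gr[[paste0("att", blk)]] <- list(M1 = ab$dM1, M2 = ab$dM2, b = ab$db)
        dcur <- ab$dx
      }
      dt_pre <- dcur * .activate_grad(cb$t_pre, act)
      wt_g <- cpp_conv3d_bwd_weights(as.numeric(cb$s_pre), dim(cb$s_pre),
                                     as.numeric(dt_pre), dim(cb$t_pre),
                                     dim(bl$wt), one, pad_t)
      ds_pre <- cpp_conv3d_bwd_input(as.numeric(dt_pre), dim(cb$t_pre),
                                     as.numeric(bl$wt), dim(bl$wt),
                                     dim(cb$s_pre), one, pad_t)
      ws_g <- cpp_conv3d_bwd_weights(as.numeric(cb$x), dim(cb$x),
                                     as.numeric(ds_pre), dim(cb$s_pre),
                                     dim(bl$ws), one, pad_s)
      dcur <- cpp_conv3d_bwd_input(as.numeric(ds_pre), dim(cb$s_pre),
                                   as.numeric(bl$ws), dim(bl$ws),
                                   dim(cb$x), one, pad_s)
      gr[[paste0("block", blk)]] <- list(ws = ws_g$dw, bs = ws_g$db,
                                         wt = wt_g$dw, bt = wt_g$db)
    }
    c1 <- cache$conv1
    dpre1 <- dcur * .activate_grad(c1$pre, act)
    w1_g <- cpp_conv3d_bwd_weights(as.numeric(c1$x), dim(c1$x),
                                   as.numeric(dpre1), dim(c1$pre),
                                   dim(params$conv1$w),
                                   config$conv1_stride, config$conv1_pad)
    gr$conv1 <- list(w = w1_g$dw, b = w1_g$db)
    dcur <- cpp_conv3d_bwd_input(as.numeric(dpre1), dim(c1$pre),
                                 as.numeric(params$conv1$w),
                                 dim(params$conv1$w), dim(c1$x),
                                 config$conv1_stride, config$conv1_pad)
  } else {
    dcur <- .avg_pool_bwd(dcur, cache$pool_in, cache$pool_win)
  }

  # ---- back through the per-band spatial stage ------------------------
  d <- cache$x_dim
  N <- d[2]; M <- d[3]
  To <- config$graph_out
  for (m in seq_len(M)) {
    cc <- cache$sog[[m]]
    dH <- matrix(dcur[, , m, , 1], B * N, To)
    dpre <- dH * .activate_grad(cc$pre, act)
    if (config$use_sog) {
      gr$sog$W_gc[[m]] <- crossprod(cc$Umat, dpre)
      dUmat <- dpre %*% t(params$sog$W_gc[[m]])
      dZmat <- matrix(0, B * N, ncol(cc$Gmat))
      for (i in seq_len(B)) {
        rows <- seq.int(i, by = B, length.out = N)
        sm <- cc$samples[[i]]
        V <- cc$Vmat[rows, , drop = FALSE]
        G <- cc$Gmat[rows, , drop = FALSE]
        dU <- dUmat[rows, , drop = FALSE]
        dAk <- tcrossprod(dU, V)
        dA <- dAk * sm$mask
        dS <- (dA - rowSums(dA * sm$A)) * sm$A
        dZmat[rows, ] <- ((dS + t(dS)) %*% G) * (1 - G^2)
      }
      gr$sog$W_embed[[m]] <- crossprod(cc$Vmat, dZmat)
    } else {
      gr$sog$W_lin[[m]] <- crossprod(cc$Vmat, dpre)
    }
  }
  gr
}

.cross_entropy <- function(probs, y_onehot) {
  eps <- 1e-12
  -mean(log(pmax(rowSums(probs * y_onehot), eps)))
}

# ---- Adam ---------------------------------------------------------------

.adam_update <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    for (j in seq_along(p)) {
      r <- .adam_update(p[[j]], g[[j]], m[[j]], v[[j]], lr, b1, b2, eps, t)
      p[[j]] <- r$p; m[[j]] <- r$m; v[[j]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Training control parameters
#'
#' Defaults follow the published training setup: Adam with learning rate
#' 0.001, batch size 15, up to 200 epochs with early stopping, dropout
#' rate 0.1 (the dropout rate itself lives in [sogpcn_config()]).
#'
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum number of epochs.
#' @param patience early-stop patience: training stops when the monitored
#'   validation loss has not improved for this many epochs and the best
#'   weights are restored. `Inf` disables early stopping.
#' @param beta1,beta2,eps Adam moment parameters (conventional defaults).
#' @param val_fraction fraction of the training set held out for
#'   early-stop monitoring when no explicit validation set is given.
#' @param verbose print per-epoch progress.
#' @return A list of class `sogpcn_control`.
#' @export
sogpcn_control <- function(lr = 0.001, batch_size = 15L, epochs = 200L,
                           patience = 20L, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8, val_fraction = 0.15, verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, patience >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 val_fraction = val_fraction, verbose = verbose),
            class = "sogpcn_control")
}

.predict_probs <- function(params, x, config, chunk = 64L) {
  B <- dim(x)[1]
  out <- matrix(0, B, config$n_classes)
  for (s in seq(1L, B, by = chunk)) {
    e <- min(s + chunk - 1L, B)
    xb <- x[s:e, , , , drop = FALSE]
    out[s:e, ] <- .nn_forward(params, xb, config)$probs
  }
  out
}

# Core minibatch trainer. x: B x N x M x T array, y: 0-based integer
# labels. Returns updated model, history and the best validation loss.
.train_network <- function(model, x, y, x_val = NULL, y_val = NULL,
                           control = sogpcn_control(), seed = 1L) {
  config <- model$config
  params <- model$params
  B <- dim(x)[1]
  C <- config$n_classes
  stopifnot(all(y >= 0), all(y < C))
  onehot <- function(yy) {
    o <- matrix(0, length(yy), C); o[cbind(seq_along(yy), yy + 1L)] <- 1; o
  }
  Y <- onehot(y)
  has_val <- !is.null(x_val)
  if (has_val) Yv <- onehot(y_val)

  set.seed(seed)
  mstate <- .zeros_like(params)
  vstate <- .zeros_like(params)
  step <- 0L
  best_loss <- Inf
  best_params <- params
  best_epoch <- 0L
  bad <- 0L
  hist <- list()

  for (epoch in seq_len(control$epochs)) {
    idx <- sample.int(B)
    ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
    for (s in seq(1L, B, by = control$batch_size)) {
      take <- idx[s:min(s + control$batch_size - 1L, B)]
      xb <- x[take, , , , drop = FALSE]
      yb <- Y[take, , drop = FALSE]
      fwd <- .nn_forward(params, xb, config, training = TRUE)
      loss <- .cross_entropy(fwd$probs, yb)
      if (!is.finite(loss)) stop("training diverged to non-finite loss")
      gr <- .nn_backward(params, fwd, yb, config)
      step <- step + 1L
      r <- .adam_update(params, gr, mstate, vstate, control$lr,
                        control$beta1, control$beta2, control$eps, step)
      params <- r$p; mstate <- r$m; vstate <- r$v
      ep_loss <- ep_loss + loss * length(take)
      ep_n <- ep_n + length(take)
      ep_correct <- ep_correct +
        sum(max.col(fwd$probs, ties.method = "first") ==
              max.col(yb, ties.method = "first"))
    }
    train_loss <- ep_loss / ep_n
    train_acc <- ep_correct / ep_n
    if (has_val) {
      pv <- .predict_probs(params, x_val, config)
      val_loss <- .cross_entropy(pv, Yv)
      val_acc <- mean(max.col(pv, ties.method = "first") == y_val + 1L)
    } else {
      val_loss <- train_loss; val_acc <- train_acc
    }
    hist[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                       train_acc = train_acc, val_loss = val_loss,
                       val_acc = val_acc)
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.4f acc %.3f  val %.4f acc %.3f",
                      epoch, train_loss, train_acc, val_loss, val_acc))
    if (val_loss < best_loss - 1e-8) {
      best_loss <- val_loss; best_params <- params
      best_epoch <- epoch; bad <- 0L
    } else {
      bad <- bad + 1L
      if (is.finite(control$patience) && bad >= control$patience) break
    }
  }
  model$params <- best_params
  list(model = model,
       history = as.data.frame(do.call(rbind, hist)),
       best_epoch = best_epoch, best_val_loss = best_loss)
}
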