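# Model assembly: parameter initialization, the composed forward pass,
# ablation variants.

.glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

.glorot_arr <- function(d) {
  # fan-in = prod(kernel extents) * in-maps, fan-out = prod * out-maps
  fan_in <- prod(d[1:3]) * d[4]
  fan_out <- prod(d[1:3]) * d[5]
  s <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(d), -s, s), d)
}

#' Build a model from a configuration
#'
#' Validates the configuration's shape chain, initializes all parameters
#' (Glorot uniform, forget-gate bias 1) from the given seed, and asserts
#' the symbolic shape chain against an actual forward pass on a dummy
#' batch.
#'
#' @param config a [sogpcn_config()].
#' @param seed integer seed for parameter initialization.
#' @return An object of class `sogpcn_model` with elements `params`,
#'   `config` and `shapes`.
#' @export
build_model <- function(config = sogpcn_config(), seed = 1L) {
  shapes <- derive_shapes(config)   # errors name the failing stage
  set.seed(seed)
  Tn <- config$padded_length; L <- config$embed_dim; To <- config$graph_out
  M <- config$n_bands
  params <- list()
  if (config$use_sog) {
    params$sog <- list(
      W_embed = lapply(seq_len(M), function(m) .glorot(Tn, L)),
      W_gc = lapply(seq_len(M), function(m) .glorot(Tn, To))
    )
  } else {
    params$sog <- list(W_lin = lapply(seq_len(M), function(m) .glorot(Tn, To)))
  }
  Cm <- config$n_maps
  if (config$use_conv) {
    params$conv1 <- list(w = .glorot_arr(c(config$conv1_kernel, 1L, Cm)),
                         b = numeric(Cm))
    for (blk in 1:2) {
      bl <- list(ws = .glorot_arr(c(config$p3d_spatial, Cm, Cm)),
                 bs = numeric(Cm),
                 wt = .glorot_arr(c(config$p3d_temporal, Cm, Cm)),
                 bt = numeric(Cm))
      params[[paste0("block", blk)]] <- bl
      if (config$use_attention) {
        d_in <- if (blk == 1) shapes$conv1 else shapes$block1
        params[[paste0("att", blk)]] <- list(
          M1 = .glorot(d_in[3], d_in[2]),
          M2 = .glorot(d_in[2], d_in[3]),
          b = array(0, d_in[1:3])
        )
      }
    }
  }
  D <- shapes$sequence$features
  lp <- lstm_params(D, config$lstm_hidden, init = "glorot")
  lp$b_f <- rep(1, config$lstm_hidden)  # open forget gates at init
  params$lstm <- unclass(lp)
  params$out <- list(W = .glorot(config$lstm_hidden, config$n_classes),
                     b = numeric(config$n_classes))
  model <- structure(list(params = params, config = config, shapes = shapes,
                          seed = as.integer(seed)),
                     class = "sogpcn_model")
  # assert the symbolic chain against a real forward pass
  dummy <- array(0.1, c(2L, config$n_channels, M, Tn))
  fwd <- .nn_forward(params, dummy, config)
  stopifnot(identical(dim(fwd$probs), c(2L, config$n_classes)))
  for (nm in intersect(names(shapes), names(fwd$stage_dims))) {
    got <- fwd$stage_dims[[nm]]
    want <- shapes[[nm]]
    if (!identical(as.integer(got), as.integer(want)))
      stop("shape chain mismatch at stage ", nm, ": derived ",
           paste(want, collapse = "x"), ", observed ",
           paste(got, collapse = "x"))
  }
  model
}

#' Number of trainable parameters
#'
#' @param model a `sogpcn_model` or fitted `sogpcn` object.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  params <- if (inherits(model, "sogpcn")) model$model$params else model$params
  sum(unlist(rapply(params, length, how = "unlist")))
}

#' Forward pass of a built model
#'
#' Deterministic evaluation-mode forward: dropout is inactive.
#'
#' @param model a `sogpcn_model` (or fitted `sogpcn`).
#' @param x batch x electrodes x bands x frames array (a single trial's
#'   3-axis array is promoted).
#' @return batch x C matrix of class probabilities (rows sum to one).
#' @export
model_forward <- function(model, x) {
  if (inherits(model, "sogpcn")) model <- model$model
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  cfg <- model$config
  want <- c(cfg$n_channels, cfg$n_bands, cfg$padded_length)
  if (!identical(as.integer(dim(x)[2:4]), as.integer(want)))
    stop("input shape ", paste(dim(x)[2:4], collapse = "x"),
         " does not match configured ", paste(want, collapse = "x"))
  .nn_forward(model$params, x, cfg)$probs
}

#' Ablation variants
#'
#' Returns a configuration with one module removed, mirroring the
#' standard ablation set:
#' * `"SOG"` replaces the self-organizing graph module with a per-band
#'   linear map (no learned adjacency),
#' * `"P3DCNN"` removes the convolution/attention stack, feeding the
#'   pooled spatial output directly to the LSTM,
#' * `"PDPAtt"` replaces the attention layers with identity.
#'
#' @param config a [sogpcn_config()].
#' @param variant one of `"SOG"`, `"P3DCNN"`, `"PDPAtt"`.
#' @return A modified `sogpcn_config`.
#' @export
ablate <- function(config, variant) {
  if (!variant %in% c("SOG", "P3DCNN", "PDPAtt"))
    stop("unknown ablation variant: ", variant)
  switch(variant,
         SOG = { config$use_sog <- FALSE; config },
         P3DCNN = { config$use_conv <- FALSE; config },
         PDPAtt = { config$use_attention <- FALSE; config })
}

#' @export
print.sogpcn_model <- function(x, ...) {
  cat("<sogpcn_model> (untrained)\n")
  print(x$config)
  cat(sprintf("  %d trainable parameters, init seed %d\n",
              n_parameters(x), x$seed))
  invisible(x)
}
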