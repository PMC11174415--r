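#' Model configuration
#'
#' Collects every architectural hyperparameter with its default. The
#' derived shape chain is validated at model build time, so any
#' inconsistent combination errors early and names the failing stage.
#'
#' Defaults: the 12-channel temporal-lobe montage, five frequency bands,
#' 265 padded frames, top-k = 10, graph-convolution output width 64,
#' a 3 x 3 x 5 entry convolution with stride 1 x 1 x 3, two pseudo-3D
#' blocks (3 x 3 x 1 then 1 x 1 x 3 kernels, 10 feature maps) each
#' followed by partial dot-product attention and 2 x 2 x 2 average
#' pooling, then a peephole LSTM (hidden size 64) and a 3-class softmax.
#'
#' @param montage electrode labels (default [seed_montage(12)][seed_montage]).
#' @param bands band names (default the five standard bands).
#' @param padded_length frame count after zero padding (default 265).
#' @param k retained neighbors in top-k sparsification (default 10).
#' @param embed_dim width L of the adjacency-learning embedding (default 32).
#' @param graph_out spatial feature width produced by the graph
#'   convolution (default 64).
#' @param n_maps feature maps in the convolutional stage (default 10).
#' @param conv1_kernel,conv1_stride,conv1_pad entry 3-D convolution
#'   geometry. The default padding `c(1, 1, 2)` preserves the electrode
#'   and band extents and yields the temporal chain 64 -> 22 -> 11 -> 5
#'   through the two pooling stages.
#' @param p3d_spatial,p3d_temporal pseudo-3D factor kernels.
#' @param pool pooling window/stride.
#' @param use_sog,use_conv,use_attention stage switches used by
#'   [ablate()].
#' @param lstm_hidden LSTM hidden size (default 64).
#' @param lstm_mode `"sequence"` feeds the pooled tensor to the LSTM as a
#'   sequence of per-frame vectors; `"flat"` feeds one flattened vector
#'   as a single step.
#' @param peephole use the peephole reference cell (default `TRUE`).
#' @param n_classes number of emotion classes (default 3).
#' @param activation network activation (default `"relu"`; `"tanh"`
#'   selects the alternative printed form).
#' @param dropout dropout rate on the LSTM output during training
#'   (default 0.1).
#' @return An object of class `sogpcn_config`.
#' @export
sogpcn_config <- function(montage = seed_montage(12),
                          bands = seed_bands()$name,
                          padded_length = 265L,
                          k = 10L,
                          embed_dim = 32L,
                          graph_out = 64L,
                          n_maps = 10L,
                          conv1_kernel = c(3L, 3L, 5L),
                          conv1_stride = c(1L, 1L, 3L),
                          conv1_pad = c(1L, 1L, 2L),
                          p3d_spatial = c(3L, 3L, 1L),
                          p3d_temporal = c(1L, 1L, 3L),
                          pool = c(2L, 2L, 2L),
                          use_sog = TRUE,
                          use_conv = TRUE,
                          use_attention = TRUE,
                          lstm_hidden = 64L,
                          lstm_mode = c("sequence", "flat"),
                          peephole = TRUE,
                          n_classes = 3L,
                          activation = "relu",
                          dropout = 0.1) {
  cfg <- list(montage = montage, bands = bands,
              n_channels = length(montage), n_bands = length(bands),
              padded_length = as.integer(padded_length), k = as.integer(k),
              embed_dim = as.integer(embed_dim),
              graph_out = as.integer(graph_out), n_maps = as.integer(n_maps),
              conv1_kernel = as.integer(conv1_kernel),
              conv1_stride = as.integer(conv1_stride),
              conv1_pad = as.integer(conv1_pad),
              p3d_spatial = as.integer(p3d_spatial),
              p3d_temporal = as.integer(p3d_temporal),
              pool = as.integer(pool),
              use_sog = use_sog, use_conv = use_conv,
              use_attention = use_attention,
              lstm_hidden = as.integer(lstm_hidden),
              lstm_mode = match.arg(lstm_mode),
              peephole = peephole,
              n_classes = as.integer(n_classes),
              activation = activation, dropout = dropout)
  class(cfg) <- "sogpcn_config"
  ext <- unlist(cfg[c("padded_length", "k", "embed_dim", "graph_out",
                      "n_maps", "lstm_hidden", "n_classes", "n_channels",
                      "n_bands")])
  if (any(ext < 1)) stop("all extents must be positive")
  if (cfg$k > cfg$n_channels)
    stop("k (", cfg$k, ") exceeds the electrode count (", cfg$n_channels, ")")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  cfg
}

#' Derive the tensor shape chain of a configuration
#'
#' Recomputes every stage's output extents symbolically from the
#' configuration arithmetic; [build_model()] asserts this chain against an
#' actual forward pass on a dummy batch.
#'
#' @param config a [sogpcn_config()].
#' @return Named list of stage shapes (`input`, `sog`, optional `conv1`,
#'   `block1`, `block2`, `pool`, and `sequence` with `len`/`features`).
#' @export
derive_shapes <- function(config) {
  cout <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L
  N <- config$n_channels; M <- config$n_bands
  shapes <- list(input = c(N, M, config$padded_length))
  cur <- c(N, M, config$graph_out); maps <- 1L
  shapes$sog <- c(cur, maps)
  if (config$use_conv) {
    cur <- vapply(1:3, function(a) cout(cur[a], config$conv1_kernel[a],
                                        config$conv1_stride[a],
                                        config$conv1_pad[a]), 1L)
    if (any(cur < 1)) stop("shape chain fails at stage conv1: extents ",
                           paste(cur, collapse = "x"))
    maps <- config$n_maps
    shapes$conv1 <- c(cur, maps)
    for (blk in 1:2) {
      # same-padded pseudo-3D factors preserve extents; pooling floors,
      # with the window clamped to the axis extent (so e.g. single-band
      # inputs keep their band axis rather than pooling it away)
      pw <- pmin(config$pool, cur)
      cur <- (cur - pw) %/% pw + 1L
      if (any(cur < 1)) stop("shape chain fails at stage block", blk,
                             " pooling: extents ", paste(cur, collapse = "x"))
      shapes[[paste0("block", blk)]] <- c(cur, maps)
    }
  } else {
    pw <- pmin(config$pool, cur)
    cur <- (cur - pw) %/% pw + 1L
    if (any(cur < 1)) stop("shape chain fails at stage pool: extents ",
                           paste(cur, collapse = "x"))
    shapes$pool <- c(cur, maps)
  }
  if (config$lstm_mode == "sequence") {
    shapes$sequence <- list(len = cur[3], features = cur[1] * cur[2] * maps)
  } else {
    shapes$sequence <- list(len = 1L, features = prod(cur) * maps)
  }
  shapes
}

#' @export
print.sogpcn_config <- function(x, ...) {
  cat("<sogpcn_config>\n")
  cat(sprintf("  %d electrodes x %d bands x %d frames; k = %d, L = %d, T' = %d\n",
              x$n_channels, x$n_bands, x$padded_length, x$k, x$embed_dim,
              x$graph_out))
  cat(sprintf("  stages: sog=%s conv=%s attention=%s; %d maps, LSTM %d (%s), %d classes\n",
              x$use_sog, x$use_conv, x$use_attention, x$n_maps,
              x$lstm_hidden, x$lstm_mode, x$n_classes))
  sh <- derive_shapes(x)
  cat("  shape chain:", paste(vapply(sh[names(sh) != "sequence"],
                                     function(s) paste(s, collapse = "x"), ""),
                              collapse = " -> "),
      sprintf("-> seq %d x %d\n", sh$sequence$len, sh$sequence$features))
  invisible(x)
}
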