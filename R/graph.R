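#' Node embedding for self-organizing adjacency learning
#'
#' Projects per-electrode feature vectors through a linear layer with tanh
#' activation, `G = tanh(V W)`.
#'
#' @param V node-feature matrix, electrodes N x features F (for one band,
#'   F is the padded frame count).
#' @param W embedding weight matrix, F x L.
#' @return N x L embedding with entries in (-1, 1).
#' @export
node_embedding <- function(V, W) {
  V <- as.matrix(V); W <- as.matrix(W)
  if (ncol(V) != nrow(W))
    stop("shape mismatch: V is ", nrow(V), "x", ncol(V),
         " but W is ", nrow(W), "x", ncol(W))
  tanh(V %*% W)
}

#' Self-organizing adjacency from a node embedding
#'
#' Pairwise similarity scores `G G^T` are exp-normalized row-wise
#' (softmax), so each electrode's outgoing connection weights are strictly
#' positive and sum to one: the adjacency is learned from the input rather
#' than fixed by electrode geometry.
#'
#' @param G_embed N x L node embedding, as from [node_embedding()].
#' @return N x N right-stochastic adjacency matrix.
#' @export
self_organizing_adjacency <- function(G_embed) {
  G_embed <- as.matrix(G_embed)
  if (!all(is.finite(G_embed))) stop("non-finite entries in embedding")
  if (nrow(G_embed) < 2) stop("need at least two nodes")
  S <- G_embed %*% t(G_embed)
  .row_softmax(S)
}

.row_softmax <- function(S) {
  # stability shift by the row max; softmax is invariant to it
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - mx)
  E / rowSums(E)
}

#' Top-k sparsification of an adjacency matrix
#'
#' Per row, the k largest entries are retained at their values and all
#' others set to exactly zero; no renormalization is applied. Ties are
#' broken by ascending column index (stable selection).
#'
#' @param A N x N adjacency matrix.
#' @param k number of retained neighbors per row, in `1:N`.
#' @return Sparsified matrix with exactly `min(k, N)` nonzeros per row
#'   (assuming nonzero inputs).
#' @export
topk_sparsify <- function(A, k) {
  A <- as.matrix(A)
  N <- ncol(A)
  if (k < 1 || k > N) stop("k must be between 1 and ", N)
  if (k == N) return(A)
  out <- A
  for (i in seq_len(nrow(A))) {
    keep <- order(A[i, ], decreasing = TRUE)[seq_len(k)]
    out[i, -keep] <- 0
  }
  out
}

# logical mask of retained entries, used on the training path; operates
# on many stacked rows at once. Same semantics as topk_sparsify: keep
# the k largest per row, ties broken by ascending column index. When
# k > N/2 it is cheaper to discard the N-k smallest (dropping the
# latest-indexed among tied minima keeps the earliest-indexed ties,
# matching the stable selection).
.topk_mask <- function(A, k) {
  N <- ncol(A)
  n <- nrow(A)
  if (k >= N) return(matrix(TRUE, n, N))
  rows <- seq_len(n)
  if (k > N / 2) {
    m <- matrix(TRUE, n, N)
    S <- A
    for (j in seq_len(N - k)) {
      drop <- max.col(-S, ties.method = "last")
      m[cbind(rows, drop)] <- FALSE
      S[cbind(rows, drop)] <- Inf
    }
  } else {
    m <- matrix(FALSE, n, N)
    S <- A
    for (j in seq_len(k)) {
      keep <- max.col(S, ties.method = "first")
      m[cbind(rows, keep)] <- TRUE
      S[cbind(rows, keep)] <- -Inf
    }
  }
  m
}

#' Graph convolution
#'
#' Aggregates node features through the (sparsified) adjacency and applies
#' a linear map and activation: `activation(A_k X W)`. The learned
#' adjacency is already row-normalized, so no degree normalization or
#' self-loop augmentation is applied.
#'
#' @param X node features N x F.
#' @param A_k adjacency N x N (typically the top-k sparsified matrix).
#' @param W weight matrix F x F_out.
#' @param activation `"relu"`, `"tanh"` or `"identity"`.
#' @return N x F_out matrix.
#' @export
graph_conv <- function(X, A_k, W, activation = "relu") {
  X <- as.matrix(X); A_k <- as.matrix(A_k); W <- as.matrix(W)
  if (ncol(A_k) != nrow(X) || ncol(X) != nrow(W))
    stop("shape mismatch in graph convolution: A_k ", nrow(A_k), "x", ncol(A_k),
         ", X ", nrow(X), "x", ncol(X), ", W ", nrow(W), "x", ncol(W))
  .activate(A_k %*% X %*% W, activation)
}

.activate <- function(x, activation) {
  switch(activation,
         relu = x * (x > 0),
         tanh = tanh(x),
         identity = x,
         stop("unknown activation: ", activation))
}

.activate_grad <- function(pre, activation) {
  switch(activation,
         relu = (pre > 0) * 1,
         tanh = 1 - tanh(pre)^2,
         identity = array(1, dim(pre)),
         stop("unknown activation: ", activation))
}

#' Per-band self-organizing graph convolution forward pass
#'
#' For each frequency band independently: the band's electrodes x frames
#' slice is embedded ([node_embedding()]), turned into a learned adjacency
#' ([self_organizing_adjacency()]), sparsified ([topk_sparsify()]) and
#' convolved ([graph_conv()]) down to `F_out` spatial features per
#' electrode. Band outputs are stacked and a trailing singleton feature-map
#' axis is appended, yielding the tensor consumed by the spatiotemporal
#' stage.
#'
#' @param x batch x electrodes x bands x frames array (a single trial's
#'   3-axis array is promoted to a batch of one).
#' @param W_embed list of per-band embedding matrices (frames x L).
#' @param W_gc list of per-band graph-convolution weights (frames x F_out).
#' @param k retained-neighbor count for top-k sparsification.
#' @param activation activation applied after the graph convolution.
#' @return batch x electrodes x bands x F_out x 1 array.
#' @export
sog_forward <- function(x, W_embed, W_gc, k = 10L, activation = "relu") {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  if (!all(is.finite(x))) stop("non-finite values in input tensor")
  d <- dim(x)
  B <- d[1]; N <- d[2]; M <- d[3]
  if (length(W_embed) != M || length(W_gc) != M)
    stop("need one W_embed and one W_gc per band (", M, " bands)")
  Tout <- ncol(W_gc[[1]])
  out <- array(0, c(B, N, M, Tout, 1L))
  for (i in seq_len(B)) {
    for (m in seq_len(M)) {
      V <- matrix(x[i, , m, ], nrow = N)
      G <- node_embedding(V, W_embed[[m]])
      A <- self_organizing_adjacency(G)
      A_k <- topk_sparsify(A, k)
      out[i, , m, , 1] <- graph_conv(V, A_k, W_gc[[m]], activation)
    }
  }
  out
}
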