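test_that("node_embedding is tanh of the matrix product", {
  V <- diag(2)
  W <- matrix(c(0.5, -0.5), 2, 1)
  expect_equal(node_embedding(V, W),
               matrix(c(tanh(0.5), tanh(-0.5)), 2, 1))
  expect_equal(node_embedding(V, matrix(0, 2, 3)), matrix(0, 2, 3))
  big <- node_embedding(matrix(10, 3, 2), matrix(1, 2, 2))
  expect_true(all(abs(big - 1) < 1e-4))
  expect_error(node_embedding(matrix(1, 2, 3), matrix(1, 2, 2)),
               "shape mismatch")
})

test_that("self-organizing adjacency is a row-wise softmax of GG^T", {
  expect_equal(self_organizing_adjacency(matrix(0, 4, 3)),
               matrix(0.25, 4, 4))
  set.seed(1)
  G <- matrix(rnorm(12), 4, 3)
  A <- self_organizing_adjacency(G)
  expect_rows_sum_to_one(A)
  expect_true(all(A > 0))
  # brute-force softmax oracle on the raw score matrix, N = 3
  G3 <- matrix(c(0.3, -1, 2, 0.5, 0, 1), 3, 2)
  S <- G3 %*% t(G3)
  oracle <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(self_organizing_adjacency(G3), oracle, tolerance = 1e-12)
  expect_error(self_organizing_adjacency(matrix(c(1, NA, 1, 1), 2)),
               "non-finite")
  expect_error(self_organizing_adjacency(matrix(1, 1, 2)), "two nodes")
})

test_that("adjacency is permutation-equivariant", {
  set.seed(2)
  V <- matrix(rnorm(5 * 7), 5, 7)
  W <- matrix(rnorm(7 * 3), 7, 3)
  A <- self_organizing_adjacency(node_embedding(V, W))
  perm <- c(3, 1, 5, 2, 4)
  Ap <- self_organizing_adjacency(node_embedding(V[perm, ], W))
  expect_equal(Ap, A[perm, perm], tolerance = 1e-12)
})

test_that("topk_sparsify retains the k largest entries per row", {
  expect_equal(topk_sparsify(matrix(c(0.5, 0.3, 0.2), 1), 2),
               matrix(c(0.5, 0.3, 0), 1))
  set.seed(3)
  A <- self_organizing_adjacency(matrix(rnorm(36), 12, 3))
  Ak <- topk_sparsify(A, 10)
  expect_true(all(rowSums(Ak != 0) == 10))
  expect_true(all(Ak[Ak != 0] %in% A))
  expect_identical(topk_sparsify(A, 12), A)
  expect_error(topk_sparsify(A, 0), "between 1 and")
  expect_error(topk_sparsify(A, 13), "between 1 and")
})

test_that("topk_sparsify matches a full-sort oracle for all k, with stable ties", {
  set.seed(4)
  for (rep in 1:3) {
    N <- sample(3:9, 1)
    A <- matrix(runif(N * N), N, N)
    for (k in seq_len(N)) {
      Ak <- topk_sparsify(A, k)
      for (i in seq_len(N)) {
        thr <- sort(A[i, ], decreasing = TRUE)[k]
        expect_equal(sum(Ak[i, ] != 0), k)
        expect_true(all(Ak[i, Ak[i, ] != 0] >= thr))
        expect_equal(Ak[i, Ak[i, ] != 0], A[i, Ak[i, ] != 0])
      }
    }
  }
  # exact ties broken by ascending column index
  tied <- matrix(c(0.3, 0.3, 0.3, 0.1), 1)
  expect_equal(topk_sparsify(tied, 2), matrix(c(0.3, 0.3, 0, 0), 1))
})

test_that("the batched training-path mask agrees with topk_sparsify", {
  set.seed(14)
  for (rep in 1:3) {
    N <- sample(4:10, 1)
    A <- matrix(runif(20 * N), 20, N)
    # inject exact ties
    A[3, 1:3] <- 0.5
    A[7, ] <- 0.25
    for (k in seq_len(N)) {
      mask <- sogpcn:::.topk_mask(A, k)
      expect_equal(A * mask, topk_sparsify(A, k),
                   info = paste("N", N, "k", k))
    }
  }
})

test_that("graph_conv computes activation(A X W)", {
  X <- matrix(1:6, 3, 2)
  expect_equal(graph_conv(X, diag(3), diag(2), "identity"), X)
  Aunif <- matrix(1 / 3, 3, 3)
  out <- graph_conv(X, Aunif, diag(2), "identity")
  expect_equal(out, matrix(colMeans(X), 3, 2, byrow = TRUE))
  # direct two-matmul oracle on a 3 x 2 case
  set.seed(5)
  A <- matrix(runif(9), 3)
  W <- matrix(rnorm(4), 2)
  expect_equal(graph_conv(X, A, W, "relu"), pmax(A %*% X %*% W, 0))
  expect_error(graph_conv(X, matrix(1, 2, 2), W), "shape mismatch")
})

test_that("sog_forward produces the documented spatial tensor shape", {
  cfg <- sogpcn_config()
  m <- build_model(cfg, seed = 1)
  x <- array(rnorm(2 * 12 * 5 * 265), c(2, 12, 5, 265))
  out <- sog_forward(x, m$params$sog$W_embed, m$params$sog$W_gc, k = 10)
  expect_equal(dim(out), c(2, 12, 5, 64, 1))
  one <- sog_forward(x[1, , , , drop = TRUE], m$params$sog$W_embed,
                     m$params$sog$W_gc, k = 10)
  expect_equal(dim(one), c(1, 12, 5, 64, 1))
  expect_equal(one[1, , , , ], out[1, , , , ], tolerance = 1e-12)
  expect_error(sog_forward(x * NA, m$params$sog$W_embed, m$params$sog$W_gc),
               "non-finite")
})

test_that("sog_forward equals the manual per-band composition", {
  set.seed(6)
  N <- 3; M <- 2; Tn <- 4; L <- 2; To <- 3
  W_e <- lapply(1:M, function(m) matrix(rnorm(Tn * L), Tn, L))
  W_g <- lapply(1:M, function(m) matrix(rnorm(Tn * To), Tn, To))
  x <- array(rnorm(N * M * Tn), c(1, N, M, Tn))
  out <- sog_forward(x, W_e, W_g, k = 2)
  for (m in 1:M) {
    V <- matrix(x[1, , m, ], N)
    manual <- graph_conv(
      V, topk_sparsify(self_organizing_adjacency(node_embedding(V, W_e[[m]])), 2),
      W_g[[m]], "relu")
    expect_equal(out[1, , m, , 1], manual, tolerance = 1e-12)
  }
})

test_that("bands are processed independently", {
  set.seed(7)
  N <- 4; M <- 3; Tn <- 6
  W_e <- lapply(1:M, function(m) matrix(rnorm(Tn * 2), Tn, 2))
  W_g <- lapply(1:M, function(m) matrix(rnorm(Tn * 5), Tn, 5))
  x <- array(rnorm(N * M * Tn), c(1, N, M, Tn))
  base <- sog_forward(x, W_e, W_g, k = 3)
  x2 <- x
  x2[1, , 2, ] <- x2[1, , 2, ] + 1
  pert <- sog_forward(x2, W_e, W_g, k = 3)
  expect_false(isTRUE(all.equal(pert[1, , 2, , 1], base[1, , 2, , 1])))
  expect_equal(pert[1, , c(1, 3), , 1], base[1, , c(1, 3), , 1],
               tolerance = 1e-12)
})
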