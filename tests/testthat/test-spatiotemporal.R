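# direct four-nested-loop 3-D cross-correlation used as the oracle
naive_conv3d <- function(x, w, bias = 0, stride = c(1, 1, 1),
                         pad = c(0, 0, 0)) {
  d <- dim(x)   # N1 N2 N3 (single map, single sample)
  k <- dim(w)
  o <- (d + 2 * pad - k) %/% stride + 1
  out <- array(0, o)
  for (i in seq_len(o[1])) for (j in seq_len(o[2])) for (t in seq_len(o[3])) {
    acc <- bias
    for (p in seq_len(k[1])) for (q in seq_len(k[2])) for (r in seq_len(k[3])) {
      i1 <- (i - 1) * stride[1] + p - pad[1]
      i2 <- (j - 1) * stride[2] + q - pad[2]
      i3 <- (t - 1) * stride[3] + r - pad[3]
      if (i1 >= 1 && i1 <= d[1] && i2 >= 1 && i2 <= d[2] &&
          i3 >= 1 && i3 <= d[3])
        acc <- acc + w[p, q, r] * x[i1, i2, i3]
    }
    out[i, j, t] <- acc
  }
  out
}

test_that("conv3d reproduces identity and hand-computable kernels", {
  set.seed(1)
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  delta <- array(0, c(1, 1, 1))
  delta[1, 1, 1] <- 1
  expect_equal(drop(conv3d(x, delta)), x, tolerance = 1e-12)
  cube <- array(1:8, c(2, 2, 2))
  expect_equal(as.numeric(conv3d(cube, array(1, c(2, 2, 2)))), 36)
  expect_error(conv3d(cube, array(1, c(3, 3, 3))), "exceeds padded input")
})

test_that("conv3d matches the four-nested-loop oracle", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  w <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  for (case in list(list(s = c(1, 1, 1), p = c(0, 0, 0)),
                    list(s = c(1, 1, 2), p = c(1, 1, 1)),
                    list(s = c(2, 1, 3), p = c(0, 1, 2)))) {
    got <- drop(conv3d(x, w, bias = 0.3, stride = case$s, pad = case$p))
    want <- naive_conv3d(x, w, bias = 0.3, stride = case$s, pad = case$p)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("conv3d is linear before activation", {
  set.seed(3)
  x <- array(rnorm(48), c(3, 4, 4))
  y <- array(rnorm(48), c(3, 4, 4))
  w <- array(rnorm(8), c(2, 2, 2))
  lhs <- conv3d(2 * x - 3 * y, w)
  rhs <- 2 * conv3d(x, w) - 3 * conv3d(y, w)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("pseudo-3D factorization equals the full kernel for rank-1 kernels", {
  set.seed(4)
  u <- matrix(rnorm(9), 3, 3)          # spatial factor P x Q
  v <- rnorm(3)                        # temporal factor R
  w_full <- array(0, c(3, 3, 3, 1, 1))
  for (r in 1:3) w_full[, , r, 1, 1] <- u * v[r]
  w_s <- array(u, c(3, 3, 1, 1, 1))
  w_t <- array(v, c(1, 1, 3, 1, 1))
  x <- array(rnorm(5 * 4 * 6), c(5, 4, 6))
  full <- conv3d(x, w_full, pad = c(1, 1, 1))
  fact <- pseudo3d_block(x, w_s, w_t, activation = "identity")
  expect_equal(fact, full, tolerance = 1e-5)
  # delta factors give identity
  ds <- array(0, c(3, 3, 1, 1, 1)); ds[2, 2, 1, 1, 1] <- 1
  dt <- array(0, c(1, 1, 3, 1, 1)); dt[1, 1, 2, 1, 1] <- 1
  expect_equal(drop(pseudo3d_block(x, ds, dt, activation = "identity")), x,
               tolerance = 1e-12)
})

test_that("default same-padded pseudo-3D kernels preserve extents", {
  cfg <- sogpcn_config()
  Cm <- 2
  x <- array(rnorm(2 * 6 * 5 * 8 * Cm), c(2, 6, 5, 8, Cm))
  w_s <- array(rnorm(prod(c(cfg$p3d_spatial, Cm, Cm))),
               c(cfg$p3d_spatial, Cm, Cm))
  w_t <- array(rnorm(prod(c(cfg$p3d_temporal, Cm, Cm))),
               c(cfg$p3d_temporal, Cm, Cm))
  out <- pseudo3d_block(x, w_s, w_t)
  expect_equal(dim(out), dim(x))
  expect_true(all(out >= 0))   # ReLU output
})

test_that("partial dot-product attention: uniform case and shape contract", {
  set.seed(5)
  x <- array(rnorm(2 * 3 * 4 * 5 * 2), c(2, 3, 4, 5, 2))
  M1 <- matrix(0, 5, 4); M2 <- matrix(0, 4, 5); b <- array(0, c(3, 4, 5))
  out <- partial_dot_attention(x, M1, M2, b)
  expect_equal(out, x / 5, tolerance = 1e-12)   # uniform weights 1/T
  M1r <- matrix(rnorm(20), 5, 4); M2r <- matrix(rnorm(20), 4, 5)
  br <- array(rnorm(60), c(3, 4, 5))
  out2 <- partial_dot_attention(x, M1r, M2r, br)
  expect_equal(dim(out2), dim(x))
  expect_error(partial_dot_attention(x, matrix(0, 4, 5), M2r, br), "M1 must be")
})

test_that("attention matches direct formula evaluation on N=2, M=2, T=3", {
  set.seed(6)
  N <- 2; M <- 2; Tt <- 3
  x <- array(rnorm(N * M * Tt), c(N, M, Tt))
  M1 <- matrix(rnorm(Tt * M), Tt, M)
  M2 <- matrix(rnorm(M * Tt), M, Tt)
  b <- array(rnorm(N * M * Tt), c(N, M, Tt))
  got <- drop(partial_dot_attention(x, M1, M2, b))
  want <- array(0, c(N, M, Tt))
  for (n in 1:N) {
    score <- x[n, , ] %*% M1 %*% M2 + b[n, , ]
    for (m in 1:M) {
      wgt <- exp(score[m, ]) / sum(exp(score[m, ]))
      expect_equal(sum(wgt), 1, tolerance = 1e-9)
      want[n, m, ] <- x[n, m, ] * wgt
    }
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("attention weights are positive and sum to one along frames", {
  set.seed(7)
  x <- array(rnorm(2 * 3 * 2 * 4 * 2) + 3, c(2, 3, 2, 4, 2))  # positive input
  M1 <- matrix(rnorm(8), 4, 2); M2 <- matrix(rnorm(8), 2, 4)
  b <- array(rnorm(24), c(3, 2, 4))
  out <- partial_dot_attention(x, M1, M2, b)
  wgt <- out / x
  expect_true(all(wgt > 0))       # softmax gates never flip sign
  sums <- apply(wgt, c(1, 2, 3, 5), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("avg_pool averages non-overlapping windows", {
  const <- array(2.5, c(4, 4, 4))
  expect_equal(drop(avg_pool(const)), array(2.5, c(2, 2, 2)))
  cube <- array(1:8, c(2, 2, 2))
  expect_equal(as.numeric(avg_pool(cube)), 4.5)
  set.seed(8)
  x <- array(rnorm(64), c(4, 4, 4))
  got <- drop(avg_pool(x))
  for (i in 1:2) for (j in 1:2) for (t in 1:2)
    expect_equal(got[i, j, t],
                 mean(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                        (2 * t - 1):(2 * t)]))
  expect_error(avg_pool(array(1, c(1, 4, 4))), "exceeds input")
})
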