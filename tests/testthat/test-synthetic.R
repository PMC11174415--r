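test_that("generation is bit-reproducible from the seed", {
  sp <- tiny_spec(seed = 5)
  d1 <- generate_dataset(sp)
  d2 <- generate_dataset(sp)
  expect_identical(d1, d2)
  d3 <- generate_dataset(tiny_spec(seed = 6))
  expect_false(identical(d1, d3))
  r1 <- planted_structure_report(sp)
  expect_identical(r1, planted_structure_report(sp))
})

test_that("trial lengths, labels and subjects follow the configured design", {
  sp <- synthetic_spec(n_subjects = 4, trials_per_subject = 9,
                       length_range = c(185L, 265L), seed = 2)
  ds <- generate_dataset(sp)
  expect_length(ds, 36)
  lens <- vapply(ds, function(tr) dim(tr$de)[3], 1L)
  expect_true(all(lens >= 185 & lens <= 265))
  expect_equal(sort(unique(vapply(ds, `[[`, 1L, "subject"))), 1:4)
  labs <- vapply(ds, `[[`, 1L, "label")
  expect_equal(unname(table(labs)), rep(12L, 3), ignore_attr = TRUE)
  expect_equal(dim(ds[[1]]$de)[1:2], c(12, 5))
  expect_identical(dimnames(ds[[1]]$de)[[1]], seed_montage(12))
})

test_that("zero effect size leaves class-conditional means indistinguishable", {
  sp <- synthetic_spec(n_subjects = 10, trials_per_subject = 10,
                       length_range = c(50L, 50L), effect_size = 0,
                       subject_sd = 0, seed = 3)
  ds <- generate_dataset(sp)
  labs <- vapply(ds, `[[`, 1L, "label")
  mean_by_class <- function(cl) {
    sel <- ds[labs == cl]
    m <- sapply(sel, function(tr) rowMeans(matrix(tr$de, 12 * 5)))
    list(mean = rowMeans(m), se = apply(m, 1, stats::sd) / sqrt(ncol(m)))
  }
  a <- mean_by_class(0); b <- mean_by_class(2)
  z <- abs(a$mean - b$mean) / sqrt(a$se^2 + b$se^2)
  expect_true(all(z < 3.5))  # ~3 standard errors plus multiplicity slack
})

test_that("nonzero effect size plants detectable shifts only on the mask", {
  sp <- synthetic_spec(n_subjects = 10, trials_per_subject = 10,
                       length_range = c(50L, 50L), effect_size = 1,
                       subject_sd = 0, seed = 4)
  ds <- generate_dataset(sp)
  rep <- planted_structure_report(sp)
  labs <- vapply(ds, `[[`, 1L, "label")
  m0 <- Reduce(`+`, lapply(ds[labs == 0], function(tr)
    apply(tr$de, c(1, 2), mean))) / sum(labs == 0)
  m2 <- Reduce(`+`, lapply(ds[labs == 2], function(tr)
    apply(tr$de, c(1, 2), mean))) / sum(labs == 2)
  diff <- m2 - m0
  expect_true(all(diff[rep$effect_mask] > 0.5))   # planted shift ~ 2e = 2
  expect_true(all(abs(diff[!rep$effect_mask]) < 0.5))
})

test_that("planted coupling drives inter-channel correlation", {
  # no coupling: off-diagonal correlations vanish with many pooled frames
  sp0 <- synthetic_spec(n_subjects = 1, trials_per_subject = 50,
                        length_range = c(265L, 265L), effect_size = 0,
                        subject_sd = 0, planted_degree = 0L, seed = 5)
  expect_equal(planted_structure_report(sp0)$adjacency, diag(12))
  pooled <- do.call(cbind, lapply(generate_dataset(sp0),
                                  function(tr) tr$de[, 1, ]))
  r0 <- stats::cor(t(pooled))
  expect_true(max(abs(r0[upper.tri(r0)])) < 0.1)

  # strong coupling: planted neighbors correlate strongly
  sp1 <- synthetic_spec(n_subjects = 1, trials_per_subject = 10,
                        length_range = c(265L, 265L), effect_size = 0,
                        subject_sd = 0, planted_degree = 10L, mixing = 0.5,
                        seed = 6)
  rep1 <- planted_structure_report(sp1)
  pooled1 <- do.call(cbind, lapply(generate_dataset(sp1),
                                   function(tr) tr$de[, 1, ]))
  r1 <- stats::cor(t(pooled1))
  planted <- rep1$adjacency == 1 & upper.tri(rep1$adjacency)
  expect_true(all(r1[planted] > 0.5))
})

test_that("achievable accuracy is monotone non-decreasing in the effect size", {
  cfg <- tiny_config()
  ctrl <- sogpcn_control(epochs = 20, patience = 20, val_fraction = 0)
  acc <- vapply(c(0, 0.75, 2), function(e) {
    sp <- synthetic_spec(n_subjects = 4, trials_per_subject = 9,
                         montage = paste0("C", 1:4),
                         length_range = c(10L, 12L), planted_degree = 2L,
                         effect_size = e, seed = 9)
    ds <- generate_dataset(sp)
    labs <- vapply(ds, `[[`, 1L, "label")
    test_ix <- which(vapply(ds, `[[`, 1L, "subject") == 4)
    fit <- sogpcn(ds[-test_ix], config = cfg, control = ctrl, seed = 31)
    100 * mean(predict(fit, ds[test_ix]) == labs[test_ix])
  }, 0)
  expect_gte(acc[2], acc[1] - 5)
  expect_gte(acc[3], acc[2] - 5)
})
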