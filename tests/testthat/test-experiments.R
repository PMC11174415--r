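fast_ctrl <- function(...) sogpcn_control(epochs = 2, patience = 2,
                                          val_fraction = 0, ...)

test_that("confusion counts true-by-predicted pairs", {
  perfect <- confusion(c(0, 1, 2, 1), c(0, 1, 2, 1), 3)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(diag(perfect), c(`0` = 1L, `1` = 2L, `2` = 1L))

  # hand-counted six-item example
  cm <- confusion(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 0, 2), 3)
  expect_equal(unname(cm),
               matrix(c(1L, 1L, 0L,
                        0L, 2L, 0L,
                        1L, 0L, 1L), 3, byrow = TRUE))
  expect_equal(unname(rowSums(cm)), c(2L, 2L, 2L))
  expect_error(confusion(c(0, 3), c(0, 0), 3), "outside")
  expect_error(confusion(0:1, 0L, 2), "equal length")
})

test_that("LOSO folds hold out one whole subject each", {
  ds <- generate_dataset(tiny_spec(effect_size = 0, seed = 1))
  res <- loso_cv(ds, tiny_config(), fast_ctrl(), seed = 1)
  expect_length(res$fold_accuracy, 3)           # one fold per subject
  expect_equal(res$subjects, 1:3)
  expect_equal(sum(res$confusion), length(ds))  # every trial tested once
  expect_equal(unname(rowSums(res$confusion)), rep(6L, 3))
  one <- generate_dataset(tiny_spec(n_subjects = 1, seed = 1))
  expect_error(loso_cv(one, tiny_config(), fast_ctrl()), "two subjects")
})

test_that("subject-dependent folds partition the shuffled data evenly", {
  ds <- generate_dataset(tiny_spec(seed = 2))      # 18 trials
  res <- subject_dependent_cv(ds, tiny_config(), fast_ctrl(),
                              n_folds = 5, seed = 3)
  expect_length(res$fold_accuracy, 5)
  sizes <- table(res$fold_assignment)
  expect_length(res$fold_assignment, length(ds))   # each trial in one fold
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(res$confusion), length(ds))
  expect_error(subject_dependent_cv(ds, tiny_config(), fast_ctrl(),
                                    n_folds = 50), "exceeds dataset size")
})

test_that("experiments are reproducible bit-for-bit from the master seed", {
  ds <- generate_dataset(tiny_spec(seed = 4))
  r1 <- loso_cv(ds, tiny_config(), fast_ctrl(), seed = 11)
  r2 <- loso_cv(ds, tiny_config(), fast_ctrl(), seed = 11)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$confusion, r2$confusion)
  # different master seeds give different trained parameters
  f1 <- sogpcn(ds, config = tiny_config(), control = fast_ctrl(), seed = 11)
  f2 <- sogpcn(ds, config = tiny_config(), control = fast_ctrl(), seed = 12)
  expect_false(identical(coef(f1), coef(f2)))
  expect_identical(coef(f1),
                   coef(sogpcn(ds, config = tiny_config(),
                               control = fast_ctrl(), seed = 11)))
})

test_that("band subsets rebuild the model with a reduced band axis", {
  ds <- generate_dataset(tiny_spec(seed = 5))
  sets <- canonical_band_sets()
  expect_named(sets, c("delta", "theta", "alpha", "beta", "gamma",
                       "theta_alpha_beta_gamma", "all_bands"))
  expect_length(sets$theta_alpha_beta_gamma, 4)
  expect_length(sets$all_bands, 5)

  res <- band_subset_run(ds, sets[c("delta", "all_bands")], tiny_config(),
                         fast_ctrl(), protocol = "holdout", seed = 1)
  expect_equal(res$delta$config$n_bands, 1)
  expect_equal(res$all_bands$config$n_bands, 5)
  expect_error(band_subset_run(ds, list(c("delta", "mu")), tiny_config(),
                               fast_ctrl()), "unknown band")
})

test_that("channel subsets reduce the montage and cap k", {
  sp <- tiny_spec(montage = seed_montage(12), planted_degree = 4L, seed = 31)
  ds <- generate_dataset(sp)
  cfg <- tiny_config()
  cfg$montage <- seed_montage(12); cfg$n_channels <- 12L; cfg$k <- 10L
  res <- channel_subset_run(ds, config = cfg, control = fast_ctrl(),
                            protocol = "holdout", seed = 1)
  # the 9-channel arrangement needs prefrontal electrodes absent here
  expect_named(res, c("4", "6", "12"))
  expect_equal(res$`4`$config$n_channels, 4)
  expect_lte(res$`4`$config$k, 4)
  expect_equal(res$`12`$config$k, 10)
})

test_that("the top-k sweep emits one result per requested k", {
  ds <- generate_dataset(tiny_spec(seed = 6))
  sw <- topk_sweep(ds, ks = c(2, 4), config = tiny_config(),
                   control = fast_ctrl(), protocol = "holdout", seed = 1)
  expect_equal(sw$table$k, c(2L, 4L))
  expect_length(sw$results, 2)
  expect_error(topk_sweep(ds, ks = c(0, 2), config = tiny_config()),
               "must lie in")
})

test_that("the ablation run covers the four documented variants", {
  ds <- generate_dataset(tiny_spec(seed = 7))
  ab <- ablation_run(ds, tiny_config(), fast_ctrl(), protocol = "holdout",
                     seed = 1)
  expect_named(ab, c("full", "-SOG", "-P3DCNN", "-PDPAtt"))
  for (r in ab) {
    expect_s3_class(r, "sogpcn_result")
    # the snapshot suffices to rebuild the variant
    cfg <- r$config; class(cfg) <- "sogpcn_config"
    expect_s3_class(build_model(cfg, seed = 1), "sogpcn_model")
  }
  expect_false(ab$`-SOG`$config$use_sog)
  expect_false(ab$`-P3DCNN`$config$use_conv)
  expect_false(ab$`-PDPAtt`$config$use_attention)
})

test_that("training reduces the loss and can overfit a tiny separable set", {
  sp <- tiny_spec(effect_size = 2, seed = 8)
  ds <- generate_dataset(sp)
  fit <- sogpcn(ds, config = tiny_config(),
                control = sogpcn_control(epochs = 200, patience = Inf,
                                         val_fraction = 0), seed = 2)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_equal(max(h$train_acc), 1)   # capacity check: fits the data
})

test_that("training defaults follow the published setup", {
  ctrl <- sogpcn_control()
  expect_equal(ctrl$lr, 0.001)
  expect_equal(ctrl$batch_size, 15L)
  expect_equal(ctrl$epochs, 200L)
  expect_equal(sogpcn_config()$dropout, 0.1)
})

test_that("fitted models predict in the original label coding", {
  ds <- generate_dataset(tiny_spec(seed = 9))
  # recode to the -1/0/1 convention used for negative/neutral/positive
  y <- vapply(ds, `[[`, 1L, "label") - 1L
  fit <- sogpcn(ds, y = y, config = tiny_config(), control = fast_ctrl(),
                seed = 1)
  expect_equal(fit$levels, c(-1L, 0L, 1L))
  pred <- predict(fit, ds[1:4])
  expect_true(all(pred %in% c(-1L, 0L, 1L)))
  pr <- predict(fit, ds[1:4], type = "prob")
  expect_rows_sum_to_one(pr)
  expect_identical(colnames(pr), c("-1", "0", "1"))
})
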