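# Cross-validation protocols, sweeps and ablation experiments.

#' Confusion matrix
#'
#' @param labels true class ids in `0:(C-1)`.
#' @param predictions predicted class ids in `0:(C-1)`.
#' @param C number of classes.
#' @return C x C integer matrix; entry (i, j) counts true class i
#'   predicted as class j.
#' @export
confusion <- function(labels, predictions, C) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (any(labels < 0 | labels >= C) || any(predictions < 0 | predictions >= C))
    stop("labels/predictions outside [0, ", C - 1, "]")
  cm <- matrix(0L, C, C,
               dimnames = list(true = 0:(C - 1), predicted = 0:(C - 1)))
  for (i in seq_along(labels))
    cm[labels[i] + 1L, predictions[i] + 1L] <- cm[labels[i] + 1L, predictions[i] + 1L] + 1L
  cm
}

.result <- function(protocol, fold_accuracy, cm, config, control, seed,
                    extra = list()) {
  out <- c(list(protocol = protocol,
                fold_accuracy = as.numeric(fold_accuracy),
                mean_accuracy = mean(fold_accuracy),
                sd_accuracy = if (length(fold_accuracy) > 1)
                  stats::sd(fold_accuracy) else 0,
                confusion = cm,
                label_coding = "internal classes 0:(C-1); SEED coding -1/0/1 maps to 0/1/2",
                config = unclass(config), control = unclass(control),
                seed = seed),
          extra)
  structure(out, class = "sogpcn_result")
}

#' @export
print.sogpcn_result <- function(x, ...) {
  cat(sprintf("<sogpcn_result> %s: mean accuracy %.2f%% (sd %.2f) over %d fold(s)\n",
              x$protocol, x$mean_accuracy, x$sd_accuracy,
              length(x$fold_accuracy)))
  invisible(x)
}

# train on one fold and score the held-out part (accuracy in %)
.run_fold <- function(train_trials, test_trials, config, control, seed) {
  fit <- sogpcn(train_trials, config = config, control = control, seed = seed)
  truth <- .trial_labels(test_trials)
  pred <- predict(fit, test_trials, type = "class")
  list(accuracy = 100 * mean(pred == truth),
       cm = confusion(truth, pred, config$n_classes))
}

#' Leave-one-subject-out cross-validation
#'
#' The subject-independent protocol: one fold per subject, that
#' subject's trials form the test set and all other subjects' trials the
#' training set (with a stratified slice held out internally for
#' early-stop monitoring).
#'
#' @param dataset list of [de_trial()] objects carrying subject ids.
#' @param config a [sogpcn_config()].
#' @param control a [sogpcn_control()].
#' @param seed master seed; per-fold seeds derive from it.
#' @param verbose print per-fold progress.
#' @return A `sogpcn_result` with per-fold accuracies (%), their
#'   mean/sd and the pooled confusion matrix.
#' @export
loso_cv <- function(dataset, config = sogpcn_config(),
                    control = sogpcn_control(), seed = 1L, verbose = FALSE) {
  subjects <- .trial_subjects(dataset)
  subj_ids <- sort(unique(subjects))
  if (length(subj_ids) < 2) stop("LOSO needs at least two subjects")
  acc <- numeric(length(subj_ids))
  cm <- matrix(0L, config$n_classes, config$n_classes,
               dimnames = list(true = 0:(config$n_classes - 1),
                               predicted = 0:(config$n_classes - 1)))
  for (fi in seq_along(subj_ids)) {
    test_ix <- which(subjects == subj_ids[fi])
    if (length(test_ix) == 0) stop("subject ", subj_ids[fi], " has no trials")
    r <- .run_fold(dataset[-test_ix], dataset[test_ix], config, control,
                   seed = seed * 1000L + fi)
    acc[fi] <- r$accuracy
    cm <- cm + r$cm
    if (verbose)
      message(sprintf("fold %2d (subject %s): %.1f%%", fi, subj_ids[fi],
                      r$accuracy))
  }
  .result("loso", acc, cm, config, control, seed,
          extra = list(subjects = subj_ids))
}

#' Subject-dependent cross-validation
#'
#' Pools all trials regardless of subject, shuffles them (seeded) and
#' divides them into `n_folds` parts of size differing by at most one;
#' each part serves once as the test set.
#'
#' @inheritParams loso_cv
#' @param n_folds number of folds (default 15).
#' @return A `sogpcn_result`.
#' @export
subject_dependent_cv <- function(dataset, config = sogpcn_config(),
                                 control = sogpcn_control(), n_folds = 15L,
                                 seed = 1L, verbose = FALSE) {
  n <- length(dataset)
  if (n_folds > n) stop("n_folds (", n_folds, ") exceeds dataset size (", n, ")")
  set.seed(seed)
  fold_of <- rep_len(seq_len(n_folds), n)[order(stats::runif(n))]
  acc <- numeric(n_folds)
  cm <- matrix(0L, config$n_classes, config$n_classes,
               dimnames = list(true = 0:(config$n_classes - 1),
                               predicted = 0:(config$n_classes - 1)))
  for (fi in seq_len(n_folds)) {
    test_ix <- which(fold_of == fi)
    r <- .run_fold(dataset[-test_ix], dataset[test_ix], config, control,
                   seed = seed * 1000L + fi)
    acc[fi] <- r$accuracy
    cm <- cm + r$cm
    if (verbose) message(sprintf("fold %2d: %.1f%%", fi, r$accuracy))
  }
  .result("subject_dependent", acc, cm, config, control, seed,
          extra = list(n_folds = n_folds, fold_assignment = fold_of))
}

# fast screening protocols used by the sweeps: one train/test split,
# either stratified by class (subject-dependent flavour) or holding out
# whole subjects (subject-independent flavour)
.holdout_run <- function(dataset, config, control, seed,
                         test_fraction = 0.25, by = c("trial", "subject")) {
  by <- match.arg(by)
  set.seed(seed)
  if (by == "trial") {
    test_ix <- .stratified_holdout(.trial_labels(dataset), test_fraction)
  } else {
    subj <- .trial_subjects(dataset)
    ids <- sort(unique(subj))
    held <- sample(ids, max(1L, round(length(ids) * test_fraction)))
    test_ix <- which(subj %in% held)
  }
  r <- .run_fold(dataset[-test_ix], dataset[test_ix], config, control,
                 seed = seed + 7L)
  .result(paste0("holdout_", by), r$accuracy, r$cm, config, control, seed)
}

.run_protocol <- function(dataset, config, control, protocol, seed, ...) {
  switch(protocol,
         loso = loso_cv(dataset, config, control, seed = seed),
         subject = subject_dependent_cv(dataset, config, control,
                                        seed = seed, ...),
         holdout = .holdout_run(dataset, config, control, seed = seed, ...),
         holdout_subject = .holdout_run(dataset, config, control,
                                        seed = seed, by = "subject", ...),
         stop("unknown protocol: ", protocol))
}

#' Canonical band configurations
#'
#' The seven configurations conventionally reported: each single band,
#' the four-band combination (theta, alpha, beta, gamma) and all five
#' bands.
#'
#' @return Named list of band-name vectors.
#' @export
canonical_band_sets <- function() {
  b <- seed_bands()$name
  sets <- c(as.list(b), list(b[2:5]), list(b))
  names(sets) <- c(b, "theta_alpha_beta_gamma", "all_bands")
  sets
}

.with_bands <- function(config, bands) {
  config$bands <- bands
  config$n_bands <- length(bands)
  config
}

.subset_bands <- function(trial, bands) {
  have <- dimnames(trial$de)[[2]]
  if (is.null(have)) stop("trials carry no band labels")
  missing <- setdiff(bands, have)
  if (length(missing) > 0)
    stop("unknown band(s): ", paste(missing, collapse = ", "))
  de_trial(trial$de[, match(bands, have), , drop = FALSE],
           label = trial$label, subject = trial$subject,
           length = trial$length)
}

#' Run the experiment over band subsets
#'
#' Rebuilds the model with the band axis reduced to each subset and runs
#' the chosen protocol.
#'
#' @inheritParams loso_cv
#' @param band_sets named list of band-name vectors (default the seven
#'   canonical configurations, [canonical_band_sets()]).
#' @param protocol `"holdout"` (fast single class-stratified split, the
#'   default), `"holdout_subject"` (single split holding out whole
#'   subjects — the fast subject-independent flavour), `"loso"` or
#'   `"subject"`.
#' @param ... passed to the underlying protocol runner (e.g.
#'   `test_fraction` for the holdout splits).
#' @return Named list of `sogpcn_result`, one per subset.
#' @export
band_subset_run <- function(dataset, band_sets = canonical_band_sets(),
                            config = sogpcn_config(),
                            control = sogpcn_control(),
                            protocol = "holdout", seed = 1L, ...) {
  stopifnot(length(band_sets) > 0)
  out <- lapply(band_sets, function(bs) {
    if (length(bs) == 0) stop("empty band subset")
    sub <- lapply(dataset, .subset_bands, bands = bs)
    .run_protocol(sub, .with_bands(config, bs), control, protocol, seed, ...)
  })
  out
}

#' Canonical electrode arrangements
#'
#' The nested electrode sets conventionally compared for emotion
#' recognition: 4, 6, 9 and 12 channels around the temporal lobes (the
#' 9-channel set adds prefrontal electrodes and therefore requires
#' 62-channel data).
#'
#' @return Named list of electrode-label vectors.
#' @export
canonical_channel_sets <- function() {
  list(`4` = c("FT7", "FT8", "T7", "T8"),
       `6` = c("FT7", "FT8", "T7", "T8", "TP7", "TP8"),
       `9` = c("FP1", "FPZ", "FP2", "FT7", "FT8", "T7", "T8", "TP7", "TP8"),
       `12` = seed_montage(12))
}

#' Run the experiment over electrode subsets
#'
#' Reduces every trial to each electrode subset, rebuilds the model with
#' the matching montage and runs the chosen protocol.
#'
#' @inheritParams band_subset_run
#' @param channel_sets named list of electrode-label vectors; defaults to
#'   the canonical arrangements that exist within the trials' montage.
#' @param ... passed to the underlying protocol runner (e.g.
#'   `test_fraction` for the holdout splits).
#' @return Named list of `sogpcn_result`, one per subset.
#' @export
channel_subset_run <- function(dataset, channel_sets = NULL,
                               config = sogpcn_config(),
                               control = sogpcn_control(),
                               protocol = "holdout", seed = 1L, ...) {
  if (is.null(channel_sets)) {
    have <- dimnames(dataset[[1]]$de)[[1]]
    channel_sets <- Filter(function(s) all(s %in% have),
                           canonical_channel_sets())
  }
  stopifnot(length(channel_sets) > 0)
  lapply(channel_sets, function(chs) {
    sub <- lapply(dataset, select_channels, names = chs)
    cfg <- config
    cfg$montage <- chs
    cfg$n_channels <- length(chs)
    if (cfg$k > cfg$n_channels) cfg$k <- cfg$n_channels
    .run_protocol(sub, cfg, control, protocol, seed, ...)
  })
}

#' Sweep the top-k sparsification parameter
#'
#' Reruns the chosen protocol for each requested retained-neighbor count
#' under shared seeds.
#'
#' @inheritParams band_subset_run
#' @param ks integer vector of k values, each in `[1, N]`.
#' @param ... passed to the underlying protocol runner (e.g.
#'   `test_fraction` for the holdout splits).
#' @return List with `table` (data frame of k and mean/sd accuracy) and
#'   `results` (per-k `sogpcn_result`).
#' @export
topk_sweep <- function(dataset, ks = c(6L, 8L, 10L, 12L),
                       config = sogpcn_config(), control = sogpcn_control(),
                       protocol = "holdout", seed = 1L, ...) {
  if (any(ks < 1 | ks > config$n_channels))
    stop("k values must lie in [1, ", config$n_channels, "]")
  results <- lapply(ks, function(k) {
    cfg <- config; cfg$k <- as.integer(k)
    .run_protocol(dataset, cfg, control, protocol, seed, ...)
  })
  names(results) <- paste0("k", ks)
  tab <- data.frame(k = as.integer(ks),
                    mean_accuracy = vapply(results, `[[`, 0, "mean_accuracy"),
                    sd_accuracy = vapply(results, `[[`, 0, "sd_accuracy"))
  list(table = tab, results = results)
}

#' Ablation experiment
#'
#' Runs the full model and the three single-module ablations (no
#' self-organizing graph, no pseudo-3D convolution stack, no attention)
#' under identical seeds and protocol.
#'
#' @inheritParams band_subset_run
#' @param ... passed to the underlying protocol runner (e.g.
#'   `test_fraction` for the holdout splits).
#' @return Named list of `sogpcn_result` for `full`, `-SOG`, `-P3DCNN`
#'   and `-PDPAtt`.
#' @export
ablation_run <- function(dataset, config = sogpcn_config(),
                         control = sogpcn_control(), protocol = "holdout",
                         seed = 1L, ...) {
  variants <- list(full = config,
                   `-SOG` = ablate(config, "SOG"),
                   `-P3DCNN` = ablate(config, "P3DCNN"),
                   `-PDPAtt` = ablate(config, "PDPAtt"))
  lapply(variants, function(cfg)
    .run_protocol(dataset, cfg, control, protocol, seed, ...))
}
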