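#' Stack DE trials into a batch tensor
#'
#' Pads every trial to the configured frame count, optionally selects the
#' configured electrode subset (when the trials carry channel names), and
#' stacks them into a batch x electrodes x bands x frames array.
#'
#' @param trials list of [de_trial()] objects (or bare 3-axis arrays).
#' @param config a [sogpcn_config()]; supplies the target montage and
#'   padded length.
#' @return A 4-axis numeric array.
#' @export
stack_trials <- function(trials, config = sogpcn_config()) {
  stopifnot(length(trials) > 0)
  arrs <- lapply(trials, function(tr) {
    if (is.array(tr)) tr <- de_trial(tr)
    have <- dimnames(tr$de)[[1]]
    if (!is.null(have) && !identical(have, config$montage)) {
      if (all(config$montage %in% have))
        tr <- select_channels(tr, config$montage)
      else if (dim(tr$de)[1] != config$n_channels)
        stop("trial montage does not match the configured one")
    }
    tr <- pad_time(tr, config$padded_length)
    if (dim(tr$de)[1] != config$n_channels)
      stop("trial has ", dim(tr$de)[1], " electrodes, config expects ",
           config$n_channels)
    if (dim(tr$de)[2] != config$n_bands)
      stop("trial has ", dim(tr$de)[2], " bands, config expects ",
           config$n_bands)
    tr$de
  })
  out <- array(0, c(length(arrs), dim(arrs[[1]])))
  for (i in seq_along(arrs)) out[i, , , ] <- arrs[[i]]
  out
}

.trial_labels <- function(trials) vapply(trials, `[[`, 0L, "label")
.trial_subjects <- function(trials) vapply(trials, `[[`, 0L, "subject")

# stratified index split: returns indices of the held-out part
.stratified_holdout <- function(y, fraction) {
  unlist(lapply(split(seq_along(y), y), function(ix) {
    n_take <- max(1L, round(length(ix) * fraction))
    if (length(ix) <= 1L) return(integer(0))
    sample(ix, min(n_take, length(ix) - 1L))
  }), use.names = FALSE)
}

#' Fit a self-organizing graph pseudo-3D convolutional network
#'
#' Trains the full network — per-band self-organizing graph convolution,
#' pseudo-3D spatiotemporal convolution with partial dot-product
#' attention, and a peephole LSTM with softmax head — on labelled
#' differential-entropy trials, minimizing cross-entropy with Adam and
#' early stopping on a held-out validation part.
#'
#' @param x training data: a list of [de_trial()] objects, or a
#'   batch x electrodes x bands x frames array.
#' @param y class labels (any integer coding or factor; taken from the
#'   trials when `x` is a trial list and `y` is `NULL`).
#' @param config a [sogpcn_config()].
#' @param control a [sogpcn_control()].
#' @param validation optional explicit validation set, a list with
#'   elements `x` and `y` in the same formats; when absent,
#'   `control$val_fraction` of the training data (stratified by class) is
#'   held out for early-stop monitoring.
#' @param seed master seed: parameter initialization, the validation
#'   split, minibatch shuffling and dropout all derive from it.
#' @return An object of class `sogpcn` with components `model` (trained
#'   parameters + config), `history` (per-epoch losses and accuracies),
#'   `levels` (original label coding, in the order mapped to classes
#'   `0:(C-1)`), `best_epoch` and `call`. Methods: [predict.sogpcn()],
#'   `print`, `summary`, `coef`, `plot`.
#' @examples
#' \donttest{
#' spec <- synthetic_spec(n_subjects = 2, trials_per_subject = 6,
#'                        length_range = c(20, 30))
#' ds <- generate_dataset(spec)
#' cfg <- sogpcn_config(padded_length = 30, graph_out = 16, embed_dim = 8,
#'                      lstm_hidden = 8)
#' fit <- sogpcn(ds, config = cfg, control = sogpcn_control(epochs = 2))
#' predict(fit, ds[1:2])
#' }
#' @export
sogpcn <- function(x, y = NULL, config = sogpcn_config(),
                   control = sogpcn_control(), validation = NULL,
                   seed = 1L) {
  if (is.list(x) && !is.array(x)) {
    if (is.null(y)) y <- .trial_labels(x)
    x <- stack_trials(x, config)
  }
  if (length(dim(x)) != 4L) stop("x must be a 4-axis batch tensor")
  if (length(y) != dim(x)[1]) stop("y length does not match batch size")
  lv <- sort(unique(as.vector(if (is.factor(y)) levels(y)[y] else y)))
  if (length(lv) > config$n_classes)
    stop("more label values (", length(lv), ") than configured classes")
  y0 <- match(if (is.factor(y)) levels(y)[y] else y, lv) - 1L

  model <- build_model(config, seed = seed)
  set.seed(seed + 1L)
  if (!is.null(validation)) {
    xv <- validation$x
    if (is.list(xv) && !is.array(xv)) {
      if (is.null(validation$y)) validation$y <- .trial_labels(xv)
      xv <- stack_trials(xv, config)
    }
    yv0 <- match(validation$y, lv) - 1L
    if (anyNA(yv0)) stop("validation labels outside the training coding")
    xt <- x; yt <- y0
  } else if (control$val_fraction > 0 && dim(x)[1] >= 10) {
    hold <- .stratified_holdout(y0, control$val_fraction)
    xv <- x[hold, , , , drop = FALSE]; yv0 <- y0[hold]
    xt <- x[-hold, , , , drop = FALSE]; yt <- y0[-hold]
  } else {
    xv <- NULL; yv0 <- NULL; xt <- x; yt <- y0
  }

  trained <- .train_network(model, xt, yt, xv, yv0, control,
                            seed = seed + 2L)
  structure(list(model = trained$model, history = trained$history,
                 best_epoch = trained$best_epoch,
                 levels = lv, config = config, control = control,
                 seed = as.integer(seed), call = match.call()),
            class = "sogpcn")
}

#' Predict emotion classes or probabilities
#'
#' @param object a fitted [sogpcn()] model.
#' @param newdata list of [de_trial()] objects or a 4-axis batch tensor.
#' @param type `"class"` for labels in the original coding, `"prob"` for
#'   the batch x C probability matrix.
#' @param ... unused.
#' @return Label vector or probability matrix.
#' @export
predict.sogpcn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.array(newdata))
    newdata <- stack_trials(newdata, object$config)
  if (length(dim(newdata)) == 3L) dim(newdata) <- c(1L, dim(newdata))
  probs <- .predict_probs(object$model$params, newdata, object$config)
  colnames(probs) <- as.character(object$levels)
  if (type == "prob") return(probs)
  object$levels[max.col(probs, ties.method = "first")]
}

#' @export
print.sogpcn <- function(x, ...) {
  cat("Self-organizing graph pseudo-3D convolutional network\n\n")
  cat("Call: "); print(x$call)
  cat(sprintf("\n%d trainable parameters; classes: %s\n",
              n_parameters(x), paste(x$levels, collapse = ", ")))
  h <- x$history
  if (nrow(h) > 0)
    cat(sprintf("Trained %d epochs (best at %d): train acc %.1f%%, val acc %.1f%%\n",
                nrow(h), x$best_epoch, 100 * h$train_acc[nrow(h)],
                100 * h$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.sogpcn <- function(object, ...) {
  print(object)
  cat("\nConfiguration:\n")
  print(object$config)
  invisible(object)
}

#' @export
coef.sogpcn <- function(object, ...) object$model$params

#' @export
plot.sogpcn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}
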