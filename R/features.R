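#' Construct a raw EEG trial
#'
#' @param signal electrodes x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names ordered electrode labels, one per signal row.
#' @return An object of class `raw_eeg_trial`.
#' @export
raw_eeg_trial <- function(signal, fs, channel_names) {
  signal <- as.matrix(signal)
  if (!all(is.finite(signal))) stop("raw signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(channel_names) != nrow(signal))
    stop("channel_names length (", length(channel_names),
         ") does not match signal rows (", nrow(signal), ")")
  structure(list(signal = signal, fs = fs,
                 channel_names = as.character(channel_names)),
            class = "raw_eeg_trial")
}

#' Construct a differential-entropy feature trial
#'
#' A trial is an electrodes x bands x frames array of differential-entropy
#' (DE) values (nats), one value per electrode, frequency band and 1-second
#' frame, plus its class label and subject id.
#'
#' @param de numeric 3-axis array, electrodes x bands x frames.
#' @param label integer class id in `0:(C-1)` (0 = negative, 1 = neutral,
#'   2 = positive under the default coding).
#' @param subject integer subject id.
#' @param length original (unpadded) number of frames; defaults to the
#'   third extent of `de`.
#' @param channels optional electrode labels (defaults to dimnames of `de`).
#' @param bands optional band labels.
#' @return An object of class `de_trial`.
#' @export
de_trial <- function(de, label = 0L, subject = 1L, length = dim(de)[3],
                     channels = NULL, bands = NULL) {
  if (!is.array(de) || base::length(dim(de)) != 3L)
    stop("de must be an electrodes x bands x frames array")
  if (!all(is.finite(de))) stop("de contains non-finite values")
  if (!is.double(de)) storage.mode(de) <- "double"
  if (length > dim(de)[3]) stop("length exceeds frame count")
  dn <- dimnames(de)
  if (is.null(channels)) channels <- if (!is.null(dn)) dn[[1]] else NULL
  if (is.null(bands)) bands <- if (!is.null(dn)) dn[[2]] else NULL
  dimnames(de) <- list(channels, bands, NULL)
  structure(list(de = de, label = as.integer(label),
                 subject = as.integer(subject), length = as.integer(length)),
            class = "de_trial")
}

#' @export
print.de_trial <- function(x, ...) {
  d <- dim(x$de)
  cat(sprintf("<de_trial> %d electrodes x %d bands x %d frames (length %d), label %d, subject %d\n",
              d[1], d[2], d[3], x$length, x$label, x$subject))
  invisible(x)
}

#' Differential entropy of multichannel EEG by band and 1-second frame
#'
#' Splits the signal into non-overlapping windows of `window_s` seconds,
#' applies a Hanning window, computes a 512-point short-time Fourier
#' transform, and for each frequency band takes the Gaussian-assumption
#' differential entropy of the band-limited signal,
#' \deqn{DE = \tfrac{1}{2}\log(2\pi e \hat\sigma^2),}
#' where \eqn{\hat\sigma^2} is the band power estimated from the windowed
#' periodogram (sum of squared STFT magnitudes over the band's frequency
#' bins, normalized so that for white noise the full-band estimate recovers
#' the signal variance).
#'
#' @param trial a [raw_eeg_trial()].
#' @param bands band definition table as from [seed_bands()].
#' @param window_s window length in seconds (default 1, non-overlapping).
#' @param nfft FFT length (default 512; the window is zero-padded to it).
#' @return A [de_trial()] with one DE value per electrode x band x frame.
#' @examples
#' tr <- raw_eeg_trial(matrix(rnorm(200 * 10), 1), fs = 200, channel_names = "CZ")
#' compute_de(tr, seed_bands())
#' @export
compute_de <- function(trial, bands = seed_bands(), window_s = 1, nfft = 512L) {
  stopifnot(inherits(trial, "raw_eeg_trial"))
  fs <- trial$fs
  win_len <- as.integer(round(fs * window_s))
  if (ncol(trial$signal) < win_len)
    stop("trial shorter than one analysis window")
  if (any(bands$hi > fs / 2))
    stop("band upper bound exceeds the Nyquist frequency (", fs / 2, " Hz)")
  if (win_len > nfft)
    stop("analysis window longer than the FFT length")
  n_frames <- floor(ncol(trial$signal) / win_len)
  n_ch <- nrow(trial$signal)
  n_bands <- nrow(bands)

  w <- signal::hanning(win_len)
  wnorm <- nfft * sum(w^2)
  freqs <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  # one-sided periodogram: double all bins except DC and Nyquist
  two_sided <- rep(2, length(freqs))
  two_sided[1] <- 1
  if (nfft %% 2 == 0) two_sided[length(freqs)] <- 1
  band_bins <- lapply(seq_len(n_bands), function(b) {
    idx <- which(freqs >= bands$lo[b] & freqs <= bands$hi[b])
    if (length(idx) == 0L)
      stop("band ", bands$name[b], " contains no frequency bins at fs = ", fs)
    idx
  })

  de <- array(NA_real_, c(n_ch, n_bands, n_frames),
              dimnames = list(trial$channel_names, bands$name, NULL))
  for (t in seq_len(n_frames)) {
    seg <- trial$signal[, ((t - 1) * win_len + 1):(t * win_len), drop = FALSE]
    seg <- sweep(seg, 2, w, `*`)
    padded <- matrix(0, n_ch, nfft)
    padded[, seq_len(win_len)] <- seg
    spec <- Mod(t(stats::mvfft(t(padded))))^2  # n_ch x nfft
    spec <- spec[, seq_along(freqs), drop = FALSE]
    spec <- sweep(spec, 2, two_sided, `*`)
    for (b in seq_len(n_bands)) {
      pw <- rowSums(spec[, band_bins[[b]], drop = FALSE]) / wnorm
      if (any(pw <= 0))
        stop("zero band power in frame ", t, ", band ", bands$name[b],
             ": differential entropy undefined")
      de[, b, t] <- 0.5 * log(2 * pi * exp(1) * pw)
    }
  }
  de_trial(de, channels = trial$channel_names, bands = bands$name)
}

#' Zero-pad a DE trial along the frame axis
#'
#' Trials whose stimulus was shorter than the longest clip are filled with
#' trailing all-zero frames up to `target_T` (265 for SEED); the original
#' unpadded length is preserved in the `length` field.
#'
#' @param trial a [de_trial()].
#' @param target_T frame count after padding.
#' @return A [de_trial()] with `dim(de)[3] == target_T`.
#' @export
pad_time <- function(trial, target_T = 265L) {
  stopifnot(inherits(trial, "de_trial"))
  d <- dim(trial$de)
  if (d[3] > target_T)
    stop("trial has ", d[3], " frames, more than target length ", target_T)
  if (d[3] == target_T) return(trial)
  out <- array(0, c(d[1], d[2], target_T), dimnames = dimnames(trial$de)[c(1, 2)])
  out[, , seq_len(d[3])] <- trial$de
  de_trial(out, label = trial$label, subject = trial$subject,
           length = trial$length)
}

#' Select and reorder electrodes of a DE trial
#'
#' @param trial a [de_trial()] whose electrode axis carries channel names.
#' @param names ordered electrode labels to keep.
#' @return A [de_trial()] with the electrode axis reduced and reordered to
#'   `names`; values are copied unchanged from the source rows.
#' @export
select_channels <- function(trial, names = seed_montage(12)) {
  stopifnot(inherits(trial, "de_trial"))
  have <- dimnames(trial$de)[[1]]
  if (is.null(have)) stop("trial carries no electrode labels")
  missing <- setdiff(names, have)
  if (length(missing) > 0)
    stop("unknown electrode name(s): ", paste(missing, collapse = ", "))
  de_trial(trial$de[match(names, have), , , drop = FALSE],
           label = trial$label, subject = trial$subject,
           length = trial$length)
}
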