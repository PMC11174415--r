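#' Standard EEG frequency bands
#'
#' The five-band decomposition conventionally used for differential-entropy
#' EEG features: delta (1-3 Hz), theta (4-7 Hz), alpha (8-13 Hz),
#' beta (14-30 Hz) and gamma (31-50 Hz).
#'
#' @return A data frame with columns `name`, `lo` and `hi` (Hz), one row
#'   per band.
#' @examples
#' seed_bands()
#' @export
seed_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(1, 4, 8, 14, 31),
    hi   = c(3, 7, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' Construct a band definition table
#'
#' @param name character vector of band labels.
#' @param lo,hi numeric vectors of lower/upper frequency bounds (Hz).
#' @return A data frame with columns `name`, `lo`, `hi`.
#' @export
band_definition <- function(name, lo, hi) {
  stopifnot(length(name) == length(lo), length(lo) == length(hi))
  if (any(lo <= 0) || any(hi <= lo))
    stop("band bounds must satisfy 0 < lo < hi")
  data.frame(name = as.character(name), lo = as.numeric(lo),
             hi = as.numeric(hi), stringsAsFactors = FALSE)
}

# 62-channel ESI NeuroScan montage used by the SEED recordings
.montage62 <- c(
  "FP1", "FPZ", "FP2", "AF3", "AF4",
  "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
  "CB1", "O1", "OZ", "O2", "CB2"
)

# 12-channel temporal-lobe subset known to carry most emotion information
.montage12 <- c("FT7", "T7", "TP7", "P7", "C5", "CP5",
                "FT8", "T8", "TP8", "P8", "C6", "CP6")

#' Electrode montages
#'
#' Named electrode sets in the 10-20 system: the full 62-channel montage of
#' the SEED recordings and the 12-channel bilateral temporal-lobe subset
#' (FT7, T7, TP7, P7, C5, CP5, FT8, T8, TP8, P8, C6, CP6) reported to carry
#' most of the emotion-discriminative signal.
#'
#' @param n either `12` or `62`.
#' @return Character vector of ordered electrode labels.
#' @examples
#' seed_montage(12)
#' @export
seed_montage <- function(n = 12) {
  n <- as.integer(n)
  if (identical(n, 12L)) return(.montage12)
  if (identical(n, 62L)) return(.montage62)
  stop("montage must be 12 or 62 channels")
}
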