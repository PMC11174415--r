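#' Write DE feature trials to the package fixture format
#'
#' One JSON file per session: electrode and band labels plus, per trial,
#' the label, subject id, unpadded length, axis extents and the DE tensor
#' flattened in column-major order with axes electrodes x bands x frames.
#'
#' @param trials list of [de_trial()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features_file <- function(trials, path) {
  stopifnot(length(trials) > 0, all(vapply(trials, inherits, TRUE, "de_trial")))
  first <- trials[[1]]
  payload <- list(
    format = "sogpcn-de-features",
    version = 1L,
    axis_order = "channels_bands_frames",
    channels = dimnames(first$de)[[1]],
    bands = dimnames(first$de)[[2]],
    trials = lapply(trials, function(tr) {
      list(label = tr$label, subject = tr$subject, length = tr$length,
           dim = dim(tr$de), de = as.numeric(tr$de))
    })
  )
  # I(17) significant digits: doubles round-trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# normalize an on-disk trial array to electrodes x bands x frames
.normalize_axes <- function(a, axis_order) {
  perm <- switch(axis_order,
                 channels_bands_frames = c(1, 2, 3),
                 channels_frames_bands = c(1, 3, 2),
                 bands_channels_frames = c(2, 1, 3),
                 stop("unknown axis order: ", axis_order))
  if (identical(perm, c(1, 2, 3))) a else aperm(a, order(perm))
}

#' Read DE feature trials
#'
#' Reads the package's JSON fixture format natively. For MATLAB `.mat`
#' feature files laid out like the SEED "Extracted_Features" folder
#' (per-trial arrays named `<feature_key><trial>` with axes
#' channels x frames x bands) the file is converted through the system
#' `python` interpreter's `scipy.io` reader when one is available.
#' Whatever the on-disk layout, the returned trials always carry axes
#' electrodes x bands x frames.
#'
#' @param path path to a feature file (`.json` fixture or `.mat`).
#' @param feature_key for `.mat` files, the variable-name prefix of the
#'   per-trial DE arrays; SEED ships `de_LDS` (default) and `de_movingAve`.
#' @param labels for `.mat` files, an integer vector of per-trial class
#'   labels (SEED stores them in a separate `label.mat`).
#' @param subject subject id to assign when the file does not record one.
#' @return List of [de_trial()] objects.
#' @export
read_features_file <- function(path, feature_key = "de_LDS",
                               labels = NULL, subject = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mat")
    return(.read_mat_features(path, feature_key, labels, subject))

  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("malformed feature file: ",
                                               conditionMessage(e)))
  if (is.null(payload$trials) || length(payload$trials) == 0)
    stop("feature file contains no trials: ", path)
  axis_order <- payload$axis_order %||% "channels_bands_frames"
  trs <- payload$trials
  # jsonlite may simplify a homogeneous list to a data frame
  n <- if (is.data.frame(trs)) nrow(trs) else length(trs)
  lapply(seq_len(n), function(i) {
    rec <- if (is.data.frame(trs)) lapply(trs, function(col) {
      if (is.list(col)) col[[i]] else col[i]
    }) else trs[[i]]
    d <- as.integer(unlist(rec$dim))
    vals <- as.numeric(unlist(rec$de))
    if (length(d) != 3L || length(vals) != prod(d))
      stop("trial ", i, " has malformed shape (dim ",
           paste(d, collapse = "x"), ", ", length(vals), " values)")
    a <- .normalize_axes(array(vals, d), axis_order)
    dimnames(a) <- list(payload$channels, payload$bands, NULL)
    de_trial(a, label = rec$label %||% 0L,
             subject = rec$subject %||% subject,
             length = rec$length %||% dim(a)[3])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_mat_features <- function(path, feature_key, labels, subject) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop(".mat feature files need a python interpreter with scipy on the PATH; ",
         "convert the file to the JSON fixture format instead")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  script <- sprintf(
    "import json, sys\nimport scipy.io as sio\nimport numpy as np\nm = sio.loadmat(%s)\nkeys = sorted([k for k in m if k.startswith(%s)], key=lambda k: int(k[len(%s):]))\nout = []\nfor k in keys:\n    a = np.asarray(m[k], dtype=float)\n    out.append({'dim': list(a.shape), 'de': a.flatten(order='F').tolist()})\njson.dump(out, open(%s, 'w'))\n",
    deparse(path), deparse(feature_key), deparse(feature_key), deparse(tmp))
  status <- system2(py, c("-c", shQuote(script)), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tmp))
    stop("failed to read ", path, " via python/scipy (missing key '",
         feature_key, "'?)")
  recs <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  if (length(recs) == 0) stop("no variables with prefix '", feature_key,
                              "' in ", path)
  lapply(seq_along(recs), function(i) {
    d <- as.integer(unlist(recs[[i]]$dim))
    a <- array(as.numeric(unlist(recs[[i]]$de)), d)
    a <- .normalize_axes(a, "channels_frames_bands")  # SEED layout
    lab <- if (!is.null(labels)) labels[i] else 0L
    de_trial(a, label = lab, subject = subject)
  })
}

#' Write an experiment result to JSON
#'
#' @param result a `sogpcn_result` as returned by [loso_cv()] and friends.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  out <- unclass(result)
  out$confusion <- list(matrix = unname(as.matrix(result$confusion)),
                        classes = colnames(result$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read an experiment result written by [write_result_json()]
#'
#' @param path JSON path.
#' @return A `sogpcn_result` object.
#' @export
read_result_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- raw$confusion$matrix
  cls <- raw$confusion$classes
  raw$confusion <- matrix(as.numeric(cm), nrow(cm), ncol(cm),
                          dimnames = list(true = cls, predicted = cls))
  raw$fold_accuracy <- as.numeric(raw$fold_accuracy)
  structure(raw, class = "sogpcn_result")
}

#' Write per-fold accuracies (and the confusion matrix) as CSV
#'
#' @param result a `sogpcn_result`.
#' @param path CSV path for the fold table; the confusion matrix goes to
#'   `<path base>_confusion.csv`.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  utils::write.csv(data.frame(fold = seq_along(result$fold_accuracy),
                              accuracy = result$fold_accuracy),
                   path, row.names = FALSE)
  cpath <- paste0(tools::file_path_sans_ext(path), "_confusion.csv")
  utils::write.csv(as.data.frame(result$confusion), cpath, row.names = TRUE)
  invisible(path)
}
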