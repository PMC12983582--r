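#' Multichannel EEG recording container
#'
#' A lightweight container for a channels-by-samples voltage matrix together
#' with its sampling rate and channel labels. All pipeline stages accept this
#' object as their entry point.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique channel names; defaults to
#'   `"ch01"`, `"ch02"`, ...
#'
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `fs` and `labels`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), 2, 250), fs = 250)
#' rec
eeg_recording <- function(data, fs, labels = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.")
  }
  if (any(!is.finite(data))) abort("`data` contains non-finite samples.")
  check_scalar(fs, "fs", lower = .Machine$double.eps)
  n_ch <- nrow(data)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(n_ch))
  labels <- as.character(labels)
  if (length(labels) != n_ch) abort("`labels` length must equal the number of channels.")
  if (anyDuplicated(labels)) abort("`labels` must be unique.")
  structure(list(data = data, fs = fs, labels = labels), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("channels:", paste(head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Tidy a recording into long format
#'
#' @param x An [eeg_recording()].
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time` (s) and `voltage` (uV).
#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble(
    channel = rep(x$labels, each = n),
    time = rep(seq_len(n) - 1, nrow(x$data)) / x$fs,
    voltage = as.vector(t(x$data))
  )
}

#' Read / write a recording as a delimited matrix plus JSON sidecar
#'
#' The interchange format is a tab-separated samples-by-channels matrix (one
#' column per channel, no header) next to a JSON sidecar holding the sampling
#' rate and channel labels.
#'
#' @param path Path of the data matrix (TSV).
#' @param sidecar Path of the JSON sidecar; defaults to `path` with a
#'   `.json` extension appended.
#' @return [read_recording()] returns an [eeg_recording()];
#'   [write_recording()] returns `path` invisibly.
#' @export
read_recording <- function(path, sidecar = NULL) {
  if (!file.exists(path)) abort(sprintf("Recording file not found: %s", path))
  sidecar <- sidecar %||% paste0(path, ".json")
  if (!file.exists(sidecar)) abort(sprintf("Sidecar not found: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) abort("Sidecar is missing the `fs` field.")
  m <- tryCatch(
    unname(as.matrix(utils::read.table(path, sep = "\t", header = FALSE))),
    error = function(e) abort(sprintf("Failed to parse recording matrix: %s", conditionMessage(e)))
  )
  suppressWarnings(storage.mode(m) <- "double")
  if (any(!is.finite(m))) abort("Failed to parse recording matrix: non-numeric entries.")
  labels <- meta$labels %||% sprintf("ch%02d", ncol(m))
  if (length(labels) != ncol(m)) {
    abort(sprintf(
      "Sidecar lists %d labels but the matrix has %d channels.",
      length(labels), ncol(m)
    ))
  }
  eeg_recording(t(m), fs = meta$fs, labels = labels)
}

#' @param rec An [eeg_recording()] to write.
#' @rdname read_recording
#' @export
write_recording <- function(rec, path, sidecar = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  sidecar <- sidecar %||% paste0(path, ".json")
  utils::write.table(t(rec$data), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, labels = rec$labels, units = "uV"),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
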