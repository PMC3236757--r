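#' Multichannel recording container
#'
#' Wraps a channels x samples numeric matrix together with its sampling rate,
#' channel labels and a reference tag. All pipeline stages operate on this
#' container or on the epoched variants produced by [extract_epochs()].
#'
#' @param data Numeric matrix, channels x samples. Must be free of NA/NaN/Inf.
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of unique channel names (defaults to row
#'   names of `data`, else `ch1..chN`).
#' @param reference Free-text reference tag (e.g. `"A2"`, `"linked-earlobes"`).
#' @return An object of class `eeg_recording` with elements `data`, `fs`,
#'   `labels`, `reference`.
#' @export
recording <- function(data, fs, labels = NULL, reference = "A2") {
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) < 1L || nrow(data) < 1L) {
    stop("invalid-input: data must be a non-empty numeric matrix (channels x samples)")
  }
  if (any(!is.finite(data))) stop("invalid-input: data contains NA/NaN/Inf")
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.null(labels)) {
    labels <- rownames(data)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(labels) != nrow(data)) {
    stop("invalid-input: length(labels) must equal nrow(data)")
  }
  if (anyDuplicated(labels)) stop("invalid-input: channel labels must be unique")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (ref: %s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$reference))
  invisible(x)
}

#' Epoched recording container
#'
#' @param data 3-d numeric array, epochs x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, is.numeric(fs), fs > 0)
  if (any(!is.finite(data)) && length(data) > 0L) {
    stop("invalid-input: epoch data contains NA/NaN/Inf")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(data)[2L]))
  stopifnot(length(labels) == dim(data)[2L])
  structure(list(data = data, fs = fs, labels = labels,
                 epoch_len = dim(data)[3L] / fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  invisible(x)
}

#' Band-limited epoch series
#'
#' Result of [morlet_band_series()]: same epochs x channels x samples layout as
#' the source [epoch_set()], restricted to one frequency band.
#'
#' @param data 3-d array, epochs x channels x samples.
#' @param band An [band()] object.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels.
#' @return Object of class `band_series`.
#' @export
band_series <- function(data, band, fs, labels = NULL) {
  stopifnot(inherits(band, "eeg_band"))
  out <- epoch_set(data, fs, labels)
  out$band <- band
  class(out) <- c("band_series", "epoch_set")
  out
}

#' @export
print.band_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<band_series> %s [%.2f, %.2f) Hz: %d epochs x %d channels x %d samples\n",
              x$band$name, x$band$low, x$band$high, d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Write / read a recording as a delimited text matrix
#'
#' Layout: rows are samples, columns are channels, with a header row of channel
#' labels. The sampling rate and reference are carried in a `# fs=... ref=...`
#' comment line, first in the file.
#'
#' @param rec An [recording()] object.
#' @param path Output file path.
#' @return `write_recording` returns `path` invisibly; `read_recording` returns
#'   an `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  writeLines(sprintf("# fs=%.10g ref=%s", rec$fs, rec$reference), con)
  close(con)
  data.table::fwrite(data.table::as.data.table(t(rec$data)), path,
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("^# fs=([0-9.eE+-]+) ref=(.*)$", hdr))[[1L]]
  if (length(m) != 3L) stop("invalid-input: missing '# fs=... ref=...' header in ", path)
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  recording(t(as.matrix(dt)), fs = as.numeric(m[2L]),
            labels = colnames(dt), reference = m[3L])
}
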