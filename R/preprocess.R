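#' Re-reference to digitally linked earlobes
#'
#' Converts an A2-referenced recording to the linked-earlobe reference: with A2
#' as the (implicit, zero) recording reference and A1 recorded as a separate
#' channel, each scalp channel `x` becomes `x - A1/2`, which equals referencing
#' to `(A1 + A2)/2`. The A1 channel is dropped from the output.
#'
#' @param rec An [recording()] currently referenced to A2.
#' @param a1_label Name of the recorded A1 channel.
#' @return Re-referenced `eeg_recording` without the A1 channel; `reference`
#'   tag set to `"linked-earlobes"`.
#' @export
rereference_linked_earlobes <- function(rec, a1_label = "A1") {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- match(a1_label, rec$labels)
  if (is.na(idx)) {
    stop("channel-not-found: no channel labelled '", a1_label, "'")
  }
  a1 <- rec$data[idx, , drop = TRUE]
  scalp <- rec$data[-idx, , drop = FALSE]
  out <- sweep(scalp, 2L, a1 / 2, "-")
  recording(out, rec$fs, labels = rec$labels[-idx],
            reference = "linked-earlobes")
}

#' Remove the linear trend from every epoch and channel
#'
#' Per epoch and channel, subtracts the least-squares line fitted over the
#' whole epoch, leaving zero mean and zero least-squares slope.
#'
#' @param epochs An [epoch_set()] (or a plain channels x samples matrix, which
#'   is treated as a single epoch and returned as a matrix).
#' @return Detrended object of the same type.
#' @export
detrend_linear <- function(epochs) {
  detrend_mat <- function(x) {
    # x: channels x samples; closed-form least squares against centred time
    s <- ncol(x)
    if (s < 2L) stop("invalid-input: need at least 2 samples to detrend")
    tc <- seq_len(s) - (s + 1) / 2
    slope <- (x %*% tc) / sum(tc^2)
    x - rowMeans(x) - tcrossprod(drop(slope), tc)
  }
  if (is.matrix(epochs)) return(detrend_mat(epochs))
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  out <- epochs$data
  for (e in seq_len(d[1L])) {
    out[e, , ] <- detrend_mat(matrix(epochs$data[e, , ], nrow = d[2L]))
  }
  epoch_set(out, epochs$fs, epochs$labels)
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (8th-order Butterworth at 80% of
#' the target Nyquist, run forwards and backwards) and keeps every
#' `factor`-th sample. `factor = 1` is the identity.
#'
#' @param rec An [recording()].
#' @param factor Integer decimation factor, >= 1.
#' @return Downsampled `eeg_recording` with `fs/factor` sampling rate and
#'   `floor(samples/factor)` samples.
#' @export
downsample <- function(rec, factor) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop("invalid-input: factor must be an integer >= 1")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  bf <- signal::butter(4, 0.8 / factor)   # cutoff 0.8 * (fs/2) / factor
  keep <- seq.int(1L, ncol(rec$data), by = factor)
  out <- t(apply(rec$data, 1L, function(x) {
    signal::filtfilt(bf, x)[keep]
  }))
  recording(out, rec$fs / factor, labels = rec$labels,
            reference = rec$reference)
}

#' Cut consecutive non-overlapping epochs from a recording
#'
#' Returns the first `n_epochs` windows of `epoch_len` seconds, in temporal
#' order.
#'
#' @param rec An [recording()].
#' @param n_epochs Number of epochs (0 yields a valid empty [epoch_set()]).
#' @param epoch_len Epoch length in seconds; `epoch_len * fs` must be a whole
#'   number of samples.
#' @return An [epoch_set()], `n_epochs` x channels x `epoch_len * fs`.
#' @export
extract_epochs <- function(rec, n_epochs, epoch_len) {
  stopifnot(inherits(rec, "eeg_recording"),
            n_epochs >= 0, n_epochs == round(n_epochs), epoch_len > 0)
  ns <- epoch_len * rec$fs
  if (abs(ns - round(ns)) > 1e-8) {
    stop("invalid-input: epoch_len * fs must be an integer sample count")
  }
  ns <- as.integer(round(ns))
  n_epochs <- as.integer(n_epochs)
  need <- n_epochs * ns
  if (ncol(rec$data) < need) {
    stop(sprintf("insufficient-data: need %d samples for %d x %gs epochs, have %d",
                 need, n_epochs, epoch_len, ncol(rec$data)))
  }
  out <- array(0, dim = c(n_epochs, nrow(rec$data), ns))
  for (e in seq_len(n_epochs)) {
    out[e, , ] <- rec$data[, ((e - 1L) * ns + 1L):(e * ns), drop = FALSE]
  }
  epoch_set(out, rec$fs, rec$labels)
}
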