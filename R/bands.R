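#' Frequency band definition
#'
#' A half-open frequency interval `[low, high)` in Hz with a name. The three
#' canonical analysis bands are returned by [eeg_bands()].
#'
#' @param name Band name, e.g. `"alpha"`.
#' @param low,high Band edges in Hz; `0 < low < high` is required.
#' @return An object of class `eeg_band`.
#' @export
#' @examples
#' band("beta", 15.05, 31.25)
band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (!(low > 0 && high > low)) {
    stop("invalid-band: need 0 < low < high (got [", low, ", ", high, "))")
  }
  structure(list(name = name, low = low, high = high), class = "eeg_band")
}

#' Canonical EEG analysis bands
#'
#' Alpha, beta and gamma band edges used throughout the analysis. The edges are
#' stored as exact constants (they partition `[7.97, 50.78)` Hz with
#' `alpha$high == beta$low` and `beta$high == gamma$low`), not derived from a
#' wavelet scale formula.
#'
#' @return Named list of [band()] objects: `alpha` (7.97--15.05 Hz), `beta`
#'   (15.05--31.25 Hz), `gamma` (31.25--50.78 Hz).
#' @export
eeg_bands <- function() {
  list(
    alpha = band("alpha", 7.97, 15.05),
    beta  = band("beta", 15.05, 31.25),
    gamma = band("gamma", 31.25, 50.78)
  )
}

#' @export
print.eeg_band <- function(x, ...) {
  cat(sprintf("<eeg_band> %s: [%.2f, %.2f) Hz\n", x$name, x$low, x$high))
  invisible(x)
}
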