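# Plug-in mutual information on equiprobable (rank-based) marginal bins.
# Rank binning makes the estimator invariant to monotone rescaling of either
# series and gives uniform marginals by construction; ties are broken by
# first-occurrence order so results are deterministic.

equiprobable_bins <- function(x, n_bins) {
  n <- length(x)
  as.integer(ceiling(rank(x, ties.method = "first") * n_bins / n))
}

mi_from_bins <- function(bx, by, n_bins) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * n_bins + by, nbins = n_bins * n_bins) / n
  px <- tabulate(bx, nbins = n_bins) / n
  py <- tabulate(by, nbins = n_bins) / n
  pij <- joint[joint > 0]
  # joint is laid out with the y bin varying fastest, so the matching product
  # of marginals at position (bx-1)*nb + by is outer(py, px)[by, bx]
  outer_p <- as.vector(outer(py, px))[joint > 0]
  max(0, sum(pij * log2(pij / outer_p)))
}

#' Mutual information between two series (bits)
#'
#' Plug-in estimate of the mutual information of the joint histogram over
#' equiprobable rank-based marginal bins. `MI(x, y) == MI(y, x)` and the
#' result is non-negative. For a continuous series with no ties and a length
#' divisible by `n_bins`, `mutual_information(x, x)` equals `log2(n_bins)`
#' exactly (all joint mass on the diagonal).
#'
#' @param x,y Numeric series of equal length, at least `10 * n_bins` samples.
#' @param n_bins Number of marginal bins (default 16).
#' @return Mutual information in bits. A constant series is a degenerate
#'   marginal and returns 0 with a warning.
#' @export
mutual_information <- function(x, y, n_bins = 16L) {
  if (length(x) != length(y)) stop("invalid-input: x and y must have equal length")
  stopifnot(n_bins >= 2)
  if (length(x) < 10 * n_bins) {
    stop(sprintf("invalid-input: need >= %d samples for %d bins, got %d",
                 10 * n_bins, n_bins, length(x)))
  }
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("degenerate marginal: constant series, returning MI = 0")
    return(0)
  }
  mi_from_bins(equiprobable_bins(x, n_bins), equiprobable_bins(y, n_bins),
               as.integer(n_bins))
}

#' Mutual-information association matrix of a band series
#'
#' For every unordered channel pair, the mutual information is estimated per
#' epoch on that epoch's band-limited series and averaged across epochs
#' (estimation-then-averaging limits nonstationarity leakage across epoch
#' boundaries; set `concatenate_epochs = TRUE` to estimate once on the
#' concatenated series instead). Zero-lag only; the matrix is symmetric with
#' a zero diagonal by convention.
#'
#' @param series A [band_series()] (an [epoch_set()] is also accepted).
#' @param n_bins Marginal bins for [mutual_information()].
#' @param concatenate_epochs Estimate on concatenated epochs instead of
#'   averaging per-epoch estimates.
#' @return An `mi_matrix`: numeric N x N matrix (bits) with channel labels as
#'   dimnames and attributes `band`, `subject`, `condition` when known.
#' @export
association_matrix <- function(series, n_bins = 16L,
                               concatenate_epochs = FALSE) {
  stopifnot(inherits(series, "epoch_set"))
  d <- dim(series$data)
  n_ep <- d[1L]; n_ch <- d[2L]
  if (n_ch < 2L) stop("invalid-input: need at least 2 channels")
  if (n_ep < 1L) stop("invalid-input: need at least one epoch")
  n_bins <- as.integer(n_bins)
  mi <- matrix(0, n_ch, n_ch)
  if (concatenate_epochs) {
    flat <- vapply(seq_len(n_ch),
                   function(ch) as.vector(t(series$data[, ch, ])),
                   numeric(n_ep * d[3L]))
    bins <- apply(flat, 2L, equiprobable_bins, n_bins = n_bins)
    for (i in seq_len(n_ch - 1L)) {
      for (j in (i + 1L):n_ch) {
        mi[i, j] <- mi[j, i] <- mi_from_bins(bins[, i], bins[, j], n_bins)
      }
    }
  } else {
    for (e in seq_len(n_ep)) {
      bins <- vapply(seq_len(n_ch),
                     function(ch) equiprobable_bins(series$data[e, ch, ], n_bins),
                     integer(d[3L]))
      for (i in seq_len(n_ch - 1L)) {
        for (j in (i + 1L):n_ch) {
          mi[i, j] <- mi[i, j] + mi_from_bins(bins[, i], bins[, j], n_bins)
        }
      }
    }
    mi <- (mi + t(mi)) / n_ep
  }
  dimnames(mi) <- list(series$labels, series$labels)
  structure(mi, class = c("mi_matrix", "matrix"),
            band = series$band)
}

#' Write / read an association matrix as CSV
#'
#' Channel labels form the header row and first column.
#'
#' @param mi An `mi_matrix` (or plain symmetric matrix).
#' @param path File path.
#' @return `write_mi_matrix` returns `path` invisibly; `read_mi_matrix`
#'   returns the matrix.
#' @export
write_mi_matrix <- function(mi, path) {
  df <- data.frame(label = rownames(mi), unclass(mi), check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_mi_matrix
#' @export
read_mi_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt[, -1L])
  dimnames(m) <- list(dt[[1L]], colnames(dt)[-1L])
  structure(m, class = c("mi_matrix", "matrix"))
}
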