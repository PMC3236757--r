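#' Uniform random graph with matched nodes and edges
#'
#' Draws uniformly over simple undirected graphs with exactly `n` nodes and
#' `m` edges (a G(n, m) draw). Deterministic given `seed`.
#'
#' @param n Number of nodes.
#' @param m Number of edges, `0 <= m <= n(n-1)/2`.
#' @param seed Optional integer seed.
#' @return An [adjacency_graph()] with exactly `m` edges.
#' @export
random_graph_matched <- function(n, m, seed = NULL) {
  p_max <- n * (n - 1) / 2
  if (m < 0 || m > p_max) stop("invalid-input: m must be in [0, n(n-1)/2]")
  draw <- function() {
    pairs <- upper_pairs(n)
    sel <- sample.int(p_max, m)
    adj <- matrix(0, n, n)
    adj[pairs[sel, , drop = FALSE]] <- 1
    adj[pairs[sel, 2:1, drop = FALSE]] <- 1
    adjacency_graph(adj)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Regular ring lattice with matched nodes and edges
#'
#' Deterministic ring lattice: every node is connected to its `k/2` nearest
#' neighbours on each side, where `k = floor(2m/n)` rounded down to even; the
#' remaining `m - nk/2` edges are added to next-nearest free neighbour slots
#' in ascending node order, so the construction has exactly `m` edges and is
#' fully reproducible.
#'
#' @inheritParams random_graph_matched
#' @return An [adjacency_graph()] with exactly `m` edges.
#' @export
regular_lattice_matched <- function(n, m) {
  p_max <- n * (n - 1) / 2
  if (m < 0 || m > p_max) stop("invalid-input: m must be in [0, n(n-1)/2]")
  adj <- matrix(0, n, n)
  k <- (floor(2 * m / n) %/% 2) * 2
  half <- k / 2
  if (half >= 1) {
    for (d in seq_len(half)) {
      for (i in seq_len(n)) {
        j <- ((i - 1 + d) %% n) + 1
        adj[i, j] <- adj[j, i] <- 1
      }
    }
  }
  r <- m - sum(adj) / 2
  d <- half + 1
  i <- 1L
  while (r > 0) {
    j <- ((i - 1 + d) %% n) + 1
    if (i != j && adj[i, j] == 0) {
      adj[i, j] <- adj[j, i] <- 1
      r <- r - 1
    }
    i <- i + 1L
    if (i > n) { i <- 1L; d <- d + 1 }
  }
  adjacency_graph(adj)
}

#' Watts-Strogatz graph with matched nodes and edges
#'
#' Starts from [regular_lattice_matched()] and rewires each edge with
#' probability `p`: the lower-index endpoint is kept and the other endpoint
#' is redrawn uniformly among currently unconnected nodes, so the edge count
#' is preserved exactly. Deterministic given `seed`.
#'
#' @inheritParams random_graph_matched
#' @param p Rewiring probability in `[0, 1]`.
#' @return An [adjacency_graph()] with exactly `m` edges.
#' @export
watts_strogatz_graph <- function(n, m, p = 0.1, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  g <- regular_lattice_matched(n, m)
  rewire <- function() {
    adj <- g$adj
    edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    for (e in seq_len(nrow(edges))) {
      if (stats::runif(1) >= p) next
      i <- edges[e, 1L]; j <- edges[e, 2L]
      free <- which(adj[i, ] == 0)
      free <- setdiff(free, i)
      if (length(free) == 0L) next
      j2 <- free[sample.int(length(free), 1L)]
      adj[i, j] <- adj[j, i] <- 0
      adj[i, j2] <- adj[j2, i] <- 1
    }
    adjacency_graph(adj)
  }
  if (is.null(seed)) rewire() else withr::with_seed(seed, rewire())
}

graph_summary <- function(g) {
  cl <- suppressWarnings(clustering_and_pathlength(g))
  c(eglob = global_efficiency(g), elocal = local_efficiency(g),
    cp = cl$cp, lp = cl$lp)
}

#' Matched null ensemble at one edge count
#'
#' Generates `n_draws` uniform random graphs and the matched regular lattice
#' (replicated `n_draws` times; the lattice construction is deterministic)
#' with the same node and edge counts, and summarises mean `Eglob`, `Elocal`,
#' `Cp`, `Lp` per family.
#'
#' @inheritParams random_graph_matched
#' @param n_draws Ensemble size per family (default 20).
#' @param keep_members Also return the random member graphs.
#' @return Object of class `null_ensemble`: list with `n`, `m`, `n_draws`,
#'   `random` and `regular` mean summaries, and optionally `members`.
#' @export
null_ensemble <- function(n, m, n_draws = 20L, seed = NULL,
                          keep_members = FALSE) {
  seeds <- if (is.null(seed)) rep(list(NULL), n_draws) else
    as.list(derive_seeds(seed, n_draws))
  members <- lapply(seeds, function(s) random_graph_matched(n, m, seed = s))
  rand <- rowMeans(vapply(members, graph_summary, numeric(4L)))
  reg <- graph_summary(regular_lattice_matched(n, m))
  out <- list(n = n, m = m, n_draws = n_draws,
              random = as.list(rand), regular = as.list(reg))
  if (keep_members) out$members <- members
  structure(out, class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<null_ensemble> n=%d m=%d (%d draws)\n",
                     "  random : Eglob %.3f Elocal %.3f Cp %.3f Lp %.3f\n",
                     "  regular: Eglob %.3f Elocal %.3f Cp %.3f Lp %.3f\n"),
              x$n, x$m, x$n_draws,
              x$random$eglob, x$random$elocal, x$random$cp, x$random$lp,
              x$regular$eglob, x$regular$elocal, x$regular$cp, x$regular$lp))
  invisible(x)
}

#' Small-worldness index sigma
#'
#' `sigma = (Cp/mean Cp_random) / (Lp/mean Lp_random)` against the random
#' members of a matched null ensemble; values above 1 indicate small-world
#' organisation (clustering well above random at near-random path length).
#'
#' @param g An [adjacency_graph()].
#' @param nulls A [null_ensemble()] matched to `g`'s node and edge counts.
#' @return Scalar sigma; `NaN` (with a warning) when the random clustering is
#'   zero or the path length is undefined.
#' @export
sigma_small_worldness <- function(g, nulls) {
  stopifnot(inherits(g, "adjacency_graph"), inherits(nulls, "null_ensemble"))
  if (g$n != nulls$n || g$n_edges != nulls$m) {
    stop("invalid-input: null ensemble is not matched to the graph (n, m)")
  }
  cl <- suppressWarnings(clustering_and_pathlength(g))
  if (!is.finite(cl$lp) || nulls$random$cp == 0 ||
      !is.finite(nulls$random$lp) || nulls$random$lp == 0) {
    warning("sigma undefined: degenerate clustering or path length")
    return(NaN)
  }
  (cl$cp / nulls$random$cp) / (cl$lp / nulls$random$lp)
}

#' Null ensembles along a cost grid
#'
#' Convenience wrapper building one [null_ensemble()] per grid cost for an
#' `n`-node graph (edge counts `round(cost * n(n-1)/2)`).
#'
#' @param n Number of nodes.
#' @param costs Cost grid.
#' @param n_draws Random draws per cost.
#' @param seed Optional integer seed.
#' @return Named list of `null_ensemble`, one per cost.
#' @export
null_ensemble_grid <- function(n, costs = cost_grid(), n_draws = 20L,
                               seed = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), length(costs)) else
    as.list(derive_seeds(seed, length(costs)))
  out <- Map(function(cc, s) {
    null_ensemble(n, as.integer(round(cc * n * (n - 1) / 2)),
                  n_draws = n_draws, seed = s)
  }, costs, seeds)
  names(out) <- sprintf("%.2f", costs)
  out
}

#' Small-world regime of a pair of metric curves
#'
#' The contiguous cost-grid interval, beginning at the lowest qualifying
#' cost, on which the empirical curves lie strictly between the null-family
#' means: `mean Eglob_regular < Eglob < mean Eglob_random` and
#' `mean Elocal_random < Elocal < mean Elocal_regular`. When no grid point
#' qualifies the interval is flagged invalid — the rule under which a band is
#' excluded from further analysis.
#'
#' @param eglob,elocal Empirical metric curves aligned to `costs`.
#' @param nulls List of [null_ensemble()] per cost (see
#'   [null_ensemble_grid()]).
#' @param costs Cost grid.
#' @param band Optional band name tag.
#' @return Object of class `regime_interval`: list with `band`, `c_low`,
#'   `c_high`, `valid`, and the logical vector `qualifies`.
#' @export
small_world_regime <- function(eglob, elocal, nulls, costs, band = NULL) {
  stopifnot(length(eglob) == length(costs), length(elocal) == length(costs),
            length(nulls) == length(costs))
  ok <- vapply(seq_along(costs), function(i) {
    nu <- nulls[[i]]
    isTRUE(nu$regular$eglob < eglob[i] && eglob[i] < nu$random$eglob &&
             nu$random$elocal < elocal[i] && elocal[i] < nu$regular$elocal)
  }, logical(1L))
  valid <- any(ok)
  if (valid) {
    start <- which(ok)[1L]
    len <- which.min(c(ok[start:length(ok)], FALSE)) - 1L
    c_low <- costs[start]
    c_high <- costs[start + len - 1L]
  } else {
    c_low <- c_high <- NA_real_
  }
  structure(list(band = band, c_low = c_low, c_high = c_high, valid = valid,
                 qualifies = ok, costs = costs),
            class = "regime_interval")
}

#' @export
print.regime_interval <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<regime_interval>%s valid: %.2f <= C <= %.2f\n",
                if (is.null(x$band)) "" else paste0(" [", x$band, "]"),
                x$c_low, x$c_high))
  } else {
    cat(sprintf("<regime_interval>%s invalid (no qualifying cost)\n",
                if (is.null(x$band)) "" else paste0(" [", x$band, "]")))
  }
  invisible(x)
}

#' Small-world-structured weight matrix
#'
#' Builds a synthetic symmetric weight matrix whose cost-thresholded graphs
#' are Watts-Strogatz-like at every density: a WS topology (ring lattice at
#' `lattice_cost`, rewired with probability `rewire_p`) receives i.i.d. edge
#' weights above an i.i.d. background, so thresholding below the topology
#' cost thins the WS graph at random and thresholding above it fills in
#' random edges. Used to emulate subject-level association matrices in
#' regime and ordering checks.
#'
#' @param n Number of nodes.
#' @param lattice_cost Topology density (fraction of all pairs).
#' @param rewire_p WS rewiring probability.
#' @param seed Optional integer seed.
#' @return Symmetric `n x n` weight matrix with zero diagonal.
#' @export
smallworld_weight_matrix <- function(n, lattice_cost = 0.45, rewire_p = 0.1,
                                     seed = NULL) {
  m <- as.integer(round(lattice_cost * n * (n - 1) / 2))
  build <- function() {
    topo_seed <- sample.int(2^30, 1L)
    ws <- watts_strogatz_graph(n, m, p = rewire_p, seed = topo_seed)
    w <- matrix(0, n, n)
    pairs <- upper_pairs(n)
    on_edge <- ws$adj[pairs] == 1
    w[pairs[on_edge, , drop = FALSE]] <- stats::runif(sum(on_edge), 1, 2)
    w[pairs[!on_edge, , drop = FALSE]] <- stats::runif(sum(!on_edge), 0, 1)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    w
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
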