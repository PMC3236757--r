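#' Binary undirected graph at a given network cost
#'
#' Constructor/validator for the `adjacency_graph` container used by all
#' network metrics: a binary symmetric adjacency matrix with zero diagonal,
#' plus its cost (fraction of possible edges) and edge count.
#'
#' @param adj Binary symmetric numeric matrix with zero diagonal.
#' @return Object of class `adjacency_graph` with elements `adj`, `n`,
#'   `n_edges`, `cost`.
#' @export
adjacency_graph <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  stopifnot(n == ncol(adj), all(adj %in% c(0, 1)))
  if (!isTRUE(all.equal(adj, t(adj)))) {
    stop("invalid-input: adjacency matrix must be symmetric")
  }
  if (any(diag(adj) != 0)) stop("invalid-input: self-loops are not allowed")
  m <- sum(adj) / 2
  structure(list(adj = adj, n = n, n_edges = m,
                 cost = m / (n * (n - 1) / 2)),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> %d nodes, %d edges (cost %.4f)\n",
              x$n, x$n_edges, x$cost))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
}

upper_pairs <- function(n) {
  # row/col indices of the upper triangle, column-major order
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

#' Threshold an association matrix at a network cost
#'
#' Keeps exactly `K = round(cost * N(N-1)/2)` strongest off-diagonal pairs as
#' edges. Ties at the cutoff are broken deterministically by ascending
#' (row, column) index, so results are reproducible.
#'
#' @param mi Symmetric association matrix (an `mi_matrix` or plain matrix).
#' @param cost Target connection density in `(0, 1]`. A cost yielding `K = 0`
#'   returns a valid empty graph.
#' @return An [adjacency_graph()].
#' @export
threshold_by_cost <- function(mi, cost) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi), cost > 0, cost <= 1)
  n <- nrow(mi)
  pairs <- upper_pairs(n)
  w <- mi[pairs]
  k <- as.integer(round(cost * n * (n - 1) / 2))
  ord <- order(-w, pairs[, 1L], pairs[, 2L])
  adj <- matrix(0, n, n)
  if (k > 0L) {
    sel <- pairs[ord[seq_len(k)], , drop = FALSE]
    adj[sel] <- 1
    adj[sel[, 2:1, drop = FALSE]] <- 1
  }
  dimnames(adj) <- dimnames(mi)
  adjacency_graph(adj)
}

#' All-pairs shortest path lengths (hop counts)
#'
#' Breadth-first-search distances between every node pair; `Inf` marks
#' disconnected pairs, and the diagonal is 0.
#'
#' @param g An [adjacency_graph()].
#' @return Symmetric N x N numeric matrix of hop counts.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"))
  d <- igraph::distances(as_igraph(g), algorithm = "unweighted")
  dimnames(d) <- dimnames(g$adj)
  d
}

efficiency_from_distances <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  inv <- 1 / d
  diag(inv) <- 0            # 1/Inf = 0 for disconnected pairs; self-pairs excluded
  # written as the mean of per-node efficiencies so that
  # mean(nodal_efficiency(g)) == global_efficiency(g) holds to the bit
  mean(rowSums(inv) / (n - 1))
}

#' Global efficiency
#'
#' Mean over ordered node pairs `i != j` of the inverse shortest path length,
#' with `1/Inf = 0` for disconnected pairs, so disconnected and non-sparse
#' graphs are handled without special cases. Lies in `[0, 1]`; 1 for a
#' complete graph, 0 for an edgeless one.
#'
#' @param g An [adjacency_graph()].
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"), g$n >= 2)
  efficiency_from_distances(shortest_path_lengths(g))
}

#' Nodal (regional) efficiency
#'
#' `Enodal(i) = mean over j != i of 1/L(i, j)`: the inverse harmonic mean of
#' node `i`'s shortest path lengths to all other nodes. The across-node mean
#' of `Enodal` equals [global_efficiency()] identically.
#'
#' @param g An [adjacency_graph()].
#' @return Named numeric vector, one value per node.
#' @export
nodal_efficiency <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"), g$n >= 2)
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (g$n - 1)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours (the communication efficiency among a node's neighbours
#' when the node itself is removed). Neighbourhoods with fewer than 2 nodes
#' contribute 0.
#'
#' @param g An [adjacency_graph()].
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"), g$n >= 1)
  vals <- vapply(seq_len(g$n), function(i) {
    nb <- which(g$adj[i, ] == 1)
    if (length(nb) < 2L) return(0)
    sub <- adjacency_graph(g$adj[nb, nb, drop = FALSE])
    efficiency_from_distances(shortest_path_lengths(sub))
  }, numeric(1L))
  mean(vals)
}

#' Clustering coefficient and characteristic path length
#'
#' `Cp` is the mean Watts-Strogatz node clustering coefficient (triangles over
#' possible neighbour pairs; nodes of degree < 2 contribute 0). `Lp` is the
#' mean finite shortest path length over connected ordered pairs; on a fully
#' disconnected graph `Lp` is undefined and returned as `NaN` with a warning.
#'
#' @param g An [adjacency_graph()].
#' @return List with elements `cp` and `lp`.
#' @export
clustering_and_pathlength <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"), g$n >= 3)
  a <- g$adj
  deg <- rowSums(a)
  tri <- diag(a %*% a %*% a)           # 2 x triangles through each node
  ci <- ifelse(deg < 2, 0, tri / (deg * (deg - 1)))
  d <- shortest_path_lengths(g)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  lp <- if (length(fin) == 0L) {
    warning("fully disconnected graph: Lp undefined (NaN)")
    NaN
  } else mean(fin)
  list(cp = mean(ci), lp = lp)
}

#' Cost-efficiency curve and its maximum
#'
#' `CE(c) = Eglob(c) - c` pointwise on the cost grid; positive values mark an
#' economical network. `max_ce` is the curve maximum, with ties resolved to
#' the lowest cost.
#'
#' @param eglob Numeric vector of global efficiencies aligned to `costs`.
#' @param costs Cost grid (strictly increasing, in `(0, 1]`).
#' @return List with `ce` (vector), `max_ce` (scalar) and `argmax_cost`.
#' @export
cost_efficiency_curve <- function(eglob, costs) {
  stopifnot(length(eglob) == length(costs), all(diff(costs) > 0),
            all(costs > 0), all(costs <= 1))
  ce <- eglob - costs
  i <- which.max(ce)                   # which.max takes the first (lowest-cost) tie
  list(ce = ce, max_ce = ce[i], argmax_cost = costs[i])
}

#' Default cost grid
#'
#' Costs from `from` to `to` in steps of `by`; the analysis default spans
#' 0.16--0.50 in steps of 0.02, matching the per-cost reporting resolution of
#' the cohort statistics.
#'
#' @param from,to,by Grid limits and step.
#' @return Strictly increasing numeric vector.
#' @export
cost_grid <- function(from = 0.16, to = 0.50, by = 0.02) {
  g <- seq(from, to, by = by)
  stopifnot(all(g > 0), all(g <= 1))
  round(g, 10)
}

#' Metric curves of an association matrix over a cost grid
#'
#' Thresholds `mi` at every grid cost and evaluates the requested metrics on
#' each graph. Because thresholded graphs of a fixed matrix are nested as the
#' cost grows (edges are only added), `Eglob` is non-decreasing along the
#' grid.
#'
#' @param mi Symmetric association matrix.
#' @param costs Cost grid from [cost_grid()].
#' @param metrics Character subset of `c("Eglob", "Elocal", "Cp", "Lp")`.
#' @return Data frame with columns `cost` and one column per metric.
#' @export
metric_curves <- function(mi, costs = cost_grid(),
                          metrics = c("Eglob", "Elocal")) {
  metrics <- match.arg(metrics, c("Eglob", "Elocal", "Cp", "Lp"),
                       several.ok = TRUE)
  rows <- lapply(costs, function(cc) {
    g <- threshold_by_cost(mi, cc)
    out <- list(cost = cc)
    if (any(c("Cp", "Lp") %in% metrics)) {
      cl <- clustering_and_pathlength(g)
      if ("Cp" %in% metrics) out$Cp <- cl$cp
      if ("Lp" %in% metrics) out$Lp <- cl$lp
    }
    if ("Eglob" %in% metrics) out$Eglob <- global_efficiency(g)
    if ("Elocal" %in% metrics) out$Elocal <- local_efficiency(g)
    as.data.frame(out)
  })
  do.call(rbind, rows)
}
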