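# Brute-force oracles, written independently of the package internals (and of
# igraph): Floyd-Warshall distances and direct metric enumerations.

fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_eglob <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  }
  s / (n * (n - 1))
}

oracle_enodal <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    s / (n - 1)
  })
}

oracle_elocal <- function(adj) {
  n <- nrow(adj)
  vals <- sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_eglob(adj[nb, nb, drop = FALSE])
  })
  mean(vals)
}

oracle_cp <- function(adj) {
  n <- nrow(adj)
  ci <- sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (adj[nb[a], nb[b]] == 1) links <- links + 1
    }
    2 * links / (k * (k - 1))
  })
  mean(ci)
}

oracle_lp <- function(adj) {
  d <- fw_distances(adj)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) NaN else mean(fin)
}

# uniform random adjacency with an edge probability (for oracle sweeps)
random_adj <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  a[up] <- as.numeric(runif(sum(up)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# permutation null for an MI value: 95th percentile of MI between x and
# permuted y
mi_perm_quantile <- function(x, y, n_perm = 200, q = 0.95, n_bins = 16) {
  vals <- sapply(seq_len(n_perm), function(i)
    mutual_information(x, sample(y), n_bins))
  unname(quantile(vals, q))
}
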