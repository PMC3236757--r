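test_that("cost thresholding yields the printed sparse-graph constants", {
  withr::local_seed(1)
  w <- smallworld_weight_matrix(58, seed = 1)
  g <- threshold_by_cost(w, 0.16)
  expect_identical(g$n_edges, 264)
  expect_equal(round(2 * g$n_edges / g$n), 9)      # mean degree ~ 9
  expect_identical(threshold_by_cost(w, 1)$n_edges, 1653)
  expect_identical(threshold_by_cost(w, 1e-4)$n_edges, 0)
})

test_that("threshold ties break deterministically by ascending index", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 5
  w[1, 3] <- w[3, 1] <- 3
  w[1, 4] <- w[4, 1] <- 3
  w[3, 4] <- w[4, 3] <- 3                          # three-way tie at 3
  g <- threshold_by_cost(w, 2 / 6)                 # keep 2 edges
  expect_equal(g$adj[1, 2], 1)
  expect_equal(g$adj[1, 3], 1)                     # (1,3) beats (1,4), (3,4)
  expect_equal(g$adj[1, 4] + g$adj[3, 4], 0)
  expect_identical(threshold_by_cost(w, 2 / 6)$adj, g$adj)
})

test_that("shortest path lengths match a Floyd-Warshall oracle", {
  path3 <- adjacency_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  d <- shortest_path_lengths(path3)
  expect_equal(d[1, 3], 2)
  two <- adjacency_graph(matrix(0, 2, 2))
  expect_identical(shortest_path_lengths(two)[1, 2], Inf)
  withr::local_seed(2)
  for (i in 1:50) {
    adj <- random_adj(sample(4:20, 1), runif(1, 0.1, 0.6))
    g <- adjacency_graph(adj)
    expect_equal(shortest_path_lengths(g), fw_distances(adj),
                 ignore_attr = TRUE)
  }
})

test_that("global/nodal efficiency closed forms and identities hold", {
  kn <- adjacency_graph(1 - diag(6))
  expect_equal(global_efficiency(kn), 1)
  path3 <- adjacency_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(adjacency_graph(matrix(0, 4, 4))), 0)

  star4 <- matrix(0, 4, 4); star4[1, 2:4] <- star4[2:4, 1] <- 1
  en <- nodal_efficiency(adjacency_graph(star4))
  expect_equal(en[1], 1)                           # hub reaches all in 1 hop
  expect_equal(en[2], 2 / 3)                       # leaf: distances 1, 2, 2

  withr::local_seed(3)
  for (i in 1:25) {
    g <- adjacency_graph(random_adj(sample(4:12, 1), runif(1, 0.2, 0.7)))
    expect_equal(mean(nodal_efficiency(g)), global_efficiency(g))
  }
})

test_that("local efficiency follows the neighbourhood-subgraph definition", {
  tri <- adjacency_graph(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  expect_equal(local_efficiency(tri), 1)
  path3 <- adjacency_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(local_efficiency(path3), 0)         # < 2 neighbours convention
  withr::local_seed(4)
  for (i in 1:50) {
    adj <- random_adj(sample(4:15, 1), runif(1, 0.2, 0.7))
    expect_equal(local_efficiency(adjacency_graph(adj)), oracle_elocal(adj))
  }
})

test_that("clustering coefficient and path length match enumeration", {
  k4 <- adjacency_graph(1 - diag(4))
  cl <- clustering_and_pathlength(k4)
  expect_equal(cl$cp, 1); expect_equal(cl$lp, 1)

  c6 <- regular_lattice_matched(6, 6)              # the 6-cycle
  cl6 <- clustering_and_pathlength(c6)
  expect_equal(cl6$cp, 0)
  expect_equal(cl6$lp, 1.8)                        # (1+1+2+2+3)/5 by symmetry

  withr::local_seed(5)
  for (i in 1:50) {
    adj <- random_adj(sample(4:15, 1), runif(1, 0.2, 0.7))
    cl <- suppressWarnings(clustering_and_pathlength(adjacency_graph(adj)))
    expect_equal(cl$cp, oracle_cp(adj))
    expect_equal(cl$lp, oracle_lp(adj))
  }
  expect_warning(clustering_and_pathlength(adjacency_graph(matrix(0, 4, 4))),
                 "disconnected")
})

test_that("cost-efficiency curve arithmetic and tie handling", {
  ce <- cost_efficiency_curve(c(1, 1), c(0.2, 0.5))
  expect_equal(ce$ce, c(0.8, 0.5))
  expect_equal(ce$max_ce, 0.8)
  expect_equal(ce$argmax_cost, 0.2)
  # ties resolve to the lowest cost
  tie <- cost_efficiency_curve(c(0.5, 0.6), c(0.2, 0.3))
  expect_equal(tie$argmax_cost, 0.2)
  # complete graph at cost 1: CE = 0
  expect_equal(cost_efficiency_curve(1, 1)$ce, 0)
  # a sparse random graph is economical by construction
  g <- random_graph_matched(58, 264, seed = 9)
  expect_gt(global_efficiency(g) - g$cost, 0)
})

test_that("Eglob rises monotonically with cost on nested graphs", {
  withr::local_seed(6)
  w <- smallworld_weight_matrix(24, seed = 11)
  cur <- metric_curves(w, cost_grid(0.08, 0.40, 0.04))
  expect_true(all(diff(cur$Eglob) >= 0))
  expect_true(all(cur$Eglob >= 0 & cur$Eglob <= 1))
  expect_true(all(cur$Elocal >= 0 & cur$Elocal <= 1))
})

test_that("both efficiency curves rise with cost on dense small-world matrices", {
  # Elocal monotonicity is an empirical regularity of dense small-world
  # association structure, not a theorem (an added edge can dilute a
  # neighbourhood); allow sub-0.005 local fluctuations around a rising trend
  w <- smallworld_weight_matrix(58, seed = 21)
  cur <- metric_curves(w, cost_grid())
  expect_true(all(diff(cur$Eglob) >= 0))
  expect_true(all(diff(cur$Elocal) >= -0.005))
  expect_gt(cor(cur$Elocal, cur$cost, method = "spearman"), 0.95)
  expect_gt(cur$Elocal[length(cur$Elocal)], cur$Elocal[1])
})
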