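# Shared Monte-Carlo results over planted-interaction cohorts, computed once
# per test run and reused by the power, duration-recovery and module checks.

.mc_env <- new.env(parent = emptyenv())

planted_cohort_mc <- function(n_cohorts = 50) {
  key <- paste0("planted_", n_cohorts)
  if (!is.null(.mc_env[[key]])) return(.mc_env[[key]])
  mcost <- mid_grid_cost(desk_cost_grid())
  rows <- lapply(seq_len(n_cohorts), function(i) {
    cohort <- simulate_cohort(desk_config(seed = 20000 + i))
    mi <- cohort_connectivity(cohort, n_bins = 8)
    tab <- cohort_metric_table(mi, cohort$manifest, mcost, metrics = "Eglob")
    a <- anova_2x2(tab, "Eglob", "beta", mcost)
    dc <- duration_correlation(tab, cohort$manifest, "Eglob", "beta")
    data.frame(p_interaction = a$p[a$effect == "interaction"],
               R_task = dc$R[dc$condition == "task"],
               R_rest = dc$R[dc$condition == "rest"])
  })
  .mc_env[[key]] <- do.call(rbind, rows)
  .mc_env[[key]]
}

null_cohort_pvalues <- function(n_cohorts = 200) {
  key <- paste0("null_", n_cohorts)
  if (!is.null(.mc_env[[key]])) return(.mc_env[[key]])
  pv <- vapply(seq_len(n_cohorts), function(i) {
    cohort <- simulate_cohort(desk_config(preset = "null", n_per_group = 5L,
                                          seed = 40000 + i))
    mi <- cohort_connectivity(cohort, n_bins = 8)
    tab <- cohort_metric_table(mi, cohort$manifest, 0.16, metrics = "Eglob")
    a <- anova_2x2(tab, "Eglob", "beta", 0.16)
    a$p[a$effect == "interaction"]
  }, numeric(1L))
  .mc_env[[key]] <- pv
  pv
}
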