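make_table <- function(values, n_per_group) {
  # values: named list control_rest, control_task, patient_rest, patient_task
  rows <- list()
  for (g in c("control", "patient")) {
    for (cond in c("rest", "task")) {
      v <- values[[paste(g, cond, sep = "_")]]
      ids <- sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(n_per_group))
      rows[[paste(g, cond)]] <- data.frame(
        subject = ids, group = g, condition = cond, band = "beta",
        cost = 0.16, metric = "Eglob", value = v)
    }
  }
  do.call(rbind, rows)
}

test_that("all-equal observations give F = 0 and p = 1 for every effect", {
  tab <- make_table(list(control_rest = rep(0.5, 15), control_task = rep(0.5, 15),
                         patient_rest = rep(0.5, 15), patient_task = rep(0.5, 15)),
                    15)
  a <- anova_2x2(tab, "Eglob", "beta", 0.16)
  expect_equal(a$F, rep(0, 3))
  expect_equal(a$p, rep(1, 3))
})

test_that("ANOVA matches textbook sums-of-squares arithmetic", {
  # n = 2 per cell, cell values {0,0}, {0,0}, {0,0}, {1,1}:
  # grand mean 1/4; SS_A = SS_B = SS_AB = 8*(1/4)^2 = 0.5, SS_err = 0,
  # so F is infinite; perturb one value to make it finite and compare to a
  # hand computation instead
  vals <- list(control_rest = c(0, 0), control_task = c(0, 0),
               patient_rest = c(0, 0), patient_task = c(1, 1.2))
  tab <- make_table(vals, 2)
  a <- anova_2x2(tab, "Eglob", "beta", 0.16)
  # hand computation (balanced 2x2, n = 2)
  y <- unlist(vals)
  cellm <- sapply(vals, mean)
  gm <- mean(y)
  gr <- c(mean(cellm[1:2]), mean(cellm[3:4]))      # control, patient
  cd <- c(mean(cellm[c(1, 3)]), mean(cellm[c(2, 4)]))  # rest, task
  ss_a <- 4 * sum((gr - gm)^2)
  ss_b <- 4 * sum((cd - gm)^2)
  ss_cells <- 2 * sum((cellm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_err <- sum((y - rep(cellm, each = 2))^2)
  f_expect <- c(ss_a, ss_b, ss_ab) / (ss_err / 4)
  expect_equal(a$F, f_expect, tolerance = 1e-10)
  expect_equal(a$df2, rep(4L, 3))
})

test_that("degrees of freedom are 56 (crossed) and 28 (mixed) at full size", {
  withr::local_seed(1)
  tab <- make_table(list(control_rest = rnorm(15), control_task = rnorm(15),
                         patient_rest = rnorm(15), patient_task = rnorm(15)),
                    15)
  a <- anova_2x2(tab, "Eglob", "beta", 0.16, mode = "crossed")
  expect_equal(a$df2, rep(56L, 3))
  m <- anova_2x2(tab, "Eglob", "beta", 0.16, mode = "mixed")
  expect_equal(m$df2, rep(28L, 3))
  expect_true(all(m$F >= 0) && all(m$p >= 0 & m$p <= 1))
})

test_that("sums of squares partition to the total", {
  withr::local_seed(2)
  tab <- make_table(list(control_rest = rnorm(8), control_task = rnorm(8),
                         patient_rest = rnorm(8), patient_task = rnorm(8)), 8)
  df <- tab
  df$group <- factor(df$group); df$condition <- factor(df$condition)
  aj <- stats::anova(stats::lm(value ~ group * condition, data = df))
  ss_total <- sum((df$value - mean(df$value))^2)
  expect_equal(sum(aj[["Sum Sq"]]), ss_total, tolerance = 1e-9)
})

test_that("post-hoc t-tests handle paired, two-sample and degenerate cases", {
  withr::local_seed(3)
  vals <- list(control_rest = rnorm(10), control_task = rnorm(10) + 3,
               patient_rest = rnorm(10), patient_task = rnorm(10))
  tab <- make_table(vals, 10)
  ph <- posthoc_ttests(tab, "Eglob", "beta", 0.16)
  expect_identical(nrow(ph), 4L)
  expect_lt(ph$p[ph$contrast == "control: rest vs task"], 0.05)
  # identical rest and task vectors: p = 1 flagged degenerate
  same <- rnorm(6)
  tab2 <- make_table(list(control_rest = same, control_task = same,
                          patient_rest = rnorm(6), patient_task = rnorm(6)), 6)
  ph2 <- posthoc_ttests(tab2, "Eglob", "beta", 0.16)
  row <- ph2[ph2$contrast == "control: rest vs task", ]
  expect_identical(row$p, 1)
  expect_true(row$degenerate)
  # constant unit shift with zero within-pair variance is also degenerate
  tab3 <- make_table(list(control_rest = same, control_task = same + 1,
                          patient_rest = rnorm(6), patient_task = rnorm(6)), 6)
  ph3 <- posthoc_ttests(tab3, "Eglob", "beta", 0.16)
  expect_true(ph3$degenerate[ph3$contrast == "control: rest vs task"])
})

test_that("paired t rejection rate matches the closed-form power oracle", {
  withr::local_seed(4)
  n_rep <- 400
  rej <- mean(sapply(seq_len(n_rep), function(i) {
    rest <- rnorm(15); task <- rest + rnorm(15) + 1   # delta = 1 SD of diffs
    tab <- make_table(list(control_rest = rest, control_task = task,
                           patient_rest = rnorm(15), patient_task = rnorm(15)),
                      15)
    ph <- posthoc_ttests(tab, "Eglob", "beta", 0.16)
    ph$p[ph$contrast == "control: rest vs task"] < 0.05
  }))
  oracle <- power.t.test(n = 15, delta = 1, sd = 1, type = "paired")$power
  expect_lt(abs(rej - oracle), 0.03)
})

test_that("Z-scoring is exact, affine-invariant and idempotent", {
  z <- zscore_map(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2))       # population SD
  expect_equal(zscore_map(c(1, 2, 3), sd_type = "sample"), c(-1, 0, 1))
  withr::local_seed(5)
  x <- rnorm(58)
  expect_equal(zscore_map(5 * x - 2), zscore_map(x))
  expect_equal(mean(zscore_map(x)), 0, tolerance = 1e-12)
  expect_equal(mean(zscore_map(x)^2), 1, tolerance = 1e-12)
  expect_equal(zscore_map(zscore_map(x)), zscore_map(x))
  expect_identical(order(zscore_map(x)), order(x)) # rank order preserved
  expect_warning(z0 <- zscore_map(rep(3, 5)), "degenerate")
  expect_equal(z0, rep(0, 5))
})

test_that("nodal significance tiers evaluate to the printed thresholds", {
  tiers <- significance_tiers(58)
  expect_equal(unname(tiers["uncorrected"]), 0.05)
  expect_equal(round(unname(tiers["fpc"]), 3), 0.017)
  expect_equal(round(unname(tiers["fdr_label"]), 5), 0.00086)
})

make_maps <- function(n_per_group, n_nodes, planted_node = NULL,
                      planted_delta = 0) {
  rows <- list()
  for (g in c("control", "patient")) {
    for (cond in c("rest", "task")) {
      for (s in seq_len(n_per_group)) {
        id <- sprintf("%s%02d", toupper(substr(g, 1, 1)), s)
        v <- rnorm(n_nodes)
        if (!is.null(planted_node) && cond == "task") {
          v[planted_node] <- v[planted_node] + planted_delta
        }
        rows[[paste(id, cond)]] <- data.frame(
          subject = id, group = g, condition = cond,
          node = sprintf("n%02d", seq_len(n_nodes)), value = v)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("nodal tests flag a planted condition effect at the strictest tier", {
  withr::local_seed(6)
  hits <- sapply(1:25, function(i) {
    maps <- make_maps(15, 58, planted_node = 7, planted_delta = 3)
    nt <- nodal_tests(maps)
    nt$sig_fdr_label[nt$node == "n07" & nt$effect == "condition"]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("null nodal maps produce chance-level uncorrected flags", {
  withr::local_seed(7)
  counts <- sapply(1:40, function(i) {
    maps <- make_maps(8, 30)
    nt <- nodal_tests(maps)
    sum(nt$sig_uncorrected[nt$effect == "interaction"])
  })
  # expected 0.05 * 30 = 1.5 per cohort; binomial bound over 40 x 30 tests
  total <- sum(counts)
  expect_gt(total, qbinom(0.005, 40 * 30, 0.05))
  expect_lt(total, qbinom(0.995, 40 * 30, 0.05))
})

test_that("nodal tests reject mismatched node label sets", {
  maps <- make_maps(3, 6)
  maps <- maps[!(maps$subject == "C01" & maps$condition == "rest" &
                   maps$node == "n01"), ]
  expect_error(nodal_tests(maps), "invalid-input")
})

test_that("duration correlations recover exact and null relationships", {
  dur <- data.frame(id = sprintf("P%02d", 1:15),
                    duration_years = seq(2, 25, length.out = 15))
  tab <- data.frame(subject = rep(dur$id, 2),
                    group = "patient",
                    condition = rep(c("rest", "task"), each = 15),
                    band = "beta", cost = 0.16, metric = "Eglob",
                    value = rep(-dur$duration_years, 2))
  dc <- duration_correlation(tab, dur, "Eglob", "beta")
  expect_equal(dc$R, c(-1, -1), tolerance = 1e-12)
  expect_true(all(dc$p < 1e-10))
  # constant metric flagged degenerate
  tab$value <- 1
  dc2 <- duration_correlation(tab, dur, "Eglob", "beta")
  expect_true(all(dc2$degenerate))
  expect_error(duration_correlation(tab[1:2, ], dur[1:2, ], "Eglob", "beta"),
               "insufficient-data")
})

test_that("null |R| quantile matches the analytic t-distribution bound", {
  withr::local_seed(8)
  n <- 15
  r_obs <- replicate(500, cor(rnorm(n), rnorm(n)))
  t_crit <- qt(0.975, n - 2)
  r_crit <- t_crit / sqrt(t_crit^2 + n - 2)
  expect_lt(abs(unname(quantile(abs(r_obs), 0.95)) - r_crit),
            0.1 * r_crit)
})

test_that("interaction p-values are uniform under the null model", {
  withr::local_seed(9)
  pv <- replicate(500, {
    tab <- make_table(list(control_rest = rnorm(8), control_task = rnorm(8),
                           patient_rest = rnorm(8), patient_task = rnorm(8)),
                      8)
    a <- anova_2x2(tab, "Eglob", "beta", 0.16)
    a$p[a$effect == "interaction"]
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
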