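# Cohort-level inference: per-cost 2x2 ANOVA, post-hoc t-tests, Z-scored
# nodal maps with tiered per-node tests, and efficiency-duration correlations.

metric_subset <- function(table, metric, band, cost, tol = 1e-9) {
  stopifnot(all(c("subject", "group", "condition", "band", "cost", "metric",
                  "value") %in% names(table)))
  out <- table[table$metric == metric & table$band == band &
                 abs(table$cost - cost) < tol, , drop = FALSE]
  if (nrow(out) == 0L) stop("insufficient-data: no rows for ", metric, "/",
                            band, " at cost ", cost)
  out
}

#' Two-way group x condition ANOVA of a network metric at one cost
#'
#' The default (`mode = "crossed"`) is a fully-crossed two-way ANOVA over all
#' subject-condition observations, which for 15 + 15 subjects and two
#' conditions yields denominator degrees of freedom 56 for every effect.
#' `mode = "mixed"` treats condition as a within-subject factor (subject as
#' error stratum; denominator 28), the textbook analysis for a
#' between-group/within-condition design. Both are reported as-is.
#'
#' @param table Long metric table with columns `subject`, `group`,
#'   `condition`, `band`, `cost`, `metric`, `value`.
#' @param metric,band,cost Which slice to analyse.
#' @param mode `"crossed"` (default) or `"mixed"`.
#' @return Data frame with one row per effect (`group`, `condition`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, plus the slice identifiers.
#' @export
anova_2x2 <- function(table, metric, band, cost,
                      mode = c("crossed", "mixed")) {
  mode <- match.arg(mode)
  df <- metric_subset(table, metric, band, cost)
  df$group <- factor(df$group)
  df$condition <- factor(df$condition)
  df$subject <- factor(df$subject)
  if (nlevels(df$group) != 2L || nlevels(df$condition) != 2L) {
    stop("insufficient-data: need two groups and two conditions")
  }
  if (any(table(df$group, df$condition) == 0L)) {
    stop("insufficient-data: empty group x condition cell")
  }
  if (stats::var(df$value) == 0) {
    # all observations identical: no variance to partition
    res <- data.frame(effect = c("group", "condition", "interaction"),
                      F = 0, df1 = 1L,
                      df2 = if (mode == "crossed") nrow(df) - 4L else
                        nlevels(df$subject) - 2L,
                      p = 1)
    res$metric <- metric; res$band <- band; res$cost <- cost; res$mode <- mode
    return(res)
  }
  if (mode == "crossed") {
    aj <- stats::anova(stats::lm(value ~ group * condition, data = df))
    eff <- c("group", "condition", "group:condition")
    res <- data.frame(
      effect = c("group", "condition", "interaction"),
      F = aj[eff, "F value"], df1 = aj[eff, "Df"],
      df2 = aj["Residuals", "Df"], p = aj[eff, "Pr(>F)"])
  } else {
    fit <- stats::aov(value ~ group * condition + Error(subject), data = df)
    sm <- summary(fit)
    between <- sm[["Error: subject"]][[1L]]
    within <- sm[["Error: Within"]][[1L]]
    rn <- function(tab) trimws(rownames(tab))
    res <- data.frame(
      effect = c("group", "condition", "interaction"),
      F = c(between[rn(between) == "group", "F value"],
            within[rn(within) == "condition", "F value"],
            within[rn(within) == "group:condition", "F value"]),
      df1 = 1L,
      df2 = c(between[rn(between) == "Residuals", "Df"],
              rep(within[rn(within) == "Residuals", "Df"], 2L)),
      p = c(between[rn(between) == "group", "Pr(>F)"],
            within[rn(within) == "condition", "Pr(>F)"],
            within[rn(within) == "group:condition", "Pr(>F)"]))
  }
  # all-equal responses: lm reports NaN F; report F = 0, p = 1
  degen <- !is.finite(res$F)
  res$F[degen] <- 0
  res$p[degen] <- 1
  res$metric <- metric; res$band <- band; res$cost <- cost; res$mode <- mode
  rownames(res) <- NULL
  res
}

#' Post-hoc t-tests after the 2x2 ANOVA
#'
#' Paired t-tests of rest vs task within each group (pairing on subject id)
#' and two-sample t-tests between groups within each condition. A paired
#' contrast with zero variance of the differences is degenerate: it is
#' reported with `p = 1` (no evidence either way) and flagged.
#'
#' @inheritParams anova_2x2
#' @return Data frame with columns `contrast`, `t`, `df`, `p`, `degenerate`.
#' @export
posthoc_ttests <- function(table, metric, band, cost) {
  df <- metric_subset(table, metric, band, cost)
  out <- list()
  for (g in unique(df$group)) {
    a <- df[df$group == g & df$condition == "rest", ]
    b <- df[df$group == g & df$condition == "task", ]
    b <- b[match(a$subject, b$subject), ]
    if (nrow(a) < 2L || any(is.na(b$value))) {
      stop("insufficient-data: need paired rest/task values per subject")
    }
    d <- a$value - b$value
    if (stats::sd(d) == 0) {
      out[[paste0(g, ":rest-task")]] <- data.frame(
        contrast = paste0(g, ": rest vs task"), t = NA_real_,
        df = length(d) - 1L, p = 1, degenerate = TRUE)
    } else {
      tt <- stats::t.test(a$value, b$value, paired = TRUE)
      out[[paste0(g, ":rest-task")]] <- data.frame(
        contrast = paste0(g, ": rest vs task"), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
    }
  }
  for (cond in unique(df$condition)) {
    a <- df[df$condition == cond & df$group == sort(unique(df$group))[1L], ]
    b <- df[df$condition == cond & df$group == sort(unique(df$group))[2L], ]
    if (nrow(a) < 2L || nrow(b) < 2L) stop("insufficient-data: n < 2 per group")
    if (stats::sd(c(a$value, b$value)) == 0) {
      out[[paste0(cond, ":groups")]] <- data.frame(
        contrast = paste0(cond, ": between groups"), t = NA_real_,
        df = nrow(a) + nrow(b) - 2L, p = 1, degenerate = TRUE)
    } else {
      tt <- stats::t.test(a$value, b$value)
      out[[paste0(cond, ":groups")]] <- data.frame(
        contrast = paste0(cond, ": between groups"), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$metric <- metric; res$band <- band; res$cost <- cost
  rownames(res) <- NULL
  res
}

#' Z-score a per-node map
#'
#' Standardises one participant's nodal map across nodes: subtract the
#' across-node mean and divide by the across-node standard deviation
#' (population, divide-by-n, by default, which makes the unit-variance
#' invariant exact and the operation idempotent). Rank order of nodes is
#' preserved, and any affine transform of the input yields the same map.
#'
#' @param map Numeric per-node vector (>= 2 values).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Z-scored map; all zeros (with a warning) for a zero-variance map.
#' @export
zscore_map <- function(map, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.numeric(map), length(map) >= 2L)
  ctr <- map - mean(map)
  s <- sqrt(mean(ctr^2))
  if (sd_type == "sample") s <- stats::sd(map)
  if (s == 0) {
    warning("degenerate map: zero variance, returning zeros")
    return(map * 0)
  }
  ctr / s
}

#' Per-node significance tiers
#'
#' The three reporting thresholds used for nodal maps on an `n_nodes`-channel
#' montage: uncorrected `0.05`, false-positive correction `1/N`, and the
#' printed `0.05/N` threshold. The last is arithmetically a Bonferroni
#' threshold; it is labelled `fdr_label` here to avoid asserting it is a
#' false-discovery-rate procedure.
#'
#' @param n_nodes Number of nodes (N).
#' @return Named numeric vector `c(uncorrected, fpc, fdr_label)`.
#' @export
significance_tiers <- function(n_nodes) {
  c(uncorrected = 0.05, fpc = 1 / n_nodes, fdr_label = 0.05 / n_nodes)
}

#' Per-node 2x2 ANOVA of Z-scored nodal maps
#'
#' Z-scores each participant's map across nodes (see [zscore_map()]), runs
#' the group x condition ANOVA at every node, and flags each effect at the
#' three significance tiers.
#'
#' @param maps Long data frame with columns `subject`, `group`, `condition`,
#'   `node`, `value`; every participant/condition must cover the same node
#'   labels.
#' @param mode ANOVA mode, as in [anova_2x2()].
#' @param sd_type Z-scoring convention, as in [zscore_map()].
#' @return Data frame with one row per node and effect: `F`, `df1`, `df2`,
#'   `p`, logical tier flags `sig_uncorrected`, `sig_fpc`, `sig_fdr_label`,
#'   and the tier thresholds as attributes.
#' @export
nodal_tests <- function(maps, mode = c("crossed", "mixed"),
                        sd_type = c("population", "sample")) {
  mode <- match.arg(mode)
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("subject", "group", "condition", "node", "value")
                %in% names(maps)))
  nodes <- sort(unique(maps$node))
  key <- interaction(maps$subject, maps$condition, drop = TRUE)
  for (k in levels(key)) {
    rows <- key == k
    if (!setequal(maps$node[rows], nodes)) {
      stop("invalid-input: node labels differ across participants/conditions")
    }
    maps$value[rows] <- suppressWarnings(
      zscore_map(maps$value[rows][match(nodes, maps$node[rows])],
                 sd_type = sd_type))[match(maps$node[rows], nodes)]
  }
  tiers <- significance_tiers(length(nodes))
  res <- do.call(rbind, lapply(nodes, function(nd) {
    sl <- maps[maps$node == nd, ]
    sl$metric <- "z"; sl$band <- "z"; sl$cost <- 0
    a <- anova_2x2(sl, "z", "z", 0, mode = mode)
    a$node <- nd
    a
  }))
  res$sig_uncorrected <- res$p < tiers["uncorrected"]
  res$sig_fpc <- res$p < tiers["fpc"]
  res$sig_fdr_label <- res$p < tiers["fdr_label"]
  res$metric <- NULL; res$band <- NULL; res$cost <- NULL
  attr(res, "tiers") <- tiers
  res
}

#' Pearson correlation between a metric and disease duration, per cost
#'
#' For every grid cost and condition, the Pearson correlation (with
#' two-sided p) across patients between the metric value and the
#' duration-of-disease covariate. A constant metric leaves R undefined and
#' is flagged.
#'
#' @param table Long metric table restricted or restrictable to patients.
#' @param durations Data frame with columns `id` (or `subject`) and
#'   `duration_years`.
#' @param metric,band Which metric/band to correlate.
#' @param costs Costs to evaluate (defaults to all costs present).
#' @return Data frame with columns `cost`, `condition`, `n`, `R`, `p`,
#'   `degenerate`.
#' @export
duration_correlation <- function(table, durations, metric, band,
                                 costs = NULL) {
  if ("id" %in% names(durations) && !"subject" %in% names(durations)) {
    durations$subject <- durations$id
  }
  tab <- table[table$metric == metric & table$band == band, , drop = FALSE]
  tab <- tab[tab$subject %in% durations$subject[
    !is.na(durations$duration_years)], , drop = FALSE]
  if (is.null(costs)) costs <- sort(unique(tab$cost))
  out <- list()
  for (cc in costs) {
    for (cond in sort(unique(tab$condition))) {
      sl <- tab[abs(tab$cost - cc) < 1e-9 & tab$condition == cond, ]
      dur <- durations$duration_years[match(sl$subject, durations$subject)]
      keep <- !is.na(dur)
      sl <- sl[keep, ]; dur <- dur[keep]
      if (nrow(sl) < 3L) stop("insufficient-data: need >= 3 patients with durations")
      if (stats::sd(sl$value) == 0 || stats::sd(dur) == 0) {
        out[[paste(cc, cond)]] <- data.frame(
          cost = cc, condition = cond, n = nrow(sl), R = NA_real_,
          p = NA_real_, degenerate = TRUE)
      } else {
        ct <- stats::cor.test(sl$value, dur)
        out[[paste(cc, cond)]] <- data.frame(
          cost = cc, condition = cond, n = nrow(sl),
          R = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res$metric <- metric; res$band <- band
  rownames(res) <- NULL
  res
}
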