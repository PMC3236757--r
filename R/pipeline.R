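# Orchestration: a validated config drives simulate -> connect -> analyze,
# with deterministic seeded outputs on disk. The in-memory helpers
# (cohort_connectivity / cohort_metric_table / cohort_nodal_maps) are the
# computational core; the run_* functions add file IO, checksums and
# resumability around them.

pipeline_config_keys <- c("simulation", "wavelet", "mi", "costs", "nulls",
                          "stats_mode", "seed", "out_dir")

#' Pipeline configuration
#'
#' Assembles and validates the end-to-end configuration. Unknown keys are
#' rejected. `simulation` holds overrides for [sim_config()] (plus an
#' optional `preset`/`desk` switch), `wavelet` the Morlet parameters,
#' `mi` the estimator parameters, `costs` the grid limits, `nulls` the
#' ensemble size, `stats_mode` the ANOVA mode.
#'
#' @param simulation,wavelet,mi,costs,nulls Named lists of stage settings.
#' @param stats_mode `"crossed"` or `"mixed"`.
#' @param seed Integer master seed.
#' @param out_dir Output directory for the run.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), wavelet = list(),
                            mi = list(), costs = list(), nulls = list(),
                            stats_mode = c("crossed", "mixed"),
                            seed = 1L, out_dir = "eegcostnet-run") {
  stats_mode <- match.arg(stats_mode)
  cfg <- list(
    simulation = simulation,
    wavelet = utils::modifyList(list(omega0 = 6, voices_per_octave = 4,
                                     output = "real"), wavelet),
    mi = utils::modifyList(list(n_bins = 16L, concatenate_epochs = FALSE), mi),
    costs = utils::modifyList(list(from = 0.16, to = 0.50, by = 0.02), costs),
    nulls = utils::modifyList(list(n_draws = 20L), nulls),
    stats_mode = stats_mode, seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown)) stop("config error: unknown keys: ",
                            paste(unknown, collapse = ", "))
  for (sub in c("wavelet", "mi", "costs", "nulls")) {
    known <- switch(sub,
      wavelet = c("omega0", "voices_per_octave", "output"),
      mi = c("n_bins", "concatenate_epochs"),
      costs = c("from", "to", "by"),
      nulls = c("n_draws"))
    bad <- setdiff(names(cfg[[sub]]), known)
    if (length(bad)) stop("config error: unknown keys in ", sub, ": ",
                          paste(bad, collapse = ", "))
  }
  stopifnot(cfg$wavelet$omega0 > 0, cfg$wavelet$voices_per_octave >= 1,
            cfg$mi$n_bins >= 2, cfg$nulls$n_draws >= 1,
            cfg$costs$from > 0, cfg$costs$to <= 1,
            cfg$costs$from < cfg$costs$to, cfg$costs$by > 0)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; `.json` is parsed with jsonlite, anything else
#'   with yaml.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

run_dir <- function(cfg) {
  file.path(cfg$out_dir, sprintf("run-%s-seed%d", config_hash(cfg), cfg$seed))
}

build_sim_config <- function(cfg) {
  sim <- cfg$simulation
  desk <- isTRUE(sim$desk)
  sim$desk <- NULL
  sim$seed <- sim$seed %||% cfg$seed
  if (desk) do.call(desk_config, sim) else do.call(sim_config, sim)
}

#' Run the simulation stage
#'
#' Simulates the configured cohort and writes it (recordings, manifest,
#' ground truth) under `<out_dir>/run-<confighash>-seed<seed>/cohort/`.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The cohort directory path, invisibly.
#' @export
run_simulate <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir <- file.path(run_dir(cfg), "cohort")
  cohort <- simulate_cohort(build_sim_config(cfg))
  write_cohort(cohort, dir)
  info <- list(stage = "simulate", seed = cfg$seed, hash = config_hash(cfg),
               n_recordings = length(cohort$recordings))
  jsonlite::write_json(info, file.path(dir, "run_info.json"),
                       auto_unbox = TRUE)
  if (!quiet) message(sprintf("simulate: %d recordings -> %s",
                              length(cohort$recordings), dir))
  invisible(dir)
}

#' Preprocess one recording and estimate its per-band MI matrices
#'
#' The per-recording pipeline: optional linked-earlobe re-reference (when an
#' A1 channel is present) and decimation, epoching, linear detrend, Morlet
#' band decomposition, and MI association matrices.
#'
#' @param rec An [recording()].
#' @param bands Named list of [band()]s.
#' @param n_epochs,epoch_len Epoching parameters.
#' @param wavelet,mi Parameter lists as in [pipeline_config()].
#' @param a1_label Optional A1 channel label to re-reference against.
#' @param downsample_factor Integer decimation factor applied before
#'   epoching.
#' @return Named list of `mi_matrix`, one per band.
#' @export
recording_band_mi <- function(rec, bands, n_epochs, epoch_len,
                              wavelet = list(omega0 = 6, voices_per_octave = 4,
                                             output = "real"),
                              mi = list(n_bins = 16L,
                                        concatenate_epochs = FALSE),
                              a1_label = NULL, downsample_factor = 1L) {
  if (!is.null(a1_label) && a1_label %in% rec$labels) {
    rec <- rereference_linked_earlobes(rec, a1_label)
  }
  if (downsample_factor > 1L) rec <- downsample(rec, downsample_factor)
  ep <- detrend_linear(extract_epochs(rec, n_epochs, epoch_len))
  out <- lapply(bands, function(b) {
    bs <- morlet_band_series(ep, b, omega0 = wavelet$omega0,
                             voices_per_octave = wavelet$voices_per_octave,
                             output = wavelet$output)
    association_matrix(bs, n_bins = mi$n_bins,
                       concatenate_epochs = isTRUE(mi$concatenate_epochs))
  })
  names(out) <- vapply(bands, function(b) b$name, character(1L))
  out
}

#' Per-band association matrices for a whole cohort (in memory)
#'
#' Epochs, detrends and band-decomposes every recording of a simulated
#' cohort, then estimates the MI association matrix per band.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param bands Bands to analyse (defaults to the cohort's simulated bands).
#' @param n_bins MI bins.
#' @param omega0,voices_per_octave Morlet parameters.
#' @return Nested list: `mi[[<id>.<condition>]][[<band>]]`.
#' @export
cohort_connectivity <- function(cohort, bands = NULL, n_bins = 16L,
                                omega0 = 6, voices_per_octave = 4) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  bands <- bands %||% cohort$config$bands
  lapply(cohort$recordings, recording_band_mi,
         bands = bands, n_epochs = cohort$config$n_epochs,
         epoch_len = cohort$config$epoch_len,
         wavelet = list(omega0 = omega0,
                        voices_per_octave = voices_per_octave,
                        output = "real"),
         mi = list(n_bins = n_bins, concatenate_epochs = FALSE))
}

#' Long metric table from cohort association matrices
#'
#' Thresholds every subject/condition/band MI matrix over the cost grid and
#' evaluates the requested global metrics, returning the long table consumed
#' by [anova_2x2()], [posthoc_ttests()] and [duration_correlation()].
#'
#' @param mi_list Output of [cohort_connectivity()].
#' @param manifest Cohort manifest (for the group column).
#' @param costs Cost grid.
#' @param metrics Subset of `c("Eglob", "Elocal")` plus derived `"CE"`.
#' @return Data frame with columns `subject`, `group`, `condition`, `band`,
#'   `cost`, `metric`, `value`.
#' @export
cohort_metric_table <- function(mi_list, manifest, costs = cost_grid(),
                                metrics = c("Eglob", "Elocal", "CE")) {
  metrics <- match.arg(metrics, c("Eglob", "Elocal", "CE"), several.ok = TRUE)
  base_metrics <- unique(c(intersect(metrics, c("Eglob", "Elocal")),
                           if ("CE" %in% metrics) "Eglob"))
  rows <- list()
  for (nm in names(mi_list)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    grp <- manifest$group[match(parts[1L], manifest$id)]
    for (bn in names(mi_list[[nm]])) {
      cur <- metric_curves(mi_list[[nm]][[bn]], costs,
                           metrics = base_metrics)
      for (met in metrics) {
        vals <- switch(met, CE = cur$Eglob - cur$cost, cur[[met]])
        rows[[paste(nm, bn, met)]] <- data.frame(
          subject = parts[1L], group = grp, condition = parts[2L],
          band = bn, cost = cur$cost, metric = met, value = vals,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Max cost-efficiency per subject/condition/band
#'
#' @param table Long metric table containing `Eglob` rows over a grid.
#' @return Data frame with one `maxCE` row per subject/condition/band
#'   (cost set to `NA`; `argmax_cost` carried alongside).
#' @export
maxce_table <- function(table) {
  eg <- table[table$metric == "Eglob", ]
  sp <- split(eg, interaction(eg$subject, eg$condition, eg$band, drop = TRUE))
  out <- do.call(rbind, lapply(sp, function(sl) {
    sl <- sl[order(sl$cost), ]
    ce <- cost_efficiency_curve(sl$value, sl$cost)
    data.frame(subject = sl$subject[1L], group = sl$group[1L],
               condition = sl$condition[1L], band = sl$band[1L],
               cost = NA_real_, metric = "maxCE", value = ce$max_ce,
               argmax_cost = ce$argmax_cost, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Nodal maps (degree or nodal efficiency) at one cost
#'
#' @param mi_list Output of [cohort_connectivity()].
#' @param manifest Cohort manifest.
#' @param band Band name.
#' @param cost Network cost at which to threshold.
#' @param metric `"Enodal"` or `"degree"`.
#' @return Long data frame `subject`, `group`, `condition`, `node`, `value`
#'   (raw, not yet Z-scored; [nodal_tests()] Z-scores internally).
#' @export
cohort_nodal_maps <- function(mi_list, manifest, band, cost,
                              metric = c("Enodal", "degree")) {
  metric <- match.arg(metric)
  rows <- list()
  for (nm in names(mi_list)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    grp <- manifest$group[match(parts[1L], manifest$id)]
    g <- threshold_by_cost(mi_list[[nm]][[band]], cost)
    vals <- if (metric == "Enodal") nodal_efficiency(g) else rowSums(g$adj)
    labs <- rownames(g$adj) %||% paste0("ch", seq_len(g$n))
    rows[[nm]] <- data.frame(subject = parts[1L], group = grp,
                             condition = parts[2L], node = labs,
                             value = as.numeric(vals),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_cohort_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("data error: no manifest.csv in ", dir)
  manifest <- as.data.frame(data.table::fread(man_path))
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(file.path(dir, manifest$file[i]))
  })
  names(recs) <- paste(manifest$id, manifest$condition, sep = ".")
  list(manifest = manifest, recordings = recs)
}

#' Run the connectivity stage
#'
#' Reads the cohort written by [run_simulate()], preprocesses every
#' recording and writes one MI matrix CSV per subject/condition/band, plus
#' an `mi_index.json` with md5 checksums. Existing outputs are skipped
#' unless `force = TRUE`.
#'
#' @param cfg A [pipeline_config()].
#' @param force Recompute outputs that already exist.
#' @param quiet Suppress progress messages.
#' @return The MI directory path, invisibly.
#' @export
run_connect <- function(cfg, force = FALSE, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- build_sim_config(cfg)
  base <- run_dir(cfg)
  cdir <- file.path(base, "cohort")
  mdir <- file.path(base, "mi")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  cohort_files <- read_cohort_dir(cdir)
  bands <- sim$bands
  index <- list()
  n_skip <- 0L
  for (nm in names(cohort_files$recordings)) {
    paths <- file.path(mdir, sprintf("mi_%s_%s.csv", gsub(".", "_", nm, fixed = TRUE),
                                     names(bands)))
    names(paths) <- names(bands)
    if (!force && all(file.exists(paths))) {
      n_skip <- n_skip + 1L
      for (bn in names(bands)) index[[basename(paths[[bn]])]] <-
          unname(tools::md5sum(paths[[bn]]))
      next
    }
    mi <- recording_band_mi(cohort_files$recordings[[nm]], bands,
                            n_epochs = sim$n_epochs,
                            epoch_len = sim$epoch_len,
                            wavelet = cfg$wavelet, mi = cfg$mi)
    for (bn in names(bands)) {
      write_mi_matrix(mi[[bn]], paths[[bn]])
      index[[basename(paths[[bn]])]] <- unname(tools::md5sum(paths[[bn]]))
    }
  }
  jsonlite::write_json(index, file.path(mdir, "mi_index.json"),
                       auto_unbox = TRUE)
  if (!quiet) message(sprintf("connect: %d recordings (%d skipped) -> %s",
                              length(cohort_files$recordings), n_skip, mdir))
  invisible(mdir)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

anova_report <- function(table, metric, band, costs, mode) {
  do.call(rbind, lapply(costs, function(cc) {
    a <- anova_2x2(table, metric, band, cc, mode = mode)
    sl <- metric_subset(table, metric, band, cc)
    cells <- stats::aggregate(value ~ group + condition, sl,
                              function(v) c(mean = mean(v), sem = sem(v)))
    for (r in seq_len(nrow(cells))) {
      key <- paste(cells$group[r], cells$condition[r], sep = "_")
      a[[paste0(key, "_mean")]] <- cells$value[r, "mean"]
      a[[paste0(key, "_sem")]] <- cells$value[r, "sem"]
    }
    a
  }))
}

#' Run the analysis stage
#'
#' Reads the MI matrices written by [run_connect()] (verifying checksums),
#' builds the metric curves and tables, determines the small-world regime
#' per band (bands with no valid regime are excluded from statistics, with a
#' warning), and writes per-cost ANOVA tables, nodal-map test tables,
#' duration-correlation tables, per-band regime JSON and a run summary with
#' the cost of maximal interaction.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The analysis directory path, invisibly.
#' @export
run_analyze <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- build_sim_config(cfg)
  base <- run_dir(cfg)
  mdir <- file.path(base, "mi")
  adir <- file.path(base, "analysis")
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(base, "cohort", "manifest.csv")
  if (!file.exists(man_path)) stop("data error: no cohort manifest at ", man_path)
  manifest <- as.data.frame(data.table::fread(man_path))
  index_path <- file.path(mdir, "mi_index.json")
  if (!file.exists(index_path)) stop("data error: run_connect has not been run")
  index <- jsonlite::read_json(index_path, simplifyVector = TRUE)
  for (f in names(index)) {
    path <- file.path(mdir, f)
    if (!file.exists(path)) stop("data error: missing MI file ", f)
    if (!identical(unname(tools::md5sum(path)), index[[f]])) {
      stop("data error: checksum failure for ", f)
    }
  }
  bands <- names(sim$bands)
  keys <- unique(paste(manifest$id, manifest$condition, sep = "."))
  mi_list <- lapply(keys, function(nm) {
    per_band <- lapply(bands, function(bn) {
      read_mi_matrix(file.path(mdir, sprintf(
        "mi_%s_%s.csv", gsub(".", "_", nm, fixed = TRUE), bn)))
    })
    names(per_band) <- bands
    per_band
  })
  names(mi_list) <- keys

  costs <- cost_grid(cfg$costs$from, cfg$costs$to, cfg$costs$by)
  man1 <- manifest[!duplicated(manifest$id), ]
  tab <- cohort_metric_table(mi_list, man1, costs,
                             metrics = c("Eglob", "Elocal", "CE"))
  data.table::fwrite(tab, file.path(adir, "metric_curves.csv"))

  nulls <- null_ensemble_grid(sim$n_channels, costs,
                              n_draws = cfg$nulls$n_draws,
                              seed = derive_seeds(cfg$seed, 1L, stream = 5L))
  summary_list <- list(seed = cfg$seed, hash = config_hash(cfg), bands = list())
  valid_bands <- character()
  for (bn in bands) {
    # regime from each group's mean curves; the band is valid when both
    # groups' curves sit strictly between the null families
    qual <- rep(TRUE, length(costs))
    regimes <- list()
    for (grp in unique(man1$group)) {
      sub <- tab[tab$band == bn & tab$group == grp, ]
      eg <- stats::aggregate(value ~ cost, sub[sub$metric == "Eglob", ], mean)
      el <- stats::aggregate(value ~ cost, sub[sub$metric == "Elocal", ], mean)
      rg <- small_world_regime(eg$value[order(eg$cost)],
                               el$value[order(el$cost)],
                               nulls, costs, band = bn)
      regimes[[grp]] <- rg
      qual <- qual & rg$qualifies
    }
    valid <- any(qual)
    i0 <- if (valid) which(qual)[1L] else NA_integer_
    len <- if (valid) which.min(c(qual[i0:length(qual)], FALSE)) - 1L else 0L
    regime <- list(band = bn, valid = valid, excluded = !valid,
                   c_low = if (valid) costs[i0] else NA,
                   c_high = if (valid) costs[i0 + len - 1L] else NA)
    jsonlite::write_json(regime, file.path(adir, sprintf("regime_%s.json", bn)),
                         auto_unbox = TRUE, digits = NA)
    summary_list$bands[[bn]] <- regime
    if (valid) valid_bands <- c(valid_bands, bn)
  }
  if (length(valid_bands) == 0L) {
    warning("no band has a valid small-world regime; statistics skipped")
  }

  for (bn in valid_bands) {
    rep_eg <- anova_report(tab, "Eglob", bn, costs, cfg$stats_mode)
    data.table::fwrite(rep_eg, file.path(adir, sprintf("anova_Eglob_%s.csv", bn)))
    inter <- rep_eg[rep_eg$effect == "interaction", ]
    c_star <- inter$cost[which.min(inter$p)]
    summary_list$bands[[bn]]$max_interaction_cost <- c_star
    summary_list$bands[[bn]]$max_interaction_F <-
      inter$F[which.min(inter$p)]
    summary_list$bands[[bn]]$max_interaction_p <- min(inter$p)

    ph <- posthoc_ttests(tab, "Eglob", bn, c_star)
    data.table::fwrite(ph, file.path(adir, sprintf("posthoc_Eglob_%s.csv", bn)))

    mx <- maxce_table(tab[tab$band == bn, ])
    mx$cost <- 0
    amx <- anova_2x2(mx, "maxCE", bn, 0, mode = cfg$stats_mode)
    data.table::fwrite(amx, file.path(adir, sprintf("anova_maxCE_%s.csv", bn)))

    for (nodal_metric in c("Enodal", "degree")) {
      maps <- cohort_nodal_maps(mi_list, man1, bn, c_star, nodal_metric)
      nt <- nodal_tests(maps, mode = cfg$stats_mode)
      data.table::fwrite(nt, file.path(
        adir, sprintf("nodal_%s_%s.csv", nodal_metric, bn)))
    }

    pats <- man1[man1$group == "patient" & !is.na(man1$duration_years), ]
    if (nrow(pats) >= 3L) {
      for (met in c("Eglob", "Elocal")) {
        dc <- duration_correlation(tab, pats, met, bn, costs)
        wide <- stats::reshape(
          dc[, c("cost", "condition", "R", "p")], direction = "wide",
          idvar = "cost", timevar = "condition")
        data.table::fwrite(wide, file.path(
          adir, sprintf("duration_correlation_%s_%s.csv", met, bn)))
      }
      dmx <- duration_correlation(
        transform(mx, cost = 0), pats, "maxCE", bn, 0)
      data.table::fwrite(dmx, file.path(
        adir, sprintf("duration_correlation_maxCE_%s.csv", bn)))
    }
  }
  jsonlite::write_json(summary_list, file.path(adir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!quiet) message(sprintf("analyze: bands valid: %s -> %s",
                              paste(valid_bands, collapse = ", "), adir))
  invisible(adir)
}
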