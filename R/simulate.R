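# Synthetic EEG-like cohort generator.
#
# Source model: each channel carries a narrowband AR(2) oscillation per band
# (pole radius ar_r, peak frequency jittered around the band centre), and
# coupling injects neighbours' oscillations along topology edges:
#   x = o + W o + noise,  W = backbone * A_lattice + strength * A_shortcut.
# The backbone is a short-range ring lattice at fixed strength; the tunable
# strength acts on the long-range (rewired) shortcut edges. At analysis costs
# below the backbone density, shortcut strength controls how many shortcuts
# displace lattice edges in the thresholded graph, so stronger long-range
# coupling yields more integrated (higher-Eglob) networks -- the knob that
# carries the planted group-by-condition and duration effects.

ar2_series <- function(n, f0, fs, r = 0.95, innovations = NULL) {
  phi <- c(2 * r * cos(2 * pi * f0 / fs), -r^2)
  burn <- 200L
  if (is.null(innovations)) innovations <- stats::rnorm(n + burn)
  x <- stats::filter(innovations, phi, method = "recursive")
  x <- as.numeric(x)[(burn + 1L):(burn + n)]
  x / stats::sd(x)
}

#' Simulate a band-limited coupled multichannel recording
#'
#' Every channel is a unit-variance narrowband AR(2) oscillation with peak
#' frequency inside `band`; the shared signal of each channel's neighbours is
#' injected along the topology edges, scaled by `strength`, and white noise
#' of standard deviation `noise_sd` is added:
#' `x = o + strength * A %*% o + noise`.
#'
#' Pairwise correlation across an edge rises with `strength` up to the
#' turnover `sqrt((1 + noise_sd^2)/degree)`; keep strengths below that value
#' when a monotone strength/MI relationship is wanted.
#'
#' @param topology Symmetric zero-diagonal adjacency (or non-negative weight)
#'   matrix, or an [adjacency_graph()].
#' @param band A [band()]; must lie below the Nyquist frequency.
#' @param strength Non-negative scalar multiplying the topology weights.
#' @param n_samples Number of samples to generate.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param seed Optional integer seed; the output is bit-identical for equal
#'   seed and arguments.
#' @param ar_r AR(2) pole radius in (0, 1); closer to 1 gives a narrower
#'   oscillation.
#' @return An [recording()], channels x samples.
#' @export
simulate_coupled_recording <- function(topology, band, strength, n_samples,
                                       fs, noise_sd = 1, seed = NULL,
                                       ar_r = 0.95) {
  if (inherits(topology, "adjacency_graph")) topology <- topology$adj
  topology <- as.matrix(topology)
  n <- nrow(topology)
  stopifnot(inherits(band, "eeg_band"), n >= 2, n_samples >= 1,
            strength >= 0, noise_sd >= 0)
  if (!isTRUE(all.equal(topology, t(topology))) || any(diag(topology) != 0)) {
    stop("invalid-input: topology must be symmetric with zero diagonal")
  }
  if (band$high >= fs / 2) stop("invalid-band: band high >= Nyquist")
  gen <- function() {
    o <- band_oscillators(n, n_samples, band, fs, ar_r)
    x <- o + (strength * topology) %*% o +
      noise_sd * matrix(stats::rnorm(n * n_samples), n, n_samples)
    recording(x, fs, reference = "simulated")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Independent per-channel oscillators for one band; peak frequencies are
# jittered over the middle half of the band so channels are spectrally alike
# but not identical.
band_oscillators <- function(n, n_samples, band, fs, ar_r) {
  centre <- (band$low + band$high) / 2
  width <- band$high - band$low
  f0 <- centre + (stats::runif(n) - 0.5) * width / 2
  t(vapply(f0, function(f) ar2_series(n_samples, f, fs, ar_r),
           numeric(n_samples)))
}

# Ring-lattice + shortcut decomposition of a WS topology: each lattice edge
# is rewired with probability rewire_p into a long-range shortcut (lower
# endpoint kept, other endpoint redrawn among free nodes).
ws_topology <- function(n, m, rewire_p) {
  lat <- regular_lattice_matched(n, m)$adj
  short <- matrix(0, n, n)
  adj <- lat
  edges <- which(upper.tri(lat) & lat == 1, arr.ind = TRUE)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    if (stats::runif(1) >= rewire_p) next
    i <- edges[e, 1L]; j <- edges[e, 2L]
    free <- setdiff(which(adj[i, ] == 0), i)
    if (length(free) == 0L) next
    j2 <- free[sample.int(length(free), 1L)]
    adj[i, j] <- adj[j, i] <- 0
    lat[i, j] <- lat[j, i] <- 0
    adj[i, j2] <- adj[j2, i] <- 1
    short[i, j2] <- short[j2, i] <- 1
  }
  list(lattice = lat, shortcuts = short)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of [simulate_cohort()]. The
#' defaults are the full study conditions: 58 channels at 500 Hz, 5 epochs of
#' 10 s per subject and condition, 15 subjects per group, two conditions,
#' patient durations uniform on 2--25 years, and a beta-band coupling
#' strength carrying a group-by-condition interaction (controls strengthen
#' long-range coupling during the task, patients weaken it) plus a negative
#' duration slope in patients. The `"null"` preset sets all four cell
#' strengths equal (no interaction, no duration effect); use it for type-I
#' error calibration.
#'
#' @param n_channels,fs,epoch_len,n_epochs,n_per_group Cohort geometry.
#' @param bands Named list of [band()]s to synthesise (alpha/beta/gamma by
#'   default; the planted effects act on `beta`).
#' @param coupling_topology List with `model` (`"ws"`, `"random"` or
#'   `"regular"`), `cost` (topology density as a fraction of all pairs) and
#'   `rewire_p` (WS rewiring probability; ignored for the other models).
#' @param coupling_strength Named list of beta shortcut strengths
#'   `control_rest`, `control_task`, `patient_rest`, `patient_task`.
#' @param backbone_strength Strength of the fixed lattice backbone.
#' @param alpha_strength,gamma_strength Uniform (all cells equal) coupling of
#'   the other bands; gamma defaults to 0, leaving its networks noise-driven.
#' @param duration_slope Signed change of patient beta strength per year of
#'   disease duration (negative by default).
#' @param duration_range Uniform range (years) for patient durations.
#' @param noise_sd Additive white-noise standard deviation.
#' @param ar_r AR(2) pole radius of the oscillators.
#' @param seed Master seed; per-subject streams are derived from it by a
#'   counter scheme, so cohorts are reproducible subject-by-subject.
#' @param preset `"interaction"` (default) keeps the strengths above;
#'   `"null"` replaces them with a common value.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 58L, fs = 500, epoch_len = 10,
                       n_epochs = 5L, n_per_group = 15L,
                       bands = eeg_bands(),
                       coupling_topology = list(model = "ws", cost = 0.40,
                                                rewire_p = 0.10),
                       coupling_strength = list(control_rest = 0.10,
                                                control_task = 0.30,
                                                patient_rest = 0.32,
                                                patient_task = 0.26),
                       backbone_strength = 0.15,
                       alpha_strength = 0.15, gamma_strength = 0,
                       duration_slope = -0.004,
                       duration_range = c(2, 25),
                       noise_sd = 0.5, ar_r = 0.95, seed = 1L,
                       preset = c("interaction", "null")) {
  preset <- match.arg(preset)
  if (preset == "null") {
    s0 <- mean(unlist(coupling_strength))
    coupling_strength <- list(control_rest = s0, control_task = s0,
                              patient_rest = s0, patient_task = s0)
    duration_slope <- 0
  }
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              epoch_len = epoch_len, n_epochs = as.integer(n_epochs),
              n_per_group = as.integer(n_per_group), bands = bands,
              coupling_topology = coupling_topology,
              coupling_strength = coupling_strength,
              backbone_strength = backbone_strength,
              alpha_strength = alpha_strength,
              gamma_strength = gamma_strength,
              duration_slope = duration_slope,
              duration_range = duration_range,
              noise_sd = noise_sd, ar_r = ar_r, seed = as.integer(seed),
              preset = preset)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_channels >= 2, cfg$fs > 0, cfg$epoch_len > 0,
            cfg$n_epochs >= 1, cfg$n_per_group >= 2)
  if (abs(cfg$epoch_len * cfg$fs - round(cfg$epoch_len * cfg$fs)) > 1e-8) {
    stop("invalid-input: epoch_len * fs must be an integer sample count")
  }
  ct <- cfg$coupling_topology
  stopifnot(ct$model %in% c("ws", "random", "regular"),
            ct$cost > 0, ct$cost < 1)
  if (identical(ct$model, "ws")) stopifnot(ct$rewire_p >= 0, ct$rewire_p <= 1)
  s <- cfg$coupling_strength
  stopifnot(setequal(names(s), c("control_rest", "control_task",
                                 "patient_rest", "patient_task")),
            all(unlist(s) >= 0), cfg$backbone_strength >= 0,
            cfg$alpha_strength >= 0, cfg$gamma_strength >= 0,
            cfg$noise_sd >= 0, cfg$ar_r > 0, cfg$ar_r < 1,
            length(cfg$duration_range) == 2L,
            cfg$duration_range[1] >= 0,
            diff(cfg$duration_range) >= 0)
  invisible(cfg)
}

#' Desk-scale validation configuration
#'
#' A reduced cohort used by the statistical-calibration and recovery checks:
#' 24 channels at 125 Hz, 4 epochs of 4 s, beta band only, a sparser lattice
#' (density 0.24) analysed on the matching sparser grid [desk_cost_grid()],
#' and coupling strengths re-balanced for the smaller lattice degree (the
#' correlation turnover scales as `1/sqrt(degree)`, so the usable strength
#' range widens when the lattice is sparser). Planted directions are the
#' same as in the full [sim_config()].
#'
#' @param preset `"interaction"` or `"null"`, as in [sim_config()].
#' @param n_per_group Subjects per group (default 15).
#' @param seed Master seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
desk_config <- function(preset = c("interaction", "null"), n_per_group = 15L,
                        seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- utils::modifyList(list(
    n_channels = 24L, fs = 125, epoch_len = 4, n_epochs = 2L,
    n_per_group = n_per_group,
    bands = eeg_bands()["beta"],
    coupling_topology = list(model = "ws", cost = 0.24, rewire_p = 0.22),
    coupling_strength = list(control_rest = 0.22, control_task = 0.55,
                             patient_rest = 0.60, patient_task = 0.48),
    backbone_strength = 0.30,
    alpha_strength = 0, gamma_strength = 0,
    duration_slope = -0.010,
    noise_sd = 0.5, ar_r = 0.90, seed = seed, preset = preset),
    list(...))
  do.call(sim_config, args)
}

#' Cost grid matched to the desk-scale configuration
#'
#' The sparser analysis grid used with [desk_config()] cohorts: 0.08--0.24
#' in steps of 0.02, whose midpoint (0.16) lies below the desk lattice
#' density, so shortcut strength acts by displacing lattice edges at every
#' grid cost.
#'
#' @return Strictly increasing numeric vector.
#' @export
desk_cost_grid <- function() cost_grid(0.08, 0.24, 0.02)

#' Cost at the middle of a grid
#'
#' @param costs Cost grid.
#' @return The middle grid value (`costs[ceiling(length/2)]`).
#' @export
mid_grid_cost <- function(costs = cost_grid()) {
  costs[ceiling(length(costs) / 2)]
}

cell_strength <- function(cfg, group, condition, duration) {
  base <- cfg$coupling_strength[[paste(group, condition, sep = "_")]]
  s <- if (group == "patient") base + cfg$duration_slope * duration else base
  if (s < 0) {
    warning(sprintf("coupling strength clipped to 0 (%s/%s, duration %.1f)",
                    group, condition, duration))
    s <- 0
  }
  s
}

#' Simulate a synthetic cohort
#'
#' Generates one multichannel recording per subject and condition under the
#' study conditions in `config`, with a shared coupling topology per cohort
#' and per-subject beta shortcut strengths
#' `base(group, condition) + duration_slope * duration` (patients; floored at
#' 0 with a warning). The manifest lists id, group, duration (patients only)
#' and age; the ground truth records the lattice/shortcut topology and every
#' per-subject strength actually used.
#'
#' @param config A [sim_config()].
#' @return Object of class `cohort_dataset`: list with `recordings` (named
#'   `id.condition`), `manifest`, `conditions`, `ground_truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_channels
  p_max <- n * (n - 1) / 2
  m <- as.integer(round(cfg$coupling_topology$cost * p_max))
  cohort_seed <- derive_seeds(cfg$seed, 1L, stream = 0L)

  topo <- withr::with_seed(cohort_seed, {
    switch(cfg$coupling_topology$model,
      ws = ws_topology(n, m, cfg$coupling_topology$rewire_p),
      random = list(lattice = random_graph_matched(n, m)$adj,
                    shortcuts = matrix(0, n, n)),
      regular = list(lattice = regular_lattice_matched(n, m)$adj,
                     shortcuts = matrix(0, n, n)))
  })

  n_g <- cfg$n_per_group
  manifest <- data.frame(
    id = c(sprintf("P%02d", seq_len(n_g)), sprintf("C%02d", seq_len(n_g))),
    group = rep(c("patient", "control"), each = n_g),
    stringsAsFactors = FALSE)
  demo_seed <- derive_seeds(cfg$seed, 1L, stream = 2L)
  manifest <- withr::with_seed(demo_seed, {
    manifest$duration_years <- ifelse(
      manifest$group == "patient",
      stats::runif(nrow(manifest), cfg$duration_range[1], cfg$duration_range[2]),
      NA_real_)
    manifest$age <- round(stats::runif(nrow(manifest), 30, 65), 1)
    manifest
  })

  conditions <- c("rest", "task")
  n_samples <- as.integer(round(cfg$n_epochs * cfg$epoch_len * cfg$fs))
  rec_seeds <- derive_seeds(cfg$seed, nrow(manifest) * length(conditions),
                            stream = 1L)
  recordings <- list()
  strengths <- list()
  k <- 0L
  for (si in seq_len(nrow(manifest))) {
    for (cond in conditions) {
      k <- k + 1L
      grp <- manifest$group[si]
      dur <- manifest$duration_years[si]
      s_beta <- cell_strength(cfg, grp, cond,
                              if (is.na(dur)) 0 else dur)
      recordings[[paste(manifest$id[si], cond, sep = ".")]] <-
        simulate_cohort_recording(cfg, topo, s_beta, n_samples, rec_seeds[k])
      strengths[[k]] <- data.frame(id = manifest$id[si], condition = cond,
                                   band = "beta", strength = s_beta,
                                   stringsAsFactors = FALSE)
    }
  }

  structure(list(
    recordings = recordings,
    manifest = manifest,
    conditions = conditions,
    ground_truth = list(lattice = topo$lattice, shortcuts = topo$shortcuts,
                        backbone_strength = cfg$backbone_strength,
                        strengths = do.call(rbind, strengths)),
    config = cfg), class = "cohort_dataset")
}

# One subject/condition recording: sum of per-band coupled oscillator fields
# plus a single white-noise term.
simulate_cohort_recording <- function(cfg, topo, s_beta, n_samples, seed) {
  n <- cfg$n_channels
  withr::with_seed(seed, {
    x <- matrix(0, n, n_samples)
    for (bn in names(cfg$bands)) {
      w <- switch(bn,
        beta = cfg$backbone_strength * topo$lattice + s_beta * topo$shortcuts,
        alpha = cfg$alpha_strength * (topo$lattice + topo$shortcuts),
        gamma = cfg$gamma_strength * (topo$lattice + topo$shortcuts),
        matrix(0, n, n))
      o <- band_oscillators(n, n_samples, cfg$bands[[bn]], cfg$fs, cfg$ar_r)
      x <- x + o + w %*% o
    }
    x <- x + cfg$noise_sd * matrix(stats::rnorm(n * n_samples), n, n_samples)
    recording(x, cfg$fs, reference = "simulated")
  })
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(paste0("<cohort_dataset> %d subjects x %d conditions ",
                     "(%d recordings), %d channels @ %g Hz, preset '%s'\n"),
              nrow(x$manifest), length(x$conditions), length(x$recordings),
              x$config$n_channels, x$config$fs, x$config$preset))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One delimited recording per subject/condition (see [write_recording()]), a
#' `manifest.csv` (id, group, condition, duration_years, age, file) and a
#' `ground_truth.json` with the coupling topology edge lists and per-subject
#' strengths.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (nm in names(cohort$recordings)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    file <- file.path(dir, paste0(nm, ".csv"))
    write_recording(cohort$recordings[[nm]], file)
    i <- match(parts[1L], cohort$manifest$id)
    rows[[nm]] <- data.frame(id = parts[1L], group = cohort$manifest$group[i],
                             condition = parts[2L],
                             duration_years = cohort$manifest$duration_years[i],
                             age = cohort$manifest$age[i],
                             file = basename(file), stringsAsFactors = FALSE)
  }
  data.table::fwrite(do.call(rbind, rows), file.path(dir, "manifest.csv"))
  edge_list <- function(adj) {
    e <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  jsonlite::write_json(
    list(lattice_edges = edge_list(cohort$ground_truth$lattice),
         shortcut_edges = edge_list(cohort$ground_truth$shortcuts),
         backbone_strength = cohort$ground_truth$backbone_strength,
         strengths = cohort$ground_truth$strengths,
         seed = cohort$config$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
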