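test_that("coupled recordings are deterministic and validate their inputs", {
  topo <- matrix(0, 3, 3); topo[1, 2] <- topo[2, 1] <- 1
  b <- eeg_bands()$beta
  r1 <- simulate_coupled_recording(topo, b, 0.5, 1000, 125, seed = 9)
  r2 <- simulate_coupled_recording(topo, b, 0.5, 1000, 125, seed = 9)
  expect_identical(r1$data, r2$data)
  bad <- topo; bad[1, 3] <- 1                       # asymmetric
  expect_error(simulate_coupled_recording(bad, b, 0.5, 100, 125),
               "invalid-input")
  expect_error(simulate_coupled_recording(topo, eeg_bands()$gamma, 0.5,
                                          100, 80), "invalid-band")
})

test_that("an edge at high strength produces MI above its permutation null", {
  topo <- matrix(0, 2, 2); topo[1, 2] <- topo[2, 1] <- 1
  rec <- simulate_coupled_recording(topo, eeg_bands()$beta, 2, 4000, 125,
                                    noise_sd = 0.5, seed = 21, ar_r = 0.9)
  x <- rec$data[1, ]; y <- rec$data[2, ]
  expect_gt(mutual_information(x, y, 16), mi_perm_quantile(x, y, 200))
})

test_that("zero coupling leaves channel pairs at the permutation null", {
  topo <- matrix(0, 2, 2); topo[1, 2] <- topo[2, 1] <- 1
  rec <- simulate_coupled_recording(topo, eeg_bands()$beta, 0, 4000, 125,
                                    noise_sd = 1, seed = 22, ar_r = 0.9)
  x <- rec$data[1, ]; y <- rec$data[2, ]
  expect_lt(mutual_information(x, y, 16), mi_perm_quantile(x, y, 200))
})

test_that("mean MI over true edges is non-decreasing in coupling strength", {
  n <- 24; m <- round(0.24 * choose(24, 2))
  mean_edge_mi <- function(strength, seed) {
    topo <- withr::with_seed(seed, eegcostnet:::ws_topology(n, m, 0.22))
    full <- topo$lattice + topo$shortcuts
    rec <- simulate_coupled_recording(full, eeg_bands()$beta, strength,
                                      1000, 125, noise_sd = 0.5,
                                      seed = seed + 1, ar_r = 0.9)
    mi <- recording_band_mi(rec, eeg_bands()["beta"], 2, 4,
                            mi = list(n_bins = 8,
                                      concatenate_epochs = FALSE))$beta
    mean(mi[upper.tri(mi) & full == 1])
  }
  for (seed in c(101, 202, 303)) {
    vals <- sapply(c(0, 0.15, 0.30), mean_edge_mi, seed = seed)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("cohort bookkeeping, manifest invariants and ground truth hold", {
  cfg <- desk_config(n_per_group = 4L, seed = 5)
  cohort <- simulate_cohort(cfg)
  expect_identical(nrow(cohort$manifest), 8L)
  expect_length(cohort$recordings, 16L)            # one per condition
  expect_true(all(!is.na(cohort$manifest$duration_years[
    cohort$manifest$group == "patient"])))
  expect_true(all(is.na(cohort$manifest$duration_years[
    cohort$manifest$group == "control"])))
  durs <- cohort$manifest$duration_years[cohort$manifest$group == "patient"]
  expect_true(all(durs >= 2 & durs <= 25))
  gt <- cohort$ground_truth
  full <- gt$lattice + gt$shortcuts
  expect_true(isSymmetric(full))
  expect_true(all(diag(full) == 0))
  expect_true(all(full %in% c(0, 1)))              # disjoint edge sets
  # per-subject strengths recorded for every recording
  expect_identical(nrow(gt$strengths), 16L)
  expect_true(all(gt$strengths$strength >= 0))
})

test_that("identical seed and config reproduce the cohort bit-for-bit", {
  c1 <- simulate_cohort(desk_config(n_per_group = 2L, seed = 77))
  c2 <- simulate_cohort(desk_config(n_per_group = 2L, seed = 77))
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$ground_truth, c2$ground_truth)
  for (nm in names(c1$recordings)) {
    expect_identical(c1$recordings[[nm]]$data, c2$recordings[[nm]]$data)
  }
  c3 <- simulate_cohort(desk_config(n_per_group = 2L, seed = 78))
  expect_false(identical(c1$recordings[[1]]$data, c3$recordings[[1]]$data))
})

test_that("negative patient strengths are clipped to zero with a warning", {
  cfg <- desk_config(n_per_group = 2L, seed = 3,
                     coupling_strength = list(control_rest = 0.2,
                                              control_task = 0.2,
                                              patient_rest = 0.2,
                                              patient_task = 0.01),
                     duration_slope = -0.05)
  warns <- capture_warnings(cohort <- simulate_cohort(cfg))
  expect_true(any(grepl("clipped", warns)))
  st <- cohort$ground_truth$strengths
  expect_true(all(st$strength >= 0))
  expect_true(any(st$strength == 0))
})

test_that("the null preset equalises all four cell strengths", {
  cfg <- desk_config(preset = "null", n_per_group = 2L, seed = 1)
  expect_length(unique(unlist(cfg$coupling_strength)), 1L)
  expect_identical(cfg$duration_slope, 0)
})

test_that("cohorts round-trip to disk with manifest and ground truth", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(desk_config(n_per_group = 2L, seed = 12,
                                        n_channels = 8L))
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  man <- data.table::fread(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 8L)                  # 4 subjects x 2 conditions
  back <- read_recording(file.path(dir, man$file[1]))
  key <- paste(man$id[1], man$condition[1], sep = ".")
  expect_equal(back$data, cohort$recordings[[key]]$data, tolerance = 1e-12,
               ignore_attr = TRUE)
})
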