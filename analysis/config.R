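# Shared configuration of the analysis workflow: desk-scale synthetic cohort
# (see ?desk_config for the study conditions it emulates), 8-bin MI on the
# sparse desk cost grid, 20-member null ensembles.
cfg <- pipeline_config(
  simulation = list(desk = TRUE, n_per_group = 10L),
  mi = list(n_bins = 8L),
  costs = list(from = 0.08, to = 0.24, by = 0.02),
  nulls = list(n_draws = 20L),
  stats_mode = "crossed",
  seed = 1L,
  out_dir = file.path("results", "pipeline"))
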