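#!/usr/bin/env Rscript
# Stage 3: graph metrics, null models and cohort statistics.
#
# Thresholds each association matrix over the cost grid, evaluates global and
# local efficiency against 20 matched random and regular null graphs per
# cost, determines the small-world regime per band (bands outside the regime
# are excluded), and runs the per-cost two-way ANOVA, post-hoc t-tests,
# Z-scored nodal-map tests and duration correlations on the valid bands.

library(eegcostnet)
source(file.path("analysis", "config.R"))

adir <- run_analyze(cfg)
message("analysis tables in ", adir)
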