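#!/usr/bin/env Rscript
# Stage 2: band decomposition and mutual-information connectivity.
#
# Every recording is epoched, linearly detrended, Morlet-decomposed into the
# configured band(s) and summarised as a channel x channel MI association
# matrix (per-epoch estimation, averaged across epochs). Outputs are cached
# with checksums; re-running skips existing matrices.

library(eegcostnet)
source(file.path("analysis", "config.R"))

mdir <- run_connect(cfg)
n_mi <- length(list.files(mdir, pattern = "^mi_.*\\.csv$"))
message(sprintf("%d association matrices in %s", n_mi, mdir))
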