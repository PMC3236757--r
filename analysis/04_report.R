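#!/usr/bin/env Rscript
# Stage 4: headline report of the workflow outputs.

library(eegcostnet)
source(file.path("analysis", "config.R"))

adir <- file.path(eegcostnet:::run_dir(cfg), "analysis")
summ <- jsonlite::read_json(file.path(adir, "run_summary.json"),
                            simplifyVector = TRUE)

for (bn in names(summ$bands)) {
  b <- summ$bands[[bn]]
  if (isTRUE(b$valid)) {
    message(sprintf("%s band: small-world regime %.2f <= C <= %.2f",
                    bn, b$c_low, b$c_high))
    message(sprintf("  strongest group x condition interaction on Eglob at cost %.2f: F = %.2f, p = %.4g",
                    b$max_interaction_cost, b$max_interaction_F,
                    b$max_interaction_p))
  } else {
    message(sprintf("%s band: no valid small-world regime -- excluded", bn))
  }
}

for (bn in names(summ$bands)) {
  if (!isTRUE(summ$bands[[bn]]$valid)) next
  dc <- data.table::fread(file.path(
    adir, sprintf("duration_correlation_Eglob_%s.csv", bn)))
  message(sprintf("%s band, Eglob vs disease duration (task): R in [%.2f, %.2f], min p = %.3g",
                  bn, min(dc$R.task), max(dc$R.task), min(dc$p.task)))
  data.table::fwrite(dc, file.path("results",
                                   sprintf("duration_correlation_%s.csv", bn)))
  an <- data.table::fread(file.path(adir, sprintf("anova_Eglob_%s.csv", bn)))
  data.table::fwrite(an, file.path("results", sprintf("anova_Eglob_%s.csv", bn)))
}
message("headline tables copied to results/")
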