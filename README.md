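# eegcostnet

Economical small-world analysis of EEG functional cortical networks in R.

`eegcostnet` implements the full analysis chain used to ask whether the
band-specific functional cortical networks of a patient group (for example,
focal hand dystonia, a task-specific movement disorder) reorganise abnormally
between rest and a motor task, and whether that reorganisation scales with
disease duration:

1. **Band decomposition** — multichannel recordings are re-referenced to
   linked earlobes, linearly detrended, decimated, cut into epochs and
   decomposed with a continuous Morlet wavelet into alpha (7.97–15.05 Hz),
   beta (15.05–31.25 Hz) and gamma (31.25–50.78 Hz) band series.
2. **Connectivity** — mutual information (MI, in bits; plug-in estimator on
   equiprobable rank bins, per-epoch and averaged) between every channel pair
   gives a symmetric association matrix per subject, condition and band.
3. **Graphs and efficiency** — each matrix is thresholded by network cost
   `C` (the fraction of the `N(N−1)/2` possible edges kept, strongest MI
   first) into binary undirected graphs; on each graph the package computes
   global efficiency `Eglob = mean over pairs of 1/L(i,j)`, local efficiency
   `Elocal` (mean efficiency of each node's neighbour subgraph), nodal
   efficiency `Enodal`, clustering `Cp`, path length `Lp`, cost-efficiency
   `CE = Eglob − C` and its maximum `maxCE`.
4. **Null models and the small-world regime** — 20 edge-matched uniform
   random graphs and matched regular ring lattices per cost; a band is kept
   only where the empirical curves fall strictly between the null families
   (`Eglob_regular < Eglob < Eglob_random` and
   `Elocal_random < Elocal < Elocal_regular`); the small-worldness index
   `sigma = (Cp/Cp_rand)/(Lp/Lp_rand) > 1` confirms small-world organisation.
5. **Cohort statistics** — per-cost two-way group × condition ANOVA of the
   global metrics, post-hoc t-tests, per-participant Z-scored nodal maps
   tested node-wise at three significance tiers (0.05, 1/N, 0.05/N), and
   Pearson correlations between efficiency and disease duration.

Because no recorded EEG ships with the package, a seeded synthetic-cohort
generator (`simulate_cohort()`) produces band-limited coupled AR(2)
recordings whose long-range coupling strength carries a planted
group × condition interaction and a negative duration slope, so every stage
is testable end to end.

## Worked example

```r
library(eegcostnet)

# a small planted-interaction cohort: 2 groups x 2 conditions, beta band
cohort <- simulate_cohort(desk_config(n_per_group = 10L, seed = 1))
mi     <- cohort_connectivity(cohort, n_bins = 8)
tab    <- cohort_metric_table(mi, cohort$manifest, desk_cost_grid(),
                              metrics = c("Eglob", "Elocal"))

cc <- mid_grid_cost(desk_cost_grid())   # 0.16
anova_2x2(tab, "Eglob", "beta", cc)
#>        effect           F df1 df2            p metric band cost    mode
#> 1       group  0.04608968   1  36 0.8312243830  Eglob beta 0.16 crossed
#> 2   condition  2.05409417   1  36 0.1604256475  Eglob beta 0.16 crossed
#> 3 interaction 15.77110277   1  36 0.0003278131  Eglob beta 0.16 crossed

duration_correlation(tab, cohort$manifest, "Eglob", "beta", cc)
#>   cost condition  n          R           p degenerate metric band
#> 1 0.16      rest 10 -0.7768517 0.008204681      FALSE  Eglob beta
#> 2 0.16      task 10 -0.3387407 0.338336495      FALSE  Eglob beta
```

The planted group × condition interaction in beta-band global efficiency is
recovered (F(1, 36) = 15.8, p = 3.3e-4) while the main effects stay small,
and the patients' efficiency declines with disease duration (negative R in
both conditions at this seed and cohort size). Single-cohort correlations at
10 patients are noisy; the Monte-Carlo tests characterise the sign-recovery
rate at the full 15-per-group desk conditions.

The same pipeline runs file-based via `run_simulate()`, `run_connect()` and
`run_analyze()` driven by the numbered scripts in `analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_connect.R
Rscript analysis/03_analyze.R
Rscript analysis/04_report.R   # prints regime, interaction scan, duration table
```

## Vignette

`vignettes/eeg-small-world-networks.Rmd` documents the model and its
assumptions, the synthetic-data generator design, the parameter defaults and
the numerical choices (thresholding tie-breaks, disconnected-graph
conventions, wavelet edge handling), and the limits of what the synthetic
validation shows about recorded EEG.
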