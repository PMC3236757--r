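---
title: "Economical small-world analysis of EEG functional networks: methods"
author: "eegcostnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Economical small-world analysis of EEG functional networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical conventions that make results reproducible.

## The analysis model

The object of study is the band-specific functional cortical network of a
multichannel EEG recording: nodes are electrodes, and the statistical
dependence between two electrodes' band-limited signals is measured by mutual
information (MI), which captures linear and nonlinear zero-lag coupling in a
single non-negative number. Thresholding the symmetric MI association matrix
by *network cost* `C` — keeping exactly `K = round(C * N(N-1)/2)` strongest
pairs — yields a family of nested binary undirected graphs indexed by the
fraction of wiring they are allowed to use.

On each graph the package evaluates the efficiency family:

* `Eglob`, the mean over ordered node pairs of the inverse shortest path
  length (with `1/Inf = 0`), an index of network-wide integration that is
  well defined on disconnected and dense graphs alike;
* `Enodal(i)`, the inverse harmonic mean of node `i`'s path lengths, whose
  across-node mean equals `Eglob` identically (the implementation computes
  `Eglob` as that mean, so the identity is exact to the bit);
* `Elocal`, the mean efficiency of each node's neighbour-induced subgraph
  (neighbourhoods smaller than two nodes contribute 0), an index of local
  fault tolerance / segregation;
* `Cp` and `Lp`, Watts–Strogatz clustering and mean finite shortest path
  length, the ingredients of the small-worldness index
  `sigma = (Cp/Cp_rand) / (Lp/Lp_rand)`;
* cost-efficiency `CE = Eglob - C`, positive where the network delivers more
  integration than its wiring fraction — the "economical" range — and its
  maximum over the grid, `maxCE`.

Whether a band's networks are meaningfully small-world is decided against
matched null families: at every cost, 20 uniform random graphs with the same
node and edge counts and the matched deterministic ring lattice. The
*small-world regime* is the contiguous run of grid costs, starting at the
lowest qualifying cost, on which the empirical curves fall strictly between
the families (`Eglob` above regular but below random, `Elocal` above random
but below regular). A band with no qualifying cost is flagged invalid and
excluded from group statistics — on noise-driven association matrices the
thresholded graphs are statistically indistinguishable from the random
family itself, so strict betweenness fails, which is exactly the desired
behaviour.

Group inference treats each subject's metric at each grid cost as one
observation in a 2 (group) x 2 (condition) design. The default ANOVA is
fully crossed over all subject-condition observations, giving denominator
degrees of freedom `2 * (n_subjects - 2)` + 2 = 56 for 15 + 15 subjects; a
mixed-design mode (condition within subject, denominator 28) is available by
configuration. The crossed layout is the default because it reproduces the
degrees of freedom conventionally reported for this design in the EEG
network literature; the mixed mode is the textbook analysis for a
between-group/within-condition design. Both are reported as what they are.
Nodal maps (degree, `Enodal`) are Z-scored per participant across nodes
before node-wise testing; Z-scoring uses the population (divide-by-n)
standard deviation so the unit-variance invariant is exact and the operation
idempotent. Node-wise significance is reported at three tiers — uncorrected
0.05, `1/N`, and `0.05/N` (for 58 channels: 0.017 and 0.00086). The last
threshold is arithmetically a Bonferroni bound; the package labels it
`fdr_label` rather than asserting it is a false-discovery-rate procedure.
Duration-of-disease associations are Pearson correlations across patients,
per cost and condition, with two-sided p-values.

## Band decomposition choices

The band edges are stored as exact constants — alpha 7.97–15.05 Hz, beta
15.05–31.25 Hz, gamma 31.25–50.78 Hz — rather than derived from a scale
formula; they partition the axis exactly (`alpha$high == beta$low`, etc.).
The Morlet transform uses nondimensional frequency `omega0 = 6` and 4 voices
per octave, the common neuroscience defaults, both configurable. The band
series is the delta-reconstruction restricted to in-band scales — the sum
over scales of the real part of the coefficients weighted by `1/sqrt(a)`,
normalised so a sinusoid at the band's geometric centre keeps unit
amplitude — because MI between real-valued band-limited series is well
defined; a coefficient-magnitude variant is available by switch. Epoch edges
are handled by symmetric reflection padding of half the longest wavelet
support, then cropping. The Gaussian frequency response of the Morlet rolls
off smoothly: at `omega0 = 6` the skirt spans under an octave, and one
octave beyond the band edges even the peak of the residual spectrum sits
more than 20 dB below the in-band peak, with the bulk of the stopband more
than 40 dB down (the property tests measure this on white noise with a
smoothed periodogram).

The preprocessing chain (linked-earlobe re-reference `x - A1/2` with the A1
channel dropped, per-epoch linear detrend, zero-phase Butterworth
anti-aliasing before decimation) is linear end to end, and the test suite
checks that linearity to 1e-6 relative.

## The MI estimator

`mutual_information()` is the plug-in estimator on equiprobable rank-based
marginal bins (default 16), in bits. Rank binning makes the estimate
invariant under monotone rescaling and gives uniform marginals by
construction; ties break by first occurrence, so results are deterministic.
For a tie-free series whose length is divisible by the bin count,
`MI(x, x) = log2(n_bins)` exactly. The estimator is biased upward on
independent data (the classic `(B-1)^2 / (2 N ln 2)` plug-in bias), which is
irrelevant here because thresholding uses only the *ranking* of pairs and
the permutation-null tests compare against the same estimator. Per-epoch
estimation followed by averaging is the default (it limits nonstationarity
leakage across epoch boundaries); concatenation is available by
configuration. Desk-scale validation uses 8 bins for its 500-sample epochs —
with narrowband series the effective number of independent samples is far
below the sample count, and fewer bins keep the estimator's ranking noise
below the planted MI contrasts.

## The synthetic-cohort generator

The package's cohorts are simulated, and the generator is designed so the
planted effects are identifiable by the pipeline that will be asked to
recover them — an empirical-study stand-in, not a biophysical model.

Each channel carries a unit-variance narrowband AR(2) oscillation (pole
radius `ar_r`, peak frequency jittered over the middle half of the band);
coupling injects neighbours' oscillations along topology edges,
`x = o + W o + noise`. The pairwise correlation across an edge rises with
its weight up to a turnover at `sqrt((1 + noise_var)/degree)`; all defaults
stay below the turnover, which is also why the monotone strength-to-MI
contract holds in the tested range.

The coupling topology is a Watts–Strogatz decomposition: a short-range ring
lattice *backbone* at fixed strength plus long-range *shortcut* edges
(rewired lattice edges) whose strength is the experimental knob. The
analysis grid sits below the backbone density, so the thresholded graph is
always a `K`-subset of the true edges, and the shortcut strength decides how
many shortcuts displace lattice edges in that subset. Weak long-range
coupling yields a thinned lattice (low `Eglob`); strong long-range coupling
yields a rewired small-world graph (high `Eglob`). The knob therefore maps
monotonically onto global efficiency, mirroring the standard account in
which reduced efficiency reflects a loss of long-range communication.
Shortcut strengths run *above* the backbone strength because lattice edges
enjoy an MI bonus from shared-neighbour (clustering) reinforcement —
adjacent lattice nodes also receive common third-party oscillations — so
shortcuts need more direct strength to reach ranking parity.

Planted conditions (the `"interaction"` preset): controls strengthen
long-range beta coupling from rest to task, patients weaken it, and patient
strength additionally declines with disease duration
(`base(group, condition) + duration_slope * duration`, floored at zero with
a warning). Durations are uniform on 2–25 years. The `"null"` preset sets
all four cells equal and the slope to zero, for type-I-error calibration.
Alpha coupling, when simulated, is equal in all cells (a valid regime with
no group differences); gamma is left uncoupled, so its networks are
noise-driven and typically fail the regime criteria — the band-exclusion
path. Seeding is counter-based: one master seed expands into per-subject
streams, so any subject's recording is reproducible in isolation.

What the generator does **not** emulate: volume conduction and field spread
(the dominant confound of sensor-space EEG connectivity), ocular/muscle
artifacts, non-stationarity within epochs, 1/f broadband background, or
realistic electrode geometry. Passing tests therefore show that the
*pipeline* recovers known structure of the stated kind at desk scale — they
are not evidence about recorded EEG.

## Problem sizes and calibration

Full study conditions (the `sim_config()` defaults) are 58 channels at
500 Hz, 5 x 10 s epochs, 15 subjects per group, three bands, analysed on the
0.16–0.50 cost grid in 0.02 steps (mid-grid 0.32–0.34). The statistical
calibration checks run at the desk validation scale (`desk_config()`):
24 channels at 125 Hz, 2 x 4 s epochs, beta only, lattice density 0.24 with
rewiring 0.22, analysed on the 0.08–0.24 grid (mid-grid 0.16), 8 MI bins.
At that scale the suite verifies, by Monte-Carlo over seeded cohorts:
interaction power at the planted preset (50 cohorts of 15 + 15), type-I
error of the per-cost interaction test within binomial 99% bounds of 0.05
(200 null cohorts of 5 + 5), sign recovery of the negative duration slope
(50 cohorts), and validity of the small-world regime for small-world
structured association matrices at the full 58-node geometry (50 draws).
These sizes were chosen once as the smallest cohorts at which the planted
contrasts sit several error-standard-deviations above the pipeline's
estimator noise, and the suite completes on a single CPU in well under half
an hour.

## Numerical conventions and degenerate inputs

* Thresholding keeps exactly `round(C * N(N-1)/2)` edges; ties at the MI
  cutoff break by ascending (row, column) index, so graphs are unique.
* `1/Inf = 0` for disconnected pairs in every efficiency sum; `Lp` averages
  finite distances only and is `NaN` (with a warning) on an edgeless graph;
  `sigma` is `NaN` when its ingredients degenerate.
* The regular null lattice places remainder edges (`m - n*k/2`, with `k`
  rounded down to even) deterministically on next-nearest neighbour slots in
  index order, so "20 regular networks" are identical by construction and
  the family mean is exact.
* Paired t-tests with zero difference variance report `p = 1` with a
  degeneracy flag; constant series give `MI = 0` with a warning; zero-
  variance nodal maps Z-score to zeros with a warning.
* Monotonicity: `Eglob` is non-decreasing in cost for nested graphs by
  construction. `Elocal` monotonicity is *not* a theorem (an added edge can
  dilute a neighbourhood subgraph); it holds empirically for the dense
  58-node small-world association structure, where the suite checks it, but
  can fail on sparse 24-node graphs.
* The self-worldness of a random graph against its own null family is 1 only
  on average; the suite checks `|mean(sigma) - 1| < 0.2` over 50 draws
  rather than bounding every draw, whose spread at 264 edges exceeds 0.2.

## Known limitations

Undirected, unweighted, zero-lag graphs only (no transfer entropy, Granger
or surrogate decomposition of linear vs nonlinear coupling); sensor-space
analysis without leakage correction; the `"EDF"` import path is out of
scope (delimited matrices are the interchange format); and the full
58-channel, 5-epoch configuration is supported but the statistical
contracts are verified at desk scale, not re-derived at full scale.
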