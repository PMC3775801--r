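---
title: "arrayrank: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{arrayrank: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayrank)
```

`arrayrank` implements a complete two-group expression-array analysis:
detection thresholding, iterative multi-loess normalization, SAM-style
regularized-t differential expression with permutation q-values, signed fold
changes with probe-to-gene collapsing, a minimum-hypergeometric rank-order
gene-set statistic with Bonferroni adjustment across sets,
variation-of-information (VI) clustering of significant sets, heatmap-matrix
assembly, and a cosinor screen for diurnal confounding in qPCR data. This
vignette explains each model, the tunable parameters and their defaults, the
numerical choices, and what the synthetic benchmark does and does not show.

## The synthetic study generator

The pipeline is exercised on generated studies shaped like a two-cohort
retinal autopsy comparison: 7 control (HIV-negative) samples against 10
lesion-free HIV-positive samples, with optional cotton-wool-spot and
intraretinal-hemorrhage cohorts, about 18,429 expressed probes, and times of
death spread over the day.

A probe's log2 value is

```
baseline + group effect + array distortion(baseline) + noise
```

* **Baseline.** Expressed probes draw from `7 + Exp(mean 1.5)` — a broad,
  right-skewed "expressed" mode. A configurable fraction (`floor_frac`,
  default 0.25 of the expressed count) of additional probes sits in a narrow
  background mode at `N(2.5, 0.3)`. The two modes give the pooled log2
  distribution a genuine valley for the detection threshold to find.
  `n_probes` counts *expressed* probes: the floor probes are appended on
  top, so the detection filter returns `n_probes` rows on a clean draw.
* **Group effect.** A fraction `de_frac` (default 0.05) of genes is planted
  as differential in all HIV-positive cohorts: `up_frac` (default 0.6) of
  them upregulated with linear folds in `up_range` (default 2–5, rod-like),
  the rest downregulated with magnitudes in `down_range` (default 1.2–1.4,
  cone-like). The planted log2 effect is `sign(f) * log2(|f|)`.
* **Distortion.** Each array gets a random monotone polynomial (default
  cubic) evaluated on the baseline rescaled to `[-1, 1]`; coefficients are
  `N(0, distortion_sd)` (default 0.15) and are resampled until the composite
  intensity map is increasing. Bounding the polynomial argument keeps the
  warp at a realistic few-tenths of a log2 unit instead of exploding in the
  skewed intensity tail; monotonicity keeps within-array ranks meaningful.
* **Noise.** i.i.d. Gaussian on the log2 scale, default sd 0.5. The noise
  model of real bead arrays is not known to us; Gaussian-on-log2 is a
  stand-in, not an inference, and heavier-tailed or intensity-dependent
  noise in real data is exactly what the benchmark does *not* probe.
* **Times of death** are truncated-normal draws on `[0, 24)`: mean 12.5 h,
  sd 6.8 h for the negative cohort and mean 11 h, sd 7.1 h for the positive
  cohorts, mirroring the autopsy cohorts the design emulates.

All randomness flows from the single `seed`; the same seed reproduces the
matrix bit for bit.

What passing tests on this generator shows: the statistics recover planted
structure under honest noise, the normalizer removes exactly the class of
distortion the generator plants, and false-discovery proportions behave at
the 2,000–18,429-probe scale. What it cannot show: behaviour under probe
cross-hybridization, donor-level correlation, batch structure, or non-normal
noise — none of which are simulated.

## Detection threshold and filter

Bead-array log-intensity distributions are bimodal. `valley` (the default
method) pools all log2 values, fits a kernel density (`stats::density`,
1024 points), finds the two largest modes and returns the density minimum
between them. A unimodal density is an explicit error directing the user to
`quantile` or `manual` — automatic valley-finding on a unimodal pool would
silently return nonsense. A probe is *detected* when its value exceeds the
threshold in at least one sample; undetected probes are removed before any
other step, and the retained order is preserved.

## Multi-loess normalization

Arrays are normalized against a reference equal to the per-probe mean of all
arrays, recomputed each sweep. For each array, `M = array − reference` and
`A = (array + reference)/2`; the lowess fit of M on A (locally linear,
span 0.4 by default) is the array's intensity-dependent departure from
consensus and is subtracted. Sweeps repeat until the largest correction is
below `tol` (default 1e-3 log2) or `max_iter` (default 10) sweeps have run.

Three numerical choices matter and are worth stating plainly:

* **Consensus centring.** The per-probe mean of one sweep's fits is a
  component shared by every array. Subtracting it would warp all arrays
  identically — it cancels in every between-array contrast and in fold
  changes, which are ratios — while feeding back into the mean reference
  and destabilizing the iteration. Only each array's fit relative to that
  consensus is subtracted, which keeps the reference fixed within a sweep
  cycle and makes the iteration contract.
* **Plain (non-robust) local fits.** With a minority of genuinely
  differential probes, lowess robustness reweighting interacts with the
  shared reference and can destabilize large arrays (we observed sudden
  group-level shifts after several sweeps at the 18,429-probe scale).
  Differential probes are a few percent of the total and spread across the
  intensity range, so the unweighted fit is only negligibly biased by them.
* **Convergence before update, best state kept.** Convergence is checked on
  freshly computed corrections *before* subtracting them, so a converged
  matrix is a verified fixed point: re-normalizing it changes nothing
  (idempotence is exact, not approximate). On noisy data the corrections
  plateau — the M-vs-A regression at the intensity extremes chases the
  correlation between an array's own noise and its A coordinate — so the
  sweep with the smallest correction is kept and iteration stops once five
  consecutive sweeps fail to improve, with a warning. The `residual`
  attribute (largest absolute fitted M against the final reference) reports
  how flat the result actually is. On noiseless cubic distortion the
  residual reaches ~1e-3; on noisy data expect a plateau around 0.05–0.2
  driven by the sparse intensity extremes.

The lowess interpolation grid is set to 0.1% of the A range (R's default of
1% leaves piecewise-linear kinks of ~1e-3 that block convergence below that
scale).

## Regularized t and permutation q-values

For probe *i* with group sizes `n1, n2`:

```
s_i = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))
d_i = (mean_test - mean_ctrl) / (s_i + s0)
```

`s0`, the exchangeability factor, is the 75th percentile of the `s_i`
distribution by default (linear interpolation between order statistics,
`quantile` type 7); it keeps probes with accidentally tiny variance from
dominating the ranking. The percentile is configurable, as is a fixed `s0`.

False discovery rates follow the SAM recipe. Group labels are permuted
(all `choose(n, n1)` assignments when that count is at most `n_perm`,
otherwise `n_perm` seeded random draws; default 200); `s0` is computed once
from the observed labels and reused for permuted statistics. For each
candidate threshold on `|d|` (the observed values), the estimated false
call count is the *median* across permutations of permuted `|d*|` at or
above the threshold, scaled by the null proportion `pi0`; a probe's q-value
is the smallest resulting FDR over all thresholds at which it is called.
`pi0` uses the standard quantile heuristic — the fraction of observed `d`
inside the permuted interquartile range, divided by 0.5, capped at 1 — and
can be fixed (e.g. `pi0 = 1`) instead. The number of permutations and the
`pi0` estimator are free choices here: the upstream description of this
analysis names neither, so exact q-values from any particular historical run
cannot be reproduced bit for bit, only the procedure.

Signed fold changes are ratios of *linear-scale* group means with the
reciprocal convention: `f = ratio` when the ratio is at least 1, else
`-1/ratio`, so `|f| >= 1` always and the sign encodes direction. When
several probes interrogate one gene, the probe with the smallest q
represents it (ties: larger `|d|`, then lexicographic probe id), and genes
are ranked by ascending q with the same tie-breaks — a strict order, which
the rank statistic requires.

## The rank-order gene-set statistic

A gene set with members at list positions `r_1 < … < r_n` (position 1 =
most significant) gets, for every depth `k`, the probability that `n` ranks
drawn uniformly without replacement from `{1..N}` would place at least `k`
of them in the top `r_k` positions:

```
p_k = sum_{j=k}^{min(n,r_k)} C(r_k, j) C(N - r_k, n - j) / C(N, n)
```

and the set p-value is `min_k p_k`. The statistic asks, at every depth, how
surprising the set's concentration at the top of the list is, and keeps the
most surprising depth. It is one-sided by construction: depletion or
mid-list clustering is invisible to it. No within-set multiplicity
adjustment is applied — the `n` depth tests on one set are strongly
dependent — so the minimum is *anti-conservative* relative to a uniform
p-value; `null_min_p()` draws its empirical null distribution, and the test
suite pins that null's CDF across seeds. Significance is controlled instead
across sets: Bonferroni over the number of testable sets, reporting sets
with adjusted p at or below `alpha` (default 0.01).

Two reading choices are locked in deliberately. "k-th highest rank" is read
as the k-th *best* list position, the only reading under which the statistic
detects overrepresentation at the top; and set members absent from the
detected list are dropped with `n` reduced, so `n` counts expressed members
only. Hypergeometric terms are accumulated in log space via `lchoose` with
log-sum-exp factoring, stable at `N ≈ 18,000`; `set_pvalue()` also returns
`log_p`, exact even when the probability underflows a double (deep
enrichments at full list scale reach p below 1e-300).

## VI clustering of significant sets

Ontology-derived collections share members heavily, so significant sets are
reported as clusters rather than as independent findings. Each set induces a
binary member/non-member partition of the detected-gene universe; the
variation of information between two partitions,
`VI = H(A) + H(B) − 2 I(A;B)` in bits, is a true metric, and average-linkage
hierarchical clustering on the pairwise VI matrix groups sets that share
genes. Cell probabilities are cell sizes over the universe size with
`0 log 0 = 0`; summation order is canonicalized (cells sorted before
summing) so `VI(a, b)` and `VI(b, a)` are bit-identical, which the metric
tests require.

Two properties of the binary-partition reading deserve note. A set and its
exact complement induce the same partition, hence distance 0 — unreachable
in practice for ontology-sized sets over a ~18,000-gene universe. And at
fixed set sizes VI decreases with overlap only from the *chance-level*
overlap `|a||b|/|U|` upward; below it, sets are anti-correlated partitions
and VI briefly rises with overlap. Clustering is unaffected (overlapping
significant sets are far above chance overlap), but a claim of global
monotonicity would be false and the tests assert the correct, restricted
version.

## Heatmap matrix and comparison reports

Heatmap rows are the genes whose regularized t exceeds the threshold
(`|d| > 1` by default; the display shows both directions, and a one-sided
flag exists). Each cell is the log2 value minus the gene's midpoint
reference — the mean of the two group means on the log2 scale — so the two
groups sit symmetrically around zero and cell sign matches fold-change
direction. The midpoint is computed on the log2 scale because the colors are
meant to correspond to fold changes, which are symmetric there. Rows are
ordered by average-linkage clustering on correlation distance (zero-variance
guard: undefined correlations become maximal distance); columns by time of
death, ascending within each group, control group first.

`run_comparison()` chains the whole pipeline on a named pair of cohorts and
records a manifest (seed, parameters, threshold, normalization residual,
and the counts at every stage) that `write_manifest()` serializes as JSON;
the same inputs and seed give byte-identical counts.

## qPCR diurnal screen

Relative abundance is `2^-(Ct_target − Ct_reference)` — plain delta-Ct
against GAPDH, one cycle per factor of two; amplification-efficiency
correction and standard curves are out of scope. The diurnal check fits
log2 abundance on a single 24-hour harmonic
(`cos(2πt/24)`, `sin(2πt/24)`): the amplitude is the coefficient norm, the
acrophase comes from the coefficient angle, and the p-value is the joint
F-test of the two harmonic terms. This cosinor is a formal stand-in for a
visual no-rhythm check; it requires at least 6 samples at 3 or more distinct
times and is invariant to shifting all times by 24 h. The qPCR generator's
default amplitude is 0 — no rhythm is the null the screen is calibrated
against — with the amplitude/phase arguments there to power the test's
sensitivity checks.

## Problem sizes used by the checks

The bundled checks run at deliberate desk scale: DE recovery at 2,000 probes
x 17 samples over 20 seeds (100 planted genes at folds 2–5, noise sd 0.5);
enrichment power at a 1,000-gene universe with 50 random sets of 20 plus one
planted set over 200 replicates; the enrichment null at 10,000 draws per
seed; exhaustive oracle equivalence for every rank combination up to list
length 8; normalization on noiseless cubic distortion at 1,500–2,000 probes;
and one full-shape run (18,429 expressed probes, 7 vs 10 samples) in the
acceptance script. Recovery of planted folds 2–5 at q < 0.05 exceeds 90%
with realized false-discovery proportion near the nominal 5%; planted
cone-like folds of 1.2–1.4 are recovered far less often at these sample
sizes — a power statement about small folds in 7-vs-10 designs, not a defect.

## Known limitations

* The normalizer's convergence guarantee is conditional: noiseless smooth
  distortion converges below `tol`; noisy data plateau (reported via the
  `residual` attribute and a warning). Values at the sparse intensity
  extremes are the least trustworthy after normalization, as in any
  MA-loess scheme.
* The rank-order set p-value is not uniform under the null (documented
  anti-conservativeness); compare raw set p-values only through the
  Bonferroni-adjusted report or against `null_min_p()`.
* The generator plants probe-level effects shared by all probes of a gene
  and all positive cohorts; it does not simulate lesion-specific signatures
  beyond that, bead-level data, or probe sequence effects.
* q-values depend on the permutation count; with small `n_perm` their
  resolution is `~1/n_perm` and a warning is raised below 20 usable
  permutations.
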