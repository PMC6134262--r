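---
title: "Analysing plant secondary metabolite profiles under combined abiotic factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing plant secondary metabolite profiles under combined abiotic factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmtools)
```

## The problem

Untargeted LC-MS profiling of plant tissue yields, per sample, thousands of
*features* — (mass, retention time) peaks with an intensity — each treated as
a proxy for one secondary metabolite. When plants are grown under factorial
combinations of abiotic drivers (warming, drought, canopy light) in a blocked
field design, the questions are multivariate: do conditions shift the whole
metabolite profile? Do they change *which* compounds are made (phytochemical
richness and turnover) rather than how much? Which individual features shift
strongly relative to a reference condition, and do named example compounds
change significantly?

`psmtools` implements that analysis chain as reusable, seeded, tested
components: dual-polarity feature fusion, Canberra/Jaccard dissimilarities,
permutational MANOVA with strata-restricted permutations, multivariate
dispersion and mean-dissimilarity diagnostics, NMDS ordination with
standard-error ellipses, reference-condition shift classification with Venn
intersections and bootstrap CIs, and random-intercept mixed models. A
synthetic-data generator with known ground truth makes every stage testable
without instrument data.

## Data model and input contract

A `feature_table` couples a samples x features nonnegative intensity matrix
with feature annotations (`mass` in Da, `rt` in minutes, `polarity`,
`provenance`) and sample metadata (`species`, `condition`, `block`, `year`).
Intensity 0 is the canonical encoding of "absent in this sample"; blank/NA
cells are coerced to 0 with a reported count, because the presence/absence
analyses need a complete matrix. On disk a table is three diffable CSV/TSV
files (intensities, feature metadata, sample metadata); round trips are
lossless to full double precision. Peak detection and chromatographic
alignment happen upstream — this package consumes peak tables.

Retention-time trimming (`trim_rt_window`, conventional window 1–21 min) is
applied per polarity before fusion, matching the narrative order of the
workflow it reproduces; both window bounds are inclusive so boundary peaks
are never silently dropped.

## Dual-polarity fusion

Polarity switching yields two partially overlapping feature sets: a molecule
seen as [M+H]+ in positive mode and [M−H]− in negative mode appears at
masses differing by roughly two proton masses. `match_features` subtracts a
`mass_offset` from positive-mode masses and pairs features agreeing within
`mass_tol` (default 0.005 Da) and `rt_tol` (default 0.10 min) — defaults at
typical Orbitrap/UHPLC reproducibility, and mandatory in the config so runs
are self-documenting. Candidates are resolved one-to-one greedily by
ascending adjusted-mass difference (ties: RT difference, then feature ID),
and every returned pair is verified to be a mutual match — a deterministic
automation of the manual mutual-match check this procedure replaces.

Two offset presets exist because the published workflow we replicate printed
2.1046 Da while describing it as "roughly the mass of two protons"
(physically 2 x 1.007276 = 2.014552 Da). The physical value is the default;
`match_config(paper_mode = TRUE)` selects the printed constant. The package
does not decide which the original analysis actually used; both are
first-class.

`merge_tables` keeps, for each pair, the intensities of the polarity with
the greater mean intensity across all samples (zeros included); exact ties
retain positive mode — an arbitrary but fixed, documented rule. New feature
IDs carry a provenance prefix (`B_`, `P_`, `N_`).

## Diversity and dissimilarity

* **Richness** is the per-sample count of features with intensity above a
  threshold (default 0: any positive intensity counts, appropriate for
  background-subtracted tables; the threshold is a first-class parameter
  because the upstream filtering convention is not recoverable).
* **Canberra** distance on intensities:
  `d(x,y) = (1/NZ) * sum_i |x_i - y_i|/(x_i + y_i)` over the NZ components
  with `x_i + y_i > 0`. Double zeros are excluded and the sum is normalized
  by NZ, the convention of the statistical environment this pipeline
  mirrors, so distances lie in [0, 1]; `raw = TRUE` exposes the
  unnormalized sum for cross-checking. A pair of all-zero samples has no
  comparable components; its distance is defined as 0 with a warning.
* **Jaccard** distance on presence/absence quantifies turnover:
  `1 - |A ∩ B| / |A ∪ B|`.

## Permutation statistics

`permanova` partitions squared dissimilarities (total SS = mean over the
N samples of pairwise d²; within SS summed per group with 1/n_g weights) into
between/within components and reports pseudo-F, r² = SS_between/SS_total, and
a permutation p-value. The test is one-way on the composite condition factor
(the factorial cell), matching the field convention of reporting a single
F/r²/P per species-year group; sequential multi-factor decomposition is out
of scope. With `strata`, labels are shuffled only within strata, so the null
distribution respects the blocked design; block effects in the data are
absorbed by the restriction rather than by a model term.

Permutation accounting:

* Monte-Carlo mode draws `n_perm` permutations (default 9,999, enough
  resolution to resolve p-values down to the 1e-4 scale) and uses the
  (count+1)/(n_perm+1) convention, so p is never 0.
* When the number of distinct within-strata permutations does not exceed
  `n_perm`, the test enumerates all of them and reports the exact
  p = count/total, identity included. This "exact when enumeration is no
  more work than sampling" rule replaces a fixed small-n cutoff: it is
  work-equivalent, covers every instance a cutoff would, and never silently
  switches to a costlier computation.

Note one subtlety of exact enumeration with a symmetric statistic: pseudo-F
is invariant to swapping group labels, so on 4 samples split 2/2 the
smallest achievable exact p is 2/6 = 1/3 — both the identity assignment and
its label-swapped mirror reach the observed F.

`permdisp` embeds the distance matrix by principal coordinates, keeping
negative-eigenvalue axes, and computes each sample's distance to its group
center as `sqrt(max(0, dr² - di²))` (real minus imaginary contributions).
The default center is the spatial median (damped Weiszfeld iteration, applied
separately to the real and imaginary axis sets); group centroids are an
option, and the choice is recorded in the result. A classical one-way ANOVA
F on these distances is tested by permuting their group labels.
`meandist_groups` gives the complementary centroid diagnostic: a
between-group mean dissimilarity exceeding both within-group means indicates
centroid separation rather than dispersion.

## Ordination

`nmds` minimizes Kruskal stress-1 with k = 2 (the conventional choice for
these visualizations): configuration distances are fitted by isotonic
regression on the rank order of the input dissimilarities (primary treatment
of ties — within tied dissimilarities no constraint is imposed), alternated
with Guttman-transform majorization steps. A step is accepted only if stress
does not increase, with step halving as fallback, so the recorded stress
trace is non-increasing; optimization stops when the per-iteration decrease
falls below `tol` (default 1e-7) or at `max_iter` (default 300). Restarts
(default 20) are one PCoA start plus random starts; the best solution is
returned centered and rotated to principal axes. No half-change rescaling or
species-score projection is applied — ordination is used solely to visualize
sample profiles. Stress values have no external reference here, so
ordination quality is verified by property (exact recovery of planar
geometry, monotone descent, restart monotonicity), not by comparison to a
published figure.

`group_ellipses` returns 95% standard-error ellipses: center = group mean
score, shape = score covariance divided by n_g, radius = sqrt of the
chi-squared(k) level quantile. The chi-squared (rather than small-sample t/F)
quantile was chosen for determinism and simplicity, and the choice is
recorded in the ellipse parameters. Ellipse area therefore shrinks as 1/n_g
for a fixed covariance.

## Reference-condition shifts

`shift_report` computes, per feature, the percent change of the
condition-mean intensity versus the reference-condition mean (arithmetic
means over samples, zeros included — means, not medians, are what such
relative-change figures annotate). Features with reference mean 0 are routed to
an `undetected` list rather than producing undefined percentages.
Classification uses inclusive bounds at ±75% (configurable), and the up/down
sets are intersected Venn-style across the non-reference conditions (counts
plus membership lists; drawing scaled diagrams is left to plotting code).
"Relative abundance" is raw intensity: the reproduced workflow describes no
TIC or other normalization, so a per-sample total-intensity normalization
flag exists but defaults off, and the choice is echoed in the report.
Whether published shift sets were computed on group means or on per-plot
averages is not recoverable; group means over samples are used and flagged.

`bootstrap_contrast` attaches a percentile bootstrap CI (default 2,000
replicates, 95%) to one feature's change: samples are resampled with
replacement independently within condition and reference; replicates with a
resampled reference mean of 0 are dropped and counted. Percentile intervals
were chosen over BCa for transparency. A condition group that is entirely
zero is reported as absent (relative change −100%, degenerate CI) — the
"compound undetected in all samples" case. Be aware that percentile
intervals at very small group sizes (n ≈ 8) run below nominal coverage
(~90–91% rather than 95%) because resampling understates sampling
variability; this is a property of the method, not of its implementation,
and is visible in the package's own coverage simulations.

## Mixed models

`fit_lme` fits `response ~ condition + (1 | block-or-site)` by REML via
`nlme::lme` — the standard routine for this model class — releveled so every fixed effect is a contrast against the
reference condition, with Wald p-values at the residual-df approximation
(recorded in the output; the original df method is unstated). A fit with
zero random-intercept variance is valid and flagged as boundary; a constant
response short-circuits to a degenerate zero fit. The package reports a
single Δ (estimate, SE, p) per contrast.

## The synthetic-data generator

`make_design` expands a factorial `design_spec` into sample metadata: the
default experimental template (2 overstory x 3 warming x 2 precipitation
levels, 6 replicates per cell) yields 72 plots and the observational
template (2 x 2, 3 replicates) yields 12, with plots assigned round-robin to
blocks within each cell so blocks are treatment-balanced.

`simulate_tables` draws a feature universe in which a `shared_fraction` of
features is detectable in both polarities (negative mass = positive mass −
`polarity_offset`, identical RT up to a jitter kept below the matching
tolerance) and generates intensities as

```
intensity = lognormal feature baseline x block effect x sample noise
            x delta (for condition/feature pairs in the effect sets)
```

with turnover features forced absent in (or present only in) their
condition, and present cells dropping to zero with a small probability.
Defaults emulate a Year-1-scale species group: ~1,900 features, log-normal
baseline (meanlog 13, sdlog 1.5; median ≈ 4e5, the Orbitrap peak-area
scale), sample noise CV 0.25, block SD 0.25 on the log scale, dropout 0.02,
shared fraction 0.3. Effect sizes are not recoverable from published
relative-change tables, so condition effects delta are free parameters; the
package's own simulations use delta in [1.75, 4], straddling the ±75%
classification threshold. Adjusted masses are drawn with a minimum spacing
of 0.05 Da (10x the default mass tolerance) so that cross-polarity matching
on generator output is unambiguous by construction — real data offer no such
guarantee, which is exactly why the matcher verifies mutual consistency and
reports unmatched features.

What the generator does *not* emulate: correlated features (co-regulated
pathways), isotopes and adducts beyond the single two-proton relationship,
RT drift, batch effects, or heteroscedastic instrument noise. Passing tests
on generator output therefore demonstrate algorithmic correctness
(recovery of planted structure under the stated noise model), not robustness
to every artifact of real instrument data.

## Orchestration

`run_pipeline` executes the full chain from one config (list or YAML):
simulate or load → RT-trim per polarity → match/merge → richness +
Canberra/Jaccard → perMANOVA (profiles and turnover, strata = blocks) +
dispersion + mean dissimilarities → NMDS + ellipses → shift report →
richness LME. Species-year groups are analyzed independently (no cross-year
pooling). Every seed and parameter is echoed into a versioned JSON report
containing nothing time- or machine-dependent, so identical configs give
byte-identical reports. The exported functions are the package's interface;
each pipeline stage is equally callable on its own.

```{r example, eval = FALSE}
cfg <- list(
  simulation = list(
    design = list(factors = list(temp = c("ambient", "warm"),
                                 light = c("low", "high")),
                  replicates_per_cell = 3, blocks = 3),
    species = "birch", year = "Y1",
    truth = list(seed = 42, n_features_total = 200, shared_fraction = 0.3,
                 effects = list(`warm+low` = list(n_features = 20, delta = 3)))
  ),
  reference = "ambient+low",
  n_perm = 999
)
report <- run_pipeline(cfg, outdir = "run1")
print(report)
```

## Verification strategy and problem sizes

The test suite checks every stage against an independent oracle: hand
arithmetic for the distance and threshold examples; classical one-way ANOVA
for the 1-D pseudo-F identity; brute-force enumeration over all label
assignments for exact permutation p-values; brute-force PAVA for the
isotonic subroutine; planted ground truth for fusion recovery, richness, and
shift membership; and `vegan` (adonis2, betadisper, meandist, monoMDS) as an
independent reference implementation on shared instances. Monte-Carlo
properties run at deliberately modest sizes chosen to keep the suite quick
while leaving binomial noise well inside the asserted bands: 500 null
permutation tests (n = 10/group, 500 features, 999 permutations) for type-I
calibration, 100 powered replicates, 500 outer replicates for bootstrap
coverage, and 300 mixed-model fits. All simulation entry points take
explicit seeds, and identical seeds reproduce results bit for bit.

## Known limitations

* One-way perMANOVA only; interaction decomposition of the factorial is
  deliberately out of scope.
* Greedy one-to-one matching can be suboptimal in pathological clusters of
  near-coincident masses; the mutual-consistency verification and the match
  report make such cases visible rather than silent.
* Percentile bootstrap CIs undercover at very small group sizes (see
  above).
* The spatial median on mixed real/imaginary PCoA geometry follows the
  per-axis-set convention; other software may optimize a slightly different
  objective, so dispersion values agree closely but not to machine precision
  across implementations.
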