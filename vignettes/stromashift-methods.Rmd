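---
title: "Methods: quantifying chemotherapy-induced CAF remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chemotherapy-induced CAF remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromashift)
```

# Scope and scientific background

Solid tumor stroma hosts heterogeneous cancer-associated fibroblast (CAF)
populations. Four populations, CAF-S1 to CAF-S4, are distinguishable by
immunohistochemistry through the joint levels of FAP, CD29, SMA and FSP1:
CAF-S1 (FAP-positive, myofibroblast-rich, ANTXR1+/YAP1-active) and CAF-S4
(FAP-negative but CD29/SMA-high) are activated states linked to
immunosuppression and T-cell exclusion, while CAF-S2 and CAF-S3 resemble
normal fibroblasts. This package implements the quantitative machinery
needed to ask whether cytotoxic treatment shifts tumors from activated
toward normal-like stroma and whether that shift tracks CD8+ T-cell
infiltration: pathology scoring arithmetic, a threshold-based population
classifier, paired delta statistics, spatial co-occurrence and
neighborhood-enrichment statistics on segmented cell maps, factorization
of spot-level expression into programs, and regulon-based
transcription-factor activity.

The patient cohorts motivating this design are controlled-access, so the
package ships generators that emit every input with known ground truth.
All empirical statements below are properties the test suite or the
acceptance script computes on those synthetic data.

# IHC scoring

The H-score of a marker in a compartment is `intensity × %positive`, with
intensity on a 0–4 ordinal scale and percentages on 0–100, giving a 0–400
range. The 0–4 scale (rather than the also-common 0–3/300 convention) is
the package default; `max_intensity` overrides it. Intensities may be
fractional, since readers often average fields. Percentages must be on
0–100: values in [0, 1] are rejected rather than silently rescaled,
because a silent 100× error is the worst failure mode of this arithmetic.

Nuclear localization (used for YAP1) is
`%nuclear-among-positive × %positive-among-total / 100`, a 0–100 product.
TIL densities are counts per area; when counting uses representative
fields (conventionally five fields of 0.105 mm²), the total count over the
summed field area is the density, and density is invariant to how a count
is split across fields. Densities can be normalized to total section area
or to a single compartment's area; both are legitimate and the caller
chooses via `area_mm2`.

Delta scores are strictly `after − before` per patient and variable;
`compute_delta()` requires exactly one observation per timepoint and
errors otherwise, because a silently dropped unpaired patient would bias
every downstream paired test.

# The CAF population classifier

Thresholds are the Q1/median/Q3 of a reference distribution per marker,
computed with linear interpolation between order statistics
(`stats::quantile` type 7) — the method is pinned because reproducibility
of cut points matters more than any particular quantile convention. Level
codes are upper-inclusive (`value ≥ cut` takes the higher level) so ties
are deterministic.

The decision tree is fixed from the populations' published ordinal marker
profiles, ordered FAP → SMA/CD29 → FSP1:

1. `FAP ≥ median(FAP)` → CAF-S1 (FAP is the CAF-S1-specific marker, so it
   is tested first);
2. else `SMA ≥ Q3(SMA)` **and** `CD29 ≥ median(CD29)` → CAF-S4;
3. else `FSP1 ≥ median(FSP1)` → CAF-S3;
4. else CAF-S2.

Whether CD29 acts as a conjunct or only as a tie-breaker in step 2 is not
recoverable from the ordinal profiles alone, so it is exposed as
`cd29_rule = c("and", "tiebreak")`, defaulting to the conjunction (the
stricter reading of the CAF-S4 profile).

Thresholds should be learned on a dedicated learning set and then applied
— mirroring how such classifiers are calibrated on one cohort and
deployed on another. When no learning set is supplied,
`classify_cohort()` falls back to the cohort's own pooled quartiles
(quantile matching). The fallback is convenient but noisier: with a
bimodal marker whose high-level mass sits near the quantile's fraction,
the empirical cut drifts into a cluster tail by an amount governed by
binomial fluctuation of the mixture, so a large learning set (the test
suite uses 2,000 synthetic samples) gives materially better recovery than
self-quantiles on 35 patients.

# Synthetic cohort generator

`generate_cohort()` emulates a paired before/after cohort. Design choices
and defaults:

- **Marker profiles.** Population means live on an ordinal grid
  Neg = 20, Low = 80, Med = 160, Med-High = 220, High = 280 (H-score
  units). CAF-S1 is (FAP 280, CD29 160, SMA 220, FSP1 220, ANTXR1 220,
  YAP1 220); CAF-S4 is (20, 280, 280, 160, 80, 160); CAF-S2 is
  quadruple-low; CAF-S3 is FSP1-high (280). Two placements deserve
  comment. CAF-S1's SMA sits at Med-High rather than High because SMA
  positivity in CAF-S1 is qualitatively below CAF-S4's hallmark High —
  and keeping the two apart lets a quartile cut separate them. CAF-S3's
  FSP1 sits at High so that the FSP1 median cut falls inside the
  (irrelevant at that branch) CAF-S1 cluster rather than between CAF-S3
  and the cut, which keeps the S2/S3 split robust. The grid is only a
  convention — the profiles are ordinal in the literature, not
  quantitative — and the matrix is overridable.
- **Mixture.** `mix_before = (0.50, 0.10, 0.15, 0.25)` for S1..S4, i.e.
  75% activated at diagnosis, a realistic figure for this tumor type. It
  also places the FAP-high mass at 50% and the SMA-High mass at 25%, so
  the FAP-median and SMA-Q3 cuts of a learning cohort fall near the
  cluster boundaries by design.
- **Treatment effect.** Each activated patient switches to a normal-like
  population with probability `switch_prob = 0.42` (the order of the
  observed activated-fraction drop from ~3/4 to ~3/7), and switching
  patients additionally shrink their FAP/SMA/ANTXR1 means by
  `shrink = 0.7`. Restricting the shrink to switchers keeps the
  zero-noise, zero-switch configuration an exact identity (after ≡
  before), which anchors several tests. No quantitative effect sizes for
  the marker shifts exist in the literature — only directions — so these
  are conventions, stated once and not tuned.
- **Noise.** Truncated-normal marker noise (`noise_sd = 20` H-score
  units, clipped to [0, 400]), on the order of inter-observer variability
  for H-scores; H-scores are bounded so clipping is the honest model.
- **TIL coupling.** The per-patient change in CD8+ density is generated
  from a Gaussian copula on the ranks of the patient's ΔFAP with latent
  Pearson correlation `2 sin(π ρ_s / 6)`, the exact inverse of the
  normal-copula Spearman map, so the population Spearman of (ΔFAP,
  ΔCD8-density) equals `rho_true` (default −0.6) up to sampling noise.
  When ΔFAP is degenerate the TIL deltas are exactly zero, preserving the
  zero-noise identity. Counts are rounded onto a 0.525 mm² field area;
  baseline densities are gamma-distributed (mean 400 cells/mm²) so the
  floor at zero is essentially never hit.

What the generator does *not* emulate: real marker correlations within a
population, observer drift, intratumoral heterogeneity across blocks, or
any transcriptome realism. Passing recovery tests therefore demonstrates
the pipeline's correctness on data satisfying its assumptions, not
performance on real cohorts.

# Spatial statistics

Coordinates are 2-D (tissue sections) and distances Euclidean in the
map's units. The co-occurrence ratio for reference label `a`, target `b`
and radius `r` is

```
ratio(b | a, r) = [N_ab(r) / N_a.(r)] / (n_b / n)
```

with `N_ab(r)` the ordered pairs (i ≠ j) from `a` to `b` within `r`,
`N_a.(r)` all ordered pairs from `a` within `r`, and `n_b / n` the
marginal frequency of `b` over all cells. Pinned conventions: self-pairs
are excluded from numerator and denominator; the marginal includes the
reference label's own cells; the ratio is NaN where no pair from `a`
exists. Radii default to 50 cumulative equal-width bins up to a quarter
of the window diagonal. Under complete spatial randomness the ratio is 1
at every radius (the suite verifies 20-seed means within [0.9, 1.1]);
values above 1 mean attraction, below 1 exclusion. No edge correction is
applied — a known limitation shared with the common screening usage of
this statistic; near-boundary reference cells see truncated disks, which
cancels in the ratio's first order but not exactly.

Neighbor graphs: `knn(k)` (default k = 6, union-symmetrized), Delaunay
triangulation, or fixed-radius. The triangulation is computed by
Bowyer–Watson insertion on coordinates normalized to the unit box;
degenerate (collinear) inputs fall back to a radius graph at 1.5× the
median nearest-neighbor distance with a warning. Neighborhood enrichment
compares each unordered label pair's edge count against uniform label
shuffles: `z = (obs − mean_perm)/sd_perm`, NaN when the permutation sd is
zero. The label vector is shuffled whole — node positions and graph are
fixed — and the seed fully determines the permutation stream. Presentation
filtering (dropping label pairs from a plot) must happen after computing
on the full label set; the API only ever computes on the full set.

The spatial generator plants interactions with the simplest point
processes carrying the right sign: exclusion by rejection sampling
(capped at 10,000 rounds, then an explicit error — an exclusion radius
covering the window is unsatisfiable, not retryable) and attraction by a
Thomas cluster process (Poisson offspring counts, isotropic Gaussian
displacement, resampled into the window).

Positivity thresholding offers a fixed cut, Otsu's criterion (exhaustive
scan of candidate cuts — midpoints of consecutive distinct values —
maximizing between-class variance; note the criterion is flat across
empty gaps, so any cut in the widest gap is equally optimal), and a
two-component Gaussian mixture (cut at the equal-weighted-density
crossing between the component means). The positive call is always
`intensity ≥ cut`.

# Expression programs and spot-level analysis

**NMF.** Lee–Seung multiplicative updates minimizing
`||X − WH||_F²`, with `1e-12` added to update denominators, random
uniform nonnegative initialization scaled to the data, and a relative
objective-change stopping rule (`tol = 1e-5`, `max_iter = 200`). The
squared-Frobenius objective is chosen for testability (its update has a
clean monotonicity guarantee, asserted on every tested input); R packages
used elsewhere for this analysis default to Kullback–Leibler objectives,
so numeric parity with them is explicitly not claimed.

**Consensus NMF.** For each K: repeated seeded runs (convention: 200 per
K over K = 5..13 at scale; scaled down in tests), program rows
L2-normalized and pooled; components whose mean Euclidean distance to
their nearest neighbors (30% of the run count) exceeds the local-density
threshold (default 0.1) are discarded as outliers; survivors are k-means
clustered into K consensus programs (component medians), and usage is
refit by nonnegative least squares (multiplicative updates with programs
fixed). Stability is the mean silhouette width of the component
clustering; error the relative Frobenius reconstruction error; the
reported K is the caller's choice or the stability maximum. A K whose
components are all filtered is marked unstable rather than fatal. With a
single run per K the procedure reduces exactly to plain NMF.

**Gene-set scores.** Mean log-expression of the set genes minus that of
control genes drawn per set gene from the same average-expression bin
(defaults: 24 bins, 100 controls per set gene, sampled without
replacement where the bin allows, set genes excluded from control pools).
This is the conventional expression-matched control construction for
signature scoring; the bin count and control count are exposed. Scores on
exchangeable (null) gene sets center on zero; adding a constant to the
set genes shifts the score by exactly that constant when controls are
held fixed (the default path re-bins, so the shift is exact only up to
bin reassignment). Real signature lists (e.g. TEAD targets for YAP1
activity) must be user-supplied; tests use synthetic sets.

**TF activity.** Regulons (tf, confidence A–E, target, mode ±1) are
filtered to high confidence (A–C by default); activity of a TF in a cell
is the mean over its targets of `mode × z(target, cell)`, with z the
gene standardized across cells. This mode-weighted mean is a deliberate
simplification of published regulon-enrichment algorithms with the same
sign semantics — simple enough to verify against planted activities,
which it recovers at Pearson ≥ 0.98 under the generator's default noise.
Constant genes get z = 0 rather than NaN. Additive shifts of a target
cancel exactly.

**Spot enrichment.** A spot is enriched for a cell type when its rounded
deconvolved abundance reaches `min_cells` (default 1). Rounding is
half-to-even, matching the "sum of rounded estimated cell numbers"
convention of abundance post-processing.

# Cohort statistics

All tests are two-sided. Conventions, each pinned because printed
p-values must be reproducible:

- **Fisher exact (2×2):** sum of hypergeometric probabilities of all
  margin-compatible tables no more probable than the observed one (with a
  `1 + 1e-7` relative tolerance against floating-point ties) — the
  definition mainstream statistical software prints. On the activated-CAF
  repartition table [[26, 9], [15, 20]] this gives p = 0.0146, i.e. 0.01
  at two decimals.
- **Wilcoxon signed-rank:** zeros dropped, absolute differences
  mid-ranked; exact null by enumerating all 2^m sign assignments for
  m ≤ 12 (the distribution is symmetric, so the two-sided p is the mass
  at least as far from m(m+1)/4 as observed); for larger untied samples
  the classical exact signed-rank distribution; tied larger samples use a
  normal approximation with tie and continuity corrections.
- **Mann–Whitney:** U with mid-ranks; enumeration over all rank
  assignments for pooled n ≤ 12; classical exact U null for larger untied
  data; corrected normal approximation under ties.
- **Spearman:** Pearson correlation of mid-ranks; full n! permutation
  null for n ≤ 8 (40,320 permutations at the cutoff, comfortably below a
  second), t-approximation on n − 2 degrees of freedom beyond.
- **Benjamini–Hochberg:** standard step-up with monotonicity, returned in
  input order.

The enumeration cutoffs (m ≤ 12, n ≤ 8) keep exact computation
instantaneous; the suites verify exact-regime equality against
independent enumeration oracles and 0.05 ± 0.02 type-I calibration under
simulated nulls for every test.

# Problem sizes and runtime

The test and acceptance workloads use: 2,000-sample learning cohorts and
200-patient analysis cohorts for classifier recovery; 2,000-cell maps
(20 seeds) for co-occurrence calibration; a 200-cell graph with 500
random-label replicates (150 permutations each) for enrichment
calibration; 300 × 200 Poisson matrices for NMF recovery and
150 × 120 with 20 runs for consensus; 500 cells for TF-activity
recovery; 2,000 replicates per test for type-I calibration. These sizes
give stable estimates (binomial/Monte-Carlo error well inside every
asserted band) while keeping the whole suite around a minute.

# Known limitations

- The classifier's decision-tree rule order and the CD29 conjunction are
  reconstructions from ordinal profiles; both are configurable but the
  published variants differ across cohorts.
- Co-occurrence and enrichment ignore window edge effects.
- The NMF objective deviates (documented above) from the KL-based
  defaults of some established implementations.
- The gene-set and TF-activity scores are transparent reconstructions of
  their families of methods, not numerically identical to any specific
  published implementation.
- Synthetic cohorts make no attempt at transcriptome- or image-level
  realism; they exist to give every estimator a known truth.
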