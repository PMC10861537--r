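# stromashift

Tools for quantifying how chemotherapy remodels cancer-associated
fibroblast (CAF) populations in solid tumors — high-grade serous ovarian
cancer being the motivating setting — and how that remodeling relates to
CD8+ T-cell infiltration.

Tumor stroma hosts four CAF populations, CAF-S1 to CAF-S4, distinguished
by the combined levels of four markers (FAP, CD29, SMA, FSP1). CAF-S1 and
CAF-S4 are activated, myofibroblast-like states associated with
immunosuppression; CAF-S2 and CAF-S3 are normal-like. The package covers
the full quantitative chain used to study a treatment-induced shift from
activated to normal-like stroma:

- **IHC scoring** — H-scores (staining intensity 0–4 × percent positive
  cells, range 0–400), nuclear-localization scores
  (`%nuclear-among-positive × %positive-among-total / 100`),
  tumor-infiltrating-lymphocyte densities (cells/mm²), and per-patient
  paired delta scores `Δ = after − before`.
- **CAF population classifier** — per-marker quartile thresholds (Q1,
  median, Q3) learned from a reference distribution, ordinal level codes
  (Neg/Low/Med/High), and a decision tree: FAP ≥ median → CAF-S1; else
  SMA ≥ Q3 and CD29 ≥ median → CAF-S4; else FSP1 ≥ median → CAF-S3; else
  CAF-S2. Cohort repartition tables collapse to the activated vs
  normal-like 2×2 for testing.
- **Spatial statistics** on segmented, labeled cell maps (GeoJSON or CSV):
  positivity thresholding (fixed / Otsu / 2-component Gaussian mixture),
  co-occurrence probability-ratio curves
  `ratio(b | a, r) = P(b within r of an a cell) / P(b)`,
  k-nearest-neighbor / Delaunay / radius neighbor graphs,
  permutation z-scores of inter-label edge counts (neighborhood
  enrichment), and nearest-distance distributions with censoring.
- **Expression programs** — non-negative matrix factorization
  (Lee–Seung multiplicative updates on the squared Frobenius objective)
  and consensus NMF over repeated seeded runs with local-density outlier
  filtering; gene-set scores against expression-matched control genes;
  regulon-based transcription-factor activity (mode-of-regulation-weighted
  mean of target z-scores, confidence classes A–C); deconvolved-abundance
  spot enrichment.
- **Cohort statistics** with exact small-sample nulls — Fisher's exact
  2×2 test by full hypergeometric enumeration, paired Wilcoxon signed-rank
  and Mann–Whitney with enumerated or classical exact nulls, Spearman
  correlation with a full-permutation null at small n, and
  Benjamini–Hochberg adjustment.
- **Synthetic data generators** for every input — paired marker cohorts
  with planted population mixtures, treatment switching, and a planted
  ΔFAP/ΔCD8 anti-correlation; spatial point patterns with planted
  exclusion/attraction; spot×gene counts from planted programs; target
  expression from planted TF activities — so the entire pipeline is
  testable without any patient data.

## Worked example

Learn thresholds from a synthetic learning cohort, classify a paired
40-patient cohort, and test the activated→normal-like shift and the
ΔFAP/ΔCD8 anti-correlation:

```r
library(stromashift)

learn <- generate_cohort(2000, seed = 100)
mk <- learn$markers[learn$markers$timepoint == "before", ]
th <- learn_thresholds(split(mk$hscore, mk$marker),
                       provenance = "synthetic learning cohort")

cohort <- generate_cohort(40, seed = 7)
calls  <- classify_cohort(cohort$markers, th)
rp     <- cohort_repartition(calls)
rp$counts
#>          population
#> timepoint CAF-S1 CAF-S2 CAF-S3 CAF-S4
#>    before     24      7      5      4
#>    after      19     10     10      1

fisher_exact_2x2(rp$activated_2x2)
#> Fisher's exact test (two-sided) (exact)
#>   statistic = 28   p = 0.1095085   n = 80

d    <- compute_delta(cohort$markers)
dfap <- d[d$marker == "FAP", ]
cd8  <- cohort$tils[cohort$tils$cell_type == "CD8", ]
cd8$density <- compute_til_density(cd8$count, cd8$area_mm2)
dcd8 <- compute_delta(cd8, value = "density", by = "cell_type")
spearman_test(dfap$delta[order(dfap$patient_id)],
              dcd8$delta[order(dcd8$patient_id)])
#> Spearman correlation (two-sided) (approximate)
#>   statistic = -0.5461538   p = 0.0002668406   n = 40
```

At n = 40 the treatment shift (28/40 activated before vs 20/40 after) is
visible but not significant (p = 0.11); the planted anti-correlation of
−0.6 between the change in FAP H-score and the change in CD8+ TIL density
is recovered as rho = −0.55 with p < 0.001. The vignette
(`vignettes/stromashift-methods.Rmd`) documents the models, defaults and
their rationale.

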