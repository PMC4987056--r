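# asphyxNMR

An end-to-end ¹H-NMR metabolomics pipeline for plasma and urine profiles
from newborn piglets subjected to progressive asphyxia, cardiac arrest and
cardiopulmonary resuscitation — the standard animal model for studying
neonatal resuscitation protocols. The package is aimed at researchers who
want a tested, fully scriptable re-implementation of this analysis chain,
together with a synthetic cohort generator that reproduces the study design
and published concentration summaries so that every stage can be validated
against known ground truth.

## What it computes

* **Spectral preprocessing** — zero-order phase correction on the TSP
  reference, separate linear baselines around the water artifact,
  chemical-shift referencing (glucose doublet at 5.24 ppm for plasma, TSP at
  0.0 ppm for urine), clipping to −0.5…9.0 ppm, normalization to the TSP
  area, TSP linewidth (FWHM) as a lipoprotein proxy, an adaptive asymmetric
  penalized-least-squares baseline, and excision of the water/TSP/urea
  regions.
* **Quantification** — metabolite concentrations from window integrals
  referenced to TSP: `c = (area/protons) / (tsp_area/9) × c_TSP`, with an
  analytic Lorentzian coverage correction for window truncation and
  overlapped neighbours, and urinary creatinine normalization.
* **Chemometrics** — unit-variance scaling, PCA (SVD), NIPALS PLS and
  PLS-DA with segment-wise cross-validation (R², Q² = 1 − PRESS/TSS),
  repeated-CV misclassification counts (NMC) against a permuted-label null,
  and back-scaled loading plots (amplitude ∝ covariance, color =
  correlation).
* **Univariate statistics** — log-transformed ANOVA, paired signed fold
  changes FC (ratio if ≥ 1, else −1/ratio) with Benjamini–Hochberg
  q-values, Pearson correlations with time-to-asystole / time-to-ROSC, and
  survivor vs non-survivor Welch t-tests.
* **Correlation structure** — all-pairs Pearson matrices of matched plasma
  and creatinine-normalized urine variables, ordered by average-linkage
  clustering on 1 − r, with |r| > 0.5 masking of the lower triangle.
* **Synthetic cohorts** — study design (six resuscitation groups, sample
  availability, survival), log-normal concentration trajectories
  moment-matched to published median/IQR summaries with signed fold-change
  transitions, and a Lorentzian spectral forward model with injected phase,
  shift, baseline, background and noise errors recorded as ground truth.

## Worked example

Simulate a 100-animal plasma baseline cohort, render and preprocess the
spectra, quantify against TSP, and compare two time points:

```r
library(asphyxNMR)

design <- study_design()                      # the six-protocol design
cohort <- sample_cohort(design, seed = 5)
model  <- concentration_model(plasma_reference_table())
conc   <- sample_concentrations(model, cohort, timepoints = "t1", seed = 6)
panel  <- metabolite_panel("plasma")

ids     <- cohort$animals$animal[1:100]
spectra <- simulate_spectra(conc, cohort, panel, timepoint = "t1",
                            seed = 7, animals = ids)
prep    <- lapply(spectra, preprocess_spectrum)
qmat    <- quantify_cohort(prep, panel)

median(qmat[, "Lactate"])   # 2.911835  (configured cohort median: 2.9 mM)
median(qmat[, "Glucose"])   # 6.003025  (configured cohort median: 6 mM)
```

The recovered cohort medians agree with the generator's configured baseline
medians to a fraction of a percent; individual small signals (e.g. acetate
at ~0.005 mM) are noise-limited. A paired time-point contrast at the
concentration level:

```r
conc2 <- sample_concentrations(model, cohort, timepoints = c("t1", "t2"),
                               seed = 6)
m1 <- log_transform(concentration_matrix(conc2, "t1"))
m2 <- log_transform(concentration_matrix(conc2, "t2"))
fc <- paired_fold_change(m1, m2)
fc[fc$metabolite == "Lactate", c("fc", "p", "q")]
#         fc            p            q
#   3.066200 1.106997e-67 5.719487e-67
```

The signed fold change reproduces the configured t1→t2 lactate transition
(3.07). `pls_fit()` / `cross_validate()` / `nmc_permutation_null()` provide
the multivariate layer, and `run_pipeline(pipeline_config(...))` executes
the whole chain with a manifest for provenance.

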