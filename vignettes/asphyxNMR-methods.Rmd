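---
title: "Methods: simulation and analysis of 1H-NMR metabolomics in newborn asphyxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of 1H-NMR metabolomics in newborn asphyxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and scientific setting

`asphyxNMR` implements the complete computational chain used for untargeted
^1^H-NMR profiling of plasma and urine from newborn piglets subjected to
progressive asphyxia, cardiac arrest and cardiopulmonary resuscitation.
Samples are drawn at baseline (t1) and 2 h (t2) and 4 h (t3) after return of
spontaneous circulation (ROSC), across six resuscitation protocols differing
in initial ventilation time, oxygen fraction and compression:ventilation
ratio. The chain has five analysis layers — spectral preprocessing,
TSP-referenced quantification, PLS/PLS-DA chemometrics with permutation-based
misclassification testing, univariate signed fold-change and endpoint
statistics, and clustered correlation structure — plus a synthetic cohort
generator that reproduces the study's design and published concentration
summaries so that every stage can be validated end-to-end against known
ground truth. No public raw data exist for this design; the generator *is*
the package's testbed, and its defaults are the study conditions.

## The synthetic cohort generator

### Study design and endpoints

`study_design()` encodes the six pooled protocol groups (n = 21, 32, 21, 8,
16, 12), per-group sample availability rates for each material and time
point, and per-group median/IQR summaries of the time to asystole and the
time to ROSC. Animal endpoints are drawn log-normally from those summaries.
The published footnote labels both times as seconds, while the asphyxiation
protocol (ventilator rate reduced every 10 min) operates on a minutes scale;
the generator therefore stores an explicit unit field, defaulting to minutes
for time-to-asystole and seconds for time-to-ROSC, and makes no further
guess. Survival is Bernoulli with default probability 0.85 (no per-group
rate is published); non-survivors contribute no post-ROSC samples.

### Concentration trajectories

Baseline concentrations are log-normal per metabolite, moment-matched to the
printed median and IQR: `mu = log(median)`,
`sigma = log(q3/q1) / (2 * qnorm(0.75))`. Two guards keep the marginals
physiologic:

* When the printed lower quartile is 0 or below a tenth of the median it
  reflects a detection floor, not log-normal spread; a full-IQR fit would
  imply `sigma` of 3–4 and occasional *molar*-range draws (plasma glycerol,
  acetate). For such metabolites `sigma` is fit from the upper half-spread
  `log(q3/median)/qnorm(0.75)` — the median and upper quartile still match
  the printed values exactly, the lower quartile does not.
* Latent normal scores are winsorized at ±3 sd. Quartiles are unaffected.

Later time points are built multiplicatively within animal:
`x(t2) = x(t1) * ratio(FC) * exp(noise)`, where `ratio` is the unsigned
ratio of the signed fold change (+2 doubles, −2 halves) and the
within-animal log-noise sd defaults to 0.25 (the published tables carry
only marginal summaries, so the within-animal correlation is a package
choice, configurable). Latent scores are drawn by stratified inversion
(Latin-hypercube style) by default: each score occupies one probability
stratum, so a finite cohort reproduces the configured median/IQR almost
exactly instead of carrying the ~12% relative sampling noise an i.i.d.
cohort median of a heavy-tailed metabolite would have. This serves the
generator's stated purpose — emulating the *printed* quantile structure —
and `sampling = "iid"` restores independent draws where true sampling
variability is wanted (all calibration tests of the statistical layer use
i.i.d. noise).

### Spectral forward model

`render_spectrum()` renders each identified panel signal as a Lorentzian
multiplet (absorption + dispersion) with total integrated area
`concentration x protons`, sharing one global area constant with the
9-proton TSP singlet at 0.0 ppm (default 0.5 mM; the true additive
concentration is not published, and only ratios matter). Defaults: grid
−1…10 ppm with 16384 points; metabolite half-width at half-maximum
0.0015 ppm; doublet/triplet spacing 0.012 ppm and a generic five-line
multiplet at 0.008 ppm spacing (no J values are published); TSP FWHM
0.003 ppm, widened per animal by a log-normal broadening factor matched to
the published plasma TSP-FWHM summaries (median 0.0047, IQR 0.003–0.007 ppm
— the lipoprotein proxy). Material backgrounds are broad Gaussians: plasma
lipid bands at 0.9 and 1.3 ppm (sd 0.08–0.09 ppm) and a macromolecule hump
at 2.2 ppm (sd 1.2 ppm); urine a urea band at 5.8 ppm; both plus a residual
water artifact at 4.7 ppm, a linear baseline drift, a zero-order phase error
(default uniform ±20°), a chemical-shift offset (uniform ±0.01 ppm) and
complex Gaussian noise (sd 1 intensity unit, i.e. one area unit per ppm).
Injected phase, offset and broadening are recorded in the spectrum metadata
as ground truth. Unknown signals (arbitrary units, unknown proton count)
are carried through the concentration-level simulator and statistics but
are *not* rendered into spectra.

What the generator does **not** emulate: pH-dependent chemical-shift drift
(the EDTA/citrate effect), peak-shape deviations from Lorentzian,
frequency-dependent (first-order) phase errors, inter-metabolite biological
correlation beyond shared animal trajectories, and within-animal drift of
the TSP broadening over time points. Passing recovery tests therefore
demonstrate correctness of the algorithms under the stated forward model,
not robustness to every artifact of real spectra.

## Preprocessing

The pipeline order is fixed and logged in each spectrum's history:
zero-order phase correction → separate linear baselines up/downfield of the
water artifact → chemical-shift referencing → clipping to −0.5…9.0 ppm →
TSP-area normalization → TSP FWHM measurement → adaptive baseline → region
excision (water, TSP, and urea for urine).

Numerical choices that matter:

* **Phase.** The angle is read off the argument of the complex sum over a
  window symmetric around the TSP line center (located sub-grid by
  parabolic interpolation of the modulus, with fractional edge weights).
  Symmetry cancels the line's own dispersion; a locally linear complex
  background, estimated from interpolated values at exactly symmetric
  flanking points, removes far-peak dispersion tails. Recovery is within
  ~0.03° noiseless and well under 1° at default noise.
* **Referencing.** Plasma anchors on the anomeric glucose doublet: the pair
  of maxima ~J apart with the largest summed height, each line refined by a
  quadratic fit to 1/y (exact for a Lorentzian), centered at 5.24 ppm.
  Pair detection is robust to offsets larger than J/4, where a nearest-line
  rule would lock onto the wrong doublet line. Urine anchors on TSP at
  0.0 ppm. Residual alignment error is ~1e-5 ppm, which matters because
  unmixing overlapped signals is alignment-sensitive.
* **Linear baselines.** One straight line per side of the water interval
  through robust lower-envelope support points (lowest-decile point of each
  of 32 sub-windows).
* **Adaptive baseline.** Asymmetric penalized least squares on a
  block-median-decimated trace (blocks of 8 points): metabolite lines a few
  points wide vanish into the medians, so the smoother follows broad
  lipid/protein envelopes without fighting sharp peaks; asymmetry p = 0.01,
  second-difference penalty lambda = 4000 on the decimated grid (effective
  smoothing width ~0.04 ppm). Because an asymmetric envelope fit settles
  below the noise mean, the baseline is re-centered so that non-peak
  residuals have median zero — without this, every narrow integration
  window would inherit a positive pedestal of roughly one noise sd.
* **Region bounds.** Water 4.55–5.0 ppm (a 4.5 lower bound would delete the
  urine ascorbate signal at 4.52 ppm that the study quantifies), urea
  5.4–6.2 ppm, TSP ±0.2 ppm. The published text names these regions without
  bounds.

## Quantification

Each identified signal is integrated over a narrow window (multiplet
half-span + 6 half-widths) **above a local chord**: the straight line
through the mean levels of ~10 grid points flanking each window edge. The
chord removes any locally linear background — including whatever the
baseline steps left behind — and is a linear operation, so it can be
corrected exactly. A coverage matrix `C[i, j]` holds the chord-subtracted
area that signal *j*'s unit-area multiplet would leave in window *i*,
evaluated numerically on the spectrum's own grid (grid sampling, edge and
flank effects included) for neighbours within 0.1 ppm; solving
`C a = a_measured` corrects simultaneously for each signal's own tail
truncation and for spill-over between overlapped neighbours (succinate
2.40 / pyruvate 2.37; methionine 2.63 / malate 2.65; creatinine 4.05 /
myo-inositol 4.06). This is an analytic inversion under the shared-linewidth
Lorentzian assumption, not lineshape fitting: no parameter is optimized.
The TSP reference area is re-measured with the same chord operation on the
fully baseline-corrected spectrum (before excision) and divided by its own
numeric coverage, so numerator and denominator see identical treatment.
Concentrations follow `c = (area/protons)/(tsp_area/9) * tsp_conc`;
negative results are floored at zero. Windows lost to excision yield `NA`
with a warning. Urinary tables can be creatinine-normalized
(`creatinine_normalize()`), excluding — and reporting — samples without a
positive creatinine value.

Under this scheme a noiseless, background-free render recovers every panel
concentration within 1%, and the default noise/background render keeps the
median absolute relative error under 10% (small signals such as acetate at
~0.005 mM are individually noise-limited; the cohort *median* concentration
of the headline metabolites is recovered to well under 5%).

## Chemometrics

Variables are unit-variance scaled (`uv_scale()`); PCA is by SVD with a
deterministic sign convention. PLS/PLS-DA uses sequential NIPALS extraction
(weights from the dominant direction of the X'Y covariance, score-based
deflation); class responses are dummy-coded and centered, predictions
assign the nearest dummy target, which for two classes is the midpoint
threshold. Segment-wise cross-validation splits a sample *ordering* into
contiguous segments; scaling and model are refit inside every training fold
(no leakage), and `Q2 = 1 − PRESS/TSS` with TSS against training-fold means.
The default ordering is the given sample order — the classical run-order
reading of "segment-wise" — but all repeated procedures re-randomize the
ordering per repetition; with class-sorted input and a non-randomized
ordering the training-mean TSS is inflated and Q² can exceed R², so the
package-level drivers always pass a seeded random ordering.

The misclassification (NMC) test repeats the cross-validation with
re-randomized segment orderings (default 500 repetitions), reports the
median and 2.5–97.5 percentile interval, and compares against a null of NMC
values from label permutations (one CV repetition each, default 500). Two
p-values are reported and labelled distinctly: the empirical exceedance
`p = (1 + #{null ≤ observed median})/(nperm + 1)`, whose resolution is
bounded by the number of permutations, and a Wilcoxon rank-sum comparison
of the observed and null NMC distributions, which can become arbitrarily
small and is the natural reading of vanishingly small published p-values —
an empirical permutation p never can. Component count defaults to the
smallest achieving the maximal cross-validated Q². Back-scaled loadings
multiply first-component weights by each variable's original sd (amplitude
proportional to covariance with the score) and color by the Pearson
correlation with the response.

## Univariate statistics and correlation structure

Concentrations are natural-log transformed after replacing zeros by half
the smallest positive value of their column (the tables' zero IQR bounds
show zeros occur). Group effects use one-way ANOVA with optional pairwise
Welch t-tests; time-point changes use paired t-tests on within-animal log
differences, reported as signed fold changes (ratio if ≥ 1, else minus the
reciprocal) with Benjamini–Hochberg q-values per table; endpoint
associations are Pearson correlations of log concentrations (and TSP FWHM)
with time-to-asystole or time-to-ROSC; survival contrasts are unpaired
Welch t-tests at baseline. All-pairs correlation matrices use
pairwise-complete Pearson with per-cell n, ordered by average-linkage
hierarchical clustering on distance 1 − r (signed, because inverse
plasma–urine correlations are themselves of interest), either over all
variables or independently per material; the lower triangle can be masked
at |r| ≤ 0.5 for display, mirroring the published figure convention.

## Validation problem sizes

The test suite validates each operation against analytic or brute-force
oracles and the whole chain on generator cohorts: 100-animal plasma cohorts
for distribution recovery (full render at 16384 points), 100-pair cohorts
for fold-change recovery, 200 null simulations at n = 60, p = 100 for
permutation-p calibration (8 CV repetitions, 99 permutations each), 100
structureless instances for the Q² null, and 400–500 replicates for
ANOVA/t-test type-I checks. `scripts/acceptance.R` re-runs the cohort-level
recoveries from scratch at n = 100 under a caller-supplied seed.

## Known limitations

* Overlap correction assumes a shared, known linewidth and Lorentzian
  shape; strongly coupled multiplets or shape mismatch would bias the
  unmixing of minor signals (no deconvolution/fitting is attempted).
* The empirical permutation p is integer-granular and mildly conservative
  for small permutation counts.
* Urinary ascorbate sits at the edge of the water region; its recovery is
  systematically low by ~20% under the default water-artifact width.
* The generator's metabolites are conditionally independent given the
  animal trajectory; real metabolic covariation (e.g. lactate–pyruvate
  coupling) is only induced through shared time-course structure unless
  injected explicitly.
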