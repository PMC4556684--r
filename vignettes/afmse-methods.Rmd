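---
title: "Methods: time-scale multiscale entropy of AF ventricular response intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-scale multiscale entropy of AF ventricular response intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmse)
```

This vignette is the package's account of its science: the model and its
assumptions, the conventions chosen where the field leaves them open, the
synthetic-data generator and its calibration, and the limits of what the
test suite demonstrates.

## 1. Problem and pipeline

During permanent atrial fibrillation the ventricular response intervals
(VRIs) fluctuate irregularly. Conventional variability measures (SDVRI,
spectral band powers) describe the *magnitude* of fluctuation; multiscale
entropy (MSE) describes its *irregularity* as a function of time scale. The
quantity of interest is the mean sample entropy over the 90–300 s scale band
(`MeanEn_VLF2`), evaluated as a predictor of incident ischemic stroke.

The pipeline is: annotated beat stream → cleaned VRI series (ectopy and
artifact handling, eligibility report) → uniform 2 Hz signal (linear
interpolation) → MSE profile and band summaries plus conventional HRV
features → cohort statistics (group tests, C-statistics, Cox models,
Nelson–Aalen curves, cross-validation).

## 2. Preprocessing conventions

* **Tachogram anchor.** Each interval is anchored at the onset of its
  *terminating* beat — the common HRV tachogram convention. The source
  analyses do not state an anchor; the choice only shifts the signal by
  less than one beat.
* **Ectopy/artifact policy.** By default both intervals touching a `V` or
  `A` beat are dropped (`ve_policy = "drop_both"`); the literature does not
  state how ectopy-adjacent intervals were handled, so the policy is an
  explicit parameter. Dropped runs longer than 10 s are bridged by the
  subsequent interpolation but reported in `gaps`.
* **Artifact accounting by time.** The artifact fraction is the summed
  duration of artifact-adjacent intervals over the recording span, matching
  an exclusion rule phrased as a percentage of monitoring time; ectopy is
  counted per beat.
* **Eligibility is reported, never enforced** (`check_eligibility()`:
  ≥ 22 h, ≤ 5 % ventricular ectopy, ≤ 5 % artifact time), so short synthetic
  fixtures can flow through the same code paths.
* **Resampling.** Linear interpolation evaluated on a 0.5 s grid from the
  first interval anchor to the last; length `floor(span · 2) + 1`. A nominal
  24-h recording yields ≈ 172,801 samples (± the boundary convention).

## 3. Sample entropy and the MSE profile

`SampEn(m, t) = −ln(A/B)` with Chebyshev template distance and **strict**
inequality `< t`; self-matches are excluded; both template sets have
`N − m` members so every template can be extended. `A = 0` or `B = 0` yields
an *undefined* flag (`NA`), never infinity, and undefined scales are
excluded from band summaries.

Conventions, with rationale:

* **Tolerance reference.** `t = r · SD(scale-1 series)`, held fixed across
  scales (`r = 0.15`, `m = 2`), following the original MSE formulation. A
  per-scale variant (`r_reference = "per_scale"`) is exposed because the
  source is silent on this point. Fixing the tolerance makes white noise's
  profile decrease with scale (coarse-graining shrinks variance ∝ 1/τ)
  while 1/f-type noise stays scale-stable — the discriminating behaviour
  the analysis relies on.
* **Scale grid.** 20 log-spaced scales per decade over 2.5–300 s, snapped to
  integer τ at 2 Hz, duplicates removed. The exact grid used originally is
  unreported; MeanEn is insensitive to density, SlopeEn slightly less so.
* **Minimum length.** Scales whose coarse-grained series has fewer than 200
  points (full-series default) are flagged undefined.
* **Band edges.** Closed on both ends. The LF/VLF boundary appears both as
  6.5 s (methods text) and 6.7 s (a table footnote) in the source; the
  methods value is used and the bands are configurable.
* **Slope sign.** SlopeEn is fitted against `log10(scale in seconds)`;
  against `log10(frequency)` it would be the negation. Seconds are used
  because the band bounds are given in seconds.
* **Engine.** Template-match counting is C++ (Rcpp): template start indices
  are sorted by their first coordinate and only pairs within tolerance on
  that coordinate are examined (a two-pointer sweep). This prunes the pair
  space by the first-coordinate match probability (~8 % for Gaussian data at
  r = 0.15) and handles the smallest 24-h scale (τ = 5, ≈ 34,500 points)
  in well under a second. The test suite proves exact count equality with a
  naive O(N²) double loop on hundreds of random series, and agreement with
  the analytic i.i.d. Gaussian value `−ln erf(r/2) ≈ 2.47` at N = 100,000.

## 4. Conventional HRV features

* **SDVRI / SDAVRI**: SD of all intervals, and SD of non-overlapping
  5-minute window means (windows with < 30 s of data dropped).
* **Spectral band powers** (ULF < 0.0033 Hz, VLF 0.0033–0.04, LF 0.04–0.15,
  HF 0.15–0.4), reported as ln(ms²). VLF/LF/HF use Welch averaging (1024-s
  Hann segments, 50 % overlap, per-segment mean removal); ULF uses a single
  full-length periodogram with linear detrend, since Welch segments cannot
  resolve it. No estimator was named in the source; these are standard
  choices. A band is undefined when the recording cannot hold two cycles of
  its slowest component or two Fourier bins; the ULF printed bound 0.0033 Hz
  is used as printed even though the source's "(≥ 333 s)" footnote is
  inconsistent with 1/0.0033 ≈ 303 s.
* **Scattering index** (Lorenz / lag-1 return plot): the default definition
  is the root of the mean of the two principal-axis variances of the
  `(VRI_n, VRI_{n+1})` cloud — for an isotropic i.i.d. cloud of SD σ the
  index is ≈ σ. The computation used in the original work is deferred to
  references we deliberately do not guess; the definition is pluggable
  (`statistic =`), and absolute values are therefore calibration-sensitive
  (a synthetic default series gives ≈ 230 ms, published AF values are
  ≈ 380–390 ms).

## 5. Diurnal analysis

`MeanEn_VLF2` is recomputed in 4-hour windows every 2 hours, the window
centre assigned as the time. Windows are defined on the wall clock (centres
at odd hours) and samples are assigned by time of day, so a 24-h recording
contributes a full 4 h to each of 12 windows regardless of start time, and
every sample falls in exactly two windows. A window that wraps across the
recording edge concatenates the two fragments; the single artificial seam
adds at most one spurious template pair per scale. At 300 s a 4-h window has
only 48 coarse-grained points, so the windowed minimum-points threshold is
relaxed to 40 — windowed entropies are accordingly noisier than full-series
values, which is why group testing (ANOVA over window centres, per-window
t-tests with Bonferroni correction) is done across patients.

## 6. The synthetic generator

The generator's defaults *are* the study conditions the package emulates:

| knob | default | basis |
|---|---|---|
| duration | 24 h | Holter recording length |
| interval mean / SD | 811 / 230 ms | published cohort moments |
| spectrum | 1/f below crossover, flat above | published AF VRI spectrum |
| crossover period | 200 s | published AF VRI spectrum |
| clipping | 200–3000 ms | physiological plausibility |
| patient MeanEn_VLF2 | Normal(0.60, 0.14²) | published non-stroke group |
| stroke hazard | 5.8 %/yr · exp(ln(1.80)·z) | published rate and per-1-SD HR |
| censoring | Exp(mean 69 mo) ∧ 96 mo | ≈ 48-month median follow-up |

**Construction.** Randomized-phase spectral synthesis in the interval
domain: amplitude ∝ `f^(−β/2)` below the crossover frequency and constant
above it (continuous at the crossover), inverse FFT, rescale to the target
moments, clip. An `entropy_scale_factor` multiplies the sub-crossover power
only, so per-patient long-scale irregularity varies while short-scale
behaviour stays AF-like and the sub-crossover log–log slope remains exactly
−β. `white_fraction` mixes in extra broadband white variance (1 = i.i.d.
Gaussian, used for closed-form checks). Clipping affects ≈ 0.4 % of beats at
the default moments (a Gaussian marginal with mean 811 and SD 230 ms has
that much mass below 200 ms); the fraction is recorded on the series and a
warning is raised above 0.1 %.

**Calibration.** The map from `entropy_scale_factor` to realised
`MeanEn_VLF2` was measured once (9-point factor grid × 5 seeds of 24-h
series, plus independent bias-check batches at the 0.60 and 0.68 anchors)
and frozen as a quadratic inverse curve (`afmse_calibration`); the default
factor (≈ 0.78) lands a default series at the non-stroke anchor 0.60, and
`generate_cohort()` maps each patient's drawn target through the same curve.
Between-seed SD of `MeanEn_VLF2` at fixed settings is ≈ 0.02–0.03.

**What the generator does *not* reproduce.** A Gaussian linear process
cannot match the published variance partition and entropy level
simultaneously: the published SDAVRI (≈ 115 ms) and ULF power imply ~25 % of
interval variance below 0.0033 Hz, but a β = 1 Gaussian process with that
much slow power has `MeanEn_VLF2 ≈ 1.4`, far above the published 0.60. Real
AF slow fluctuations are evidently more *regular* per unit variance than
phase-randomized noise. The entropy anchors take priority (they drive every
downstream statistic), so synthetic SDAVRI (≈ 37 ms) and ULF power are lower
than the published values, and synthetic short-scale band entropies
(MeanEn_HF ≈ 1.84) are higher than published (≈ 1.52). Passing tests
therefore demonstrate correctness of the *computations* and of the
outcome-coupling, not that the generator is a complete surrogate for
clinical AF recordings. Covariates are drawn independently of entropy, so
the covariate regression of `MeanEn_VLF2` has R² ≈ 0 on synthetic cohorts
(the clinical dataset reports 0.28).

**Survival model.** Event times are exponential given the linear predictor
`ln(1.80) · standardized MeanEn_VLF2` — the simplest model consistent with a
constant annualized rate; censoring is the minimum of an Exp(69 months) time
and a 96-month administrative horizon, giving ≈ 48-month median follow-up.
With these rates a 173-patient cohort accrues more events (~20 %) than the
original 13 %, because the published 5.8 %/year rate and the published mean
follow-up are not mutually consistent; the rate was kept, being the stated
constant. Event-group selection then shifts the stroke group's mean
`MeanEn_VLF2` to ≈ 0.66–0.68 and the non-stroke group to ≈ 0.58 — the
published 0.08 separation emerges from the hazard model rather than being
imposed.

**Determinism.** Every generator function seeds from its config; cohorts
pre-draw per-patient sub-seeds from the master stream, so per-patient series
are reproducible independently of evaluation order.

## 7. Statistics-layer conventions

* Student's t (equal variances) for continuous group comparisons; χ² for
  categoricals, switching to Fisher's exact test when any expected cell
  count is < 5; two-sided throughout, α = 0.05.
* C-statistic: the ROC outcome is event-ever-during-follow-up, ignoring
  censoring time (a fixed-horizon reading); DeLong confidence intervals and
  paired DeLong tests. Time-dependent AUC is out of scope.
* Cox fits standardise the feature *within the analysed subset*, so the
  hazard ratio is per 1-SD; the three reported subsets are all patients
  (adjusted for age, CHA2DS2-VASc score, antithrombotic use) and the
  antithrombotic strata (adjusted for age and score).
* Nelson–Aalen cumulative hazards via `survival::survfit(ctype = 1)`,
  groups dichotomised at the cohort mean of `MeanEn_VLF2`; log-rank
  comparison.
* Cross-validation: outcome-stratified folds with a fixed seed; the
  threshold is chosen on each training set (Youden index, evaluated midway
  between consecutive scores) and applied only to the held-out fold, so no
  threshold is ever evaluated on data that chose it.

### Threshold classification and an irreducible discrepancy

With event scores `N(0.68, 0.15²)` and non-event scores `N(0.60, 0.14²)` —
the published group moments — the sum of sensitivity and specificity is
maximised at the Youden point and equals 121.8 %. The published operating
point (66.7 % + 64.3 % = 131 %) is therefore unreachable from the printed
moments at *any* single threshold: the empirical score distributions must
depart from normality. Additionally the published dichotomisation threshold
("the mean value, 0.67") is inconsistent with the printed group means, whose
prevalence-weighted mean is 0.610. The package's closed form
(`threshold_performance()`) reproduces the published sensitivity (67.9 % vs
66.7 %) at the weighted pooled mean and the published specificity (69.1 % vs
64.3 %) at the stated 0.67 threshold; the acceptance test asserts exactly
these two reproducible facts plus agreement between the closed form and
simulation.

## 8. Problem sizes and numerical tolerances in the test suite

Unit tests use short series (10³–10⁴ samples) chosen so every property is
sharply testable; the deeper checks use 24-h-equivalent series (172,800
samples at 2 Hz), 20-seed sweeps for the MSE shape properties, 50
replicates of n = 2000 cohorts for hazard-ratio recovery (mean within
[1.70, 1.90]) and 200 replicates for null CI coverage (a 50-replicate
binomial estimate of ~95 % coverage is too noisy to verify a ≥ 90 % bound
reliably). Monotonicity of the white-noise profile is asserted strictly on a
5-fold decimated grid and up to 0.01 entropy of Monte-Carlo jitter on the
full grid: adjacent grid scales at the long-scale end differ by less than
the sampling noise of the entropy estimator, so occasional millientropy
inversions are expected even for arbitrarily correct code.

## 9. Known limitations

* The generator is a linear Gaussian surrogate (Section 6): adequate for
  validating the computations and the outcome-coupled statistics, not a
  physiological model of AV-nodal conduction; ectopy is label injection
  only, with no morphology or timing structure.
* The scattering index definition is a documented choice; published absolute
  values are not comparable without the original computation.
* Reproduction of the original cohort's numbers requires the per-patient
  clinical dataset, which is not redistributable; the corresponding test
  fails by design unless `options(afmse.study_cohort=)` points at it.
* WFDB annotation ingestion is limited to the documented CSV dialect;
  convert with standard tools upstream.
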