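# afmse

Time-scale multiscale entropy and stroke-risk statistics for atrial
fibrillation (AF) Holter recordings.

In permanent AF the ventricular response intervals (VRIs) — the AF analogue
of RR intervals — fluctuate irregularly, and conventional heart-rate
variability indices carry little prognostic information. This package
implements an analysis in which the *irregularity* of the VRI series,
quantified by multiscale entropy (MSE) on a time-scale axis, is used as a
risk stratifier for incident ischemic stroke. It is aimed at researchers
working with Holter beat annotations (or simulated interval series) who want
a tested, reproducible implementation of the full chain: beat stream →
cleaned VRI series → 2 Hz resampled signal → entropy/HRV features → cohort
survival statistics.

## The method

**Sample entropy.** For a series with pattern length `m` and absolute
tolerance `t`,

```
SampEn(m, t) = -ln(A / B)
```

where `B` counts pairs of distinct `m`-point templates whose Chebyshev
distance is `< t`, and `A` counts the pairs that still match when both
templates are extended by one point (self-matches excluded). Defaults follow
the clinical convention `m = 2`, `t = r · SD` with `r = 0.15`.

**Time-scale MSE.** The cleaned VRI series is linearly interpolated and
resampled at 2 Hz, then coarse-grained into non-overlapping block means of
`τ` samples; the scale in seconds is `τ / 2`. Sample entropy is computed per
scale with the tolerance fixed at `0.15 · SD` of the scale-1 series. Scale
bands mirror the spectral HRV bands: HF 2.5–6.5 s, LF 6.5–25 s, VLF
25–300 s, and the VLF subranges VLF1 25–90 s and VLF2 90–300 s. Each band is
summarised by the mean entropy (**MeanEn**) and the least-squares slope of
entropy against `log10(scale)` (**SlopeEn**). `MeanEn_VLF2` is the headline
predictor.

**Risk statistics.** Group comparisons (Student's t, χ²/Fisher), Spearman
correlation matrices, multiple regression, C-statistics with DeLong
intervals, Cox proportional-hazards models reporting the hazard ratio per
1-SD increment, Nelson–Aalen cumulative incidence with log-rank tests, and
stratified k-fold cross-validated sensitivity/specificity.

**Synthetic data.** A generator produces AF-like 24-hour VRI series by
randomized-phase spectral synthesis — power ∝ `1/f` below the crossover
frequency (period ≈ 200 s) and flat above it, matching the published AF
spectrum — and outcome-coupled cohorts in which ischemic-stroke times follow
an exponential proportional-hazards model driven by each patient's
`MeanEn_VLF2` (default hazard ratio 1.80 per 1-SD, 5.8 %/year baseline).
Every downstream stage is therefore testable without clinical data.

## Worked example

```r
library(afmse)

## one synthetic 24-hour recording
cfg   <- synth_config(seed = 42)
beats <- generate_vri_series(cfg)            # annotated beat stream
vri   <- build_vri(beats)                    # cleaned intervals
check_eligibility(vri)$eligible              # TRUE (24 h, 0% VE/artifact)

u    <- resample_uniform(vri)                # 2 Hz signal
prof <- mse_profile(u)                       # entropy vs scale (2.5-300 s)
mse_band_summaries(prof)
#>   band mean_en slope_en n_scales
#> 1   HF   1.842   -0.894        8
#> 2   LF   1.377   -0.913       12
#> 3  VLF   0.730   -0.456       22
#> 4 VLF1   0.852   -0.837       11
#> 5 VLF2   0.607   -0.111       11

## an outcome-coupled cohort of 173 patients
cohort <- generate_cohort(synth_config(n_patients = 173, seed = 7))
compare_groups(cohort, "mean_en_vlf2")
#> MeanEn_VLF2: stroke 0.68±0.13 (n=38) vs no stroke 0.60±0.13 (n=135), p = 8e-04
cox_fit(cohort)   # adjusted for age, CHA2DS2-VASc score, antithrombotic use
#> HR per 1-SD: 1.61 (95% CI 1.19-2.18), p = 0.002
c_statistic(cohort, "mean_en_vlf2")
#> AUC 0.66 (0.56-0.75)
```

The VLF2-band mean entropy of the single recording (0.607) sits at the
generator's non-stroke calibration anchor; in the cohort, patients who go on
to have a stroke show higher `MeanEn_VLF2` (0.68 vs 0.60 here), the adjusted
per-1-SD hazard ratio is greater than 1, and discrimination is moderate
(AUC ≈ 0.66) — the qualitative picture the method is designed to expose.

An end-to-end run (simulate → features → cohort statistics, with per-patient
CSV outputs and a JSON report) is one call:

```r
run_pipeline(pipeline_config(), out_dir = "runs/demo")
```

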