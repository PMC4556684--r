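test_that("synth_config validates its invariants", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(duration_h = 0), "duration_h")
  expect_error(synth_config(sd_vri_ms = -1), "sd_vri_ms")
  expect_error(synth_config(white_fraction = 1.2), "white_fraction")
  expect_error(synth_config(crossover_period_s = 0), "crossover")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- synth_config(seed = 7, duration_h = 1)
  b1 <- suppressWarnings(generate_vri_series(cfg))
  b2 <- suppressWarnings(generate_vri_series(cfg))
  expect_identical(b1$onsets_s, b2$onsets_s)
  expect_identical(b1$labels, b2$labels)
})

test_that("generated series hit the target moments and beat count", {
  cfg <- synth_config(seed = 5)
  b <- suppressWarnings(generate_vri_series(cfg))
  iv <- attr(b, "interval_ms")
  n_expected <- 24 * 3600 / 0.811
  expect_equal(length(iv), round(n_expected), tolerance = 0.01)
  expect_equal(mean(iv), 811, tolerance = 0.02)
  expect_equal(sd(iv), 230, tolerance = 0.02)
  expect_true(all(iv >= 200 & iv <= 3000))
  expect_lt(attr(b, "clip_fraction"), 0.01)
})

test_that("pure white configuration is i.i.d.: scale-1 entropy matches the
          analytic value and the naive oracle", {
  cfg <- synth_config(seed = 3, white_fraction = 1, duration_h = 12)
  iv <- attr(suppressWarnings(generate_vri_series(cfg)), "interval_ms")
  # clipping breaks exact normality in the far tails; negligible at r = 0.15
  s <- sample_entropy(iv, m = 2, r = 0.15)
  expect_equal(as.numeric(s), sampen_iid_gaussian(0.15), tolerance = 0.03)
  # exact agreement with the brute-force oracle on a 2000-sample subseries
  sub <- iv[1:2000]
  tol <- 0.15 * sd(iv)
  o <- sampen_oracle(sub, 2, tol)
  s2 <- sample_entropy(sub, m = 2, tolerance_abs = tol)
  expect_identical(attr(s2, "A"), unname(o["A"]))
  expect_identical(attr(s2, "B"), unname(o["B"]))
})

test_that("interval spectrum has the two-regime shape", {
  logbin_slope <- function(freq, psd, sel, nbins = 20) {
    bins <- cut(log10(freq[sel]), nbins)
    lf <- tapply(log10(freq[sel]), bins, mean)
    lp <- tapply(log10(psd[sel]), bins, mean)
    unname(coef(lm(lp ~ lf))[2])
  }
  for (s in 1:2) {
    b <- suppressWarnings(generate_vri_series(synth_config(seed = s)))
    iv <- attr(b, "interval_ms")
    ps <- afmse:::periodogram_psd(iv, 1000 / mean(iv))
    fc <- 1 / 200
    expect_equal(logbin_slope(ps$freq, ps$psd, ps$freq < fc & ps$freq > 2e-5),
                 -1, tolerance = 0.2)
    expect_equal(logbin_slope(ps$freq, ps$psd, ps$freq >= fc),
                 0, tolerance = 0.2)
  }
})

test_that("default MSE profile is steep below the crossover, flat above it", {
  cfg <- synth_config(seed = 2)
  u <- resample_uniform(build_vri(suppressWarnings(generate_vri_series(cfg))))
  p <- mse_profile(u)
  below <- band_summary(p, c(2.5, 25))
  above <- band_summary(p, c(200, 300))
  expect_lt(below$slope_en, -0.5)
  expect_lt(abs(above$slope_en), 0.35)
})

test_that("ectopy injection produces V labels at the requested rate", {
  cfg <- synth_config(seed = 9, duration_h = 2, ve_fraction = 0.06)
  b <- suppressWarnings(generate_vri_series(cfg))
  expect_equal(mean(b$labels == "V"), 0.06, tolerance = 0.01)
  # and the eligibility check flags the recording
  r <- check_eligibility(build_vri(b), min_hours = 1)
  expect_false(r$eligible)
  expect_true("ventricular_ectopy" %in% r$reasons)
})

test_that("cohorts are reproducible and respect the survival bookkeeping", {
  cfg <- synth_config(seed = 21, n_patients = 300)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  expect_true(all(co1$follow_up_months > 0))
  expect_true(all(co1$follow_up_months <= cfg$horizon_months))
  expect_true(all(co1$event %in% 0:1))
  # stored scores match recomputation from components
  expect_identical(co1$cha2ds2_vasc,
                   cha2ds2_vasc(co1$age, co1$female, co1$chf,
                                co1$hypertension, co1$diabetes,
                                co1$stroke_tia, co1$vascular))
  expect_error(generate_cohort(synth_config(n_patients = 1)), "n_patients")
})

test_that("a null-effect cohort shows no association with the outcome", {
  co <- generate_cohort(synth_config(seed = 33, n_patients = 2000,
                                     log_hr_per_sd = 0))
  fit <- cox_fit(co)
  expect_true(fit$ci[1] < 1 && fit$ci[2] > 1)
  expect_equal(fit$hr, 1, tolerance = 0.15)
})

test_that("compute mode measures entropy near the drawn targets", {
  cfg <- synth_config(seed = 4, n_patients = 4, duration_h = 6)
  co <- suppressWarnings(generate_cohort(cfg, features = "compute",
                                         min_points = 60))
  target <- synth_config(seed = 4, n_patients = 4)$mean_en_vlf2_mean +
    0.14 * local({ set.seed(4); rnorm(4) })
  expect_true(all(is.finite(co$mean_en_vlf2)))
  # 6-h windows are noisy; agreement need only be loose per patient
  expect_equal(co$mean_en_vlf2, target, tolerance = 0.25)
  expect_true(all(c("sdvri_ms", "hf_ln", "mean_en_hf") %in% names(co)))
})

test_that("the calibration map is monotone and clamped", {
  men <- seq(0.25, 0.95, by = 0.1)
  esf <- esf_for_mean_en(men)
  expect_true(all(diff(esf) > 0))
  expect_equal(esf_for_mean_en(-5), esf_for_mean_en(0.2))
  expect_equal(esf_for_mean_en(5), esf_for_mean_en(1.0))
})
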