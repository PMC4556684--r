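test_that("CHA2DS2-VASc weights reproduce the published scheme", {
  # 70-year-old male with hypertension only: age 65-74 (1) + hypertension (1)
  expect_equal(cha2ds2_vasc(70, 0, 0, 1, 0, 0, 0), 2L)
  # 30-year-old male, no comorbidity
  expect_equal(cha2ds2_vasc(30, 0, 0, 0, 0, 0, 0), 0L)
  # 80-year-old female with prior stroke, CHF, hypertension, diabetes and
  # vascular disease: 2 + 1 + 1 + 1 + 1 + 1 + 2 = 9 (the maximum)
  expect_equal(cha2ds2_vasc(80, 1, 1, 1, 1, 1, 1), 9L)
  # vectorised, always within 0-9
  set.seed(1)
  n <- 500
  sc <- cha2ds2_vasc(sample(30:95, n, TRUE), rbinom(n, 1, .4),
                     rbinom(n, 1, .4), rbinom(n, 1, .5), rbinom(n, 1, .2),
                     rbinom(n, 1, .3), rbinom(n, 1, .2))
  expect_true(all(sc >= 0 & sc <= 9))
  expect_error(cha2ds2_vasc(NA, 0, 0, 0, 0, 0, 0), "missing component: age")
})

test_that("group comparison uses the right test per variable type", {
  vals <- rnorm(40)
  d <- data.frame(event = rep(c(1, 0), each = 40),
                  x = rep(vals, 2),          # identical group compositions
                  flag = rep(c(1, 0), times = 40))
  # identical continuous groups: p = 1
  r <- compare_groups(d, "x")
  expect_equal(r$p, 1, tolerance = 1e-9)
  expect_equal(r$mean_1, r$mean_0)
  expect_identical(r$test, "student_t")
  # balanced categorical with no association
  r2 <- compare_groups(d, "flag", categorical = TRUE)
  expect_true(r2$test %in% c("chisq", "fisher"))
  expect_gt(r2$p, 0.9)
  # small expected cells switch to Fisher
  d$rare <- c(rep(1, 3), rep(0, 77))
  expect_identical(compare_groups(d, "rare", categorical = TRUE)$test,
                   "fisher")
  expect_error(compare_groups(d[d$event == 1, ], "x"), "non-empty")
})

test_that("a separated synthetic cohort is detected by the t-test", {
  set.seed(42)
  pows <- replicate(50, {
    d <- data.frame(event = rep(c(1, 0), c(22, 151)),
                    men = c(rnorm(22, 0.68, 0.15), rnorm(151, 0.60, 0.14)))
    compare_groups(d, "men")$p
  })
  expect_gt(mean(pows < 0.05), 0.5)   # power at the study's own effect size
})

test_that("Spearman matrix has exact structure for known relations", {
  set.seed(2)
  d <- data.frame(a = rnorm(60))
  d$b <- -d$a
  d$c <- rnorm(60)
  d$k <- 5
  r <- correlation_matrix(d, c("a", "b", "c", "k"))
  expect_equal(r$rho["a", "a"], 1)
  expect_equal(r$rho["a", "b"], -1)
  expect_lt(abs(r$rho["a", "c"]), 0.35)
  expect_identical(r$constant, "k")
  expect_true(is.na(r$rho["a", "k"]))
  expect_identical(r$stars["a", "b"], "***")
  expect_error(correlation_matrix(d[1:2, ], c("a", "b")), "3 records")
})

test_that("covariate regression recovers coefficients and flags collinearity", {
  set.seed(3)
  n <- 1500
  d <- data.frame(age = rnorm(n, 69, 11), female = rbinom(n, 1, 0.3),
                  chf = rbinom(n, 1, 0.4), hypertension = rbinom(n, 1, 0.5),
                  diabetes = rbinom(n, 1, 0.1), stroke_tia = rbinom(n, 1, 0.3),
                  vascular = rbinom(n, 1, 0.1),
                  antithrombotic = rbinom(n, 1, 0.6))
  # null target: R^2 near zero
  d$mean_en_vlf2 <- rnorm(n, 0.6, 0.14)
  r0 <- covariate_regression(d)
  expect_lt(r0$r_squared, 0.02)
  # known sex effect is recovered within its CI
  d$mean_en_vlf2 <- 0.6 + 0.08 * d$female + rnorm(n, 0, 0.1)
  r1 <- covariate_regression(d)
  co <- r1$coefficients["female", ]
  expect_lt(abs(co[["Estimate"]] - 0.08), 2 * co[["Std. Error"]] + 1e-9)
  # a duplicated column is named in the rank-deficiency error
  d$dup <- d$age
  expect_error(covariate_regression(d, covariates = c("age", "dup")), "dup")
})

test_that("C-statistic behaves at the extremes and under negation", {
  set.seed(4)
  d <- data.frame(event = rbinom(200, 1, 0.3), x = rnorm(200))
  d$perfect <- d$event
  expect_equal(suppressWarnings(c_statistic(d, "perfect"))$auc, 1)
  d$neg <- -d$x
  expect_equal(c_statistic(d, "x")$auc, 1 - c_statistic(d, "neg")$auc)
  aucs <- replicate(10, {
    dd <- data.frame(event = rbinom(300, 1, 0.2), x = rnorm(300))
    c_statistic(dd, "x")$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
  expect_error(c_statistic(data.frame(event = rep(1, 5), x = rnorm(5)), "x"),
               "both outcome classes")
  # DeLong comparison of a score against itself: no difference
  expect_equal(compare_c(d, "x", "x")$p, 1, tolerance = 1e-6)
})

test_that("Cox hazard ratios are per-SD and scale-invariant", {
  co <- generate_cohort(synth_config(seed = 17, n_patients = 1500))
  f1 <- cox_fit(co)
  co$scaled <- co$mean_en_vlf2 * 1000
  f2 <- cox_fit(co, "scaled")
  expect_equal(f1$hr, f2$hr, tolerance = 1e-8)
  expect_gt(f1$hr, 1)  # generated with a positive effect
  small <- co[1:5, ]; small$event <- c(1, 0, 0, 0, 0)
  expect_error(cox_fit(small), "2 events")
})

test_that("cox_table reports the three study subsets", {
  co <- generate_cohort(synth_config(seed = 18, n_patients = 1200))
  tab <- cox_table(co)
  expect_equal(tab$subset, c("all", "no_antithrombotic", "antithrombotic"))
  expect_true(all(is.finite(tab$hr)))
  expect_equal(tab$n[1], 1200)
  expect_equal(tab$n[2] + tab$n[3], 1200)
})

test_that("Nelson-Aalen curves match hand enumeration on a toy cohort", {
  # 10 subjects, no censoring, score splits them 5/5 at the mean
  d <- data.frame(
    follow_up_months = c(2, 4, 6, 8, 10, 3, 5, 7, 9, 11),
    event = c(1, 1, 0, 1, 0, 1, 0, 1, 1, 0),
    mean_en_vlf2 = c(rep(1, 5), rep(0, 5)))
  res <- cumulative_incidence(d)
  for (g in c("low", "high")) {
    sel <- if (g == "high") d$mean_en_vlf2 > 0.5 else d$mean_en_vlf2 <= 0.5
    hand <- nelson_aalen_hand(d$follow_up_months[sel], d$event[sel])
    got <- res$curves[res$curves$group == g, ]
    expect_equal(got$cumhaz, hand$cumhaz[match(got$time, hand$time)],
                 tolerance = 1e-12)
  }
  expect_true(res$logrank_p > 0 && res$logrank_p <= 1)

  # no events: curves stay at zero
  d0 <- d; d0$event <- 0
  expect_true(all(cumulative_incidence(d0)$curves$cumhaz == 0))
})

test_that("the high-entropy group's hazard dominates at the true effect", {
  ps <- sapply(1:10, function(s) {
    co <- generate_cohort(synth_config(seed = s, n_patients = 600))
    res <- cumulative_incidence(co)
    hi <- res$curves[res$curves$group == "high", ]
    lo <- res$curves[res$curves$group == "low", ]
    c(p = res$logrank_p, dom = max(hi$cumhaz) > max(lo$cumhaz))
  })
  expect_gt(mean(ps["p", ] < 0.05), 0.5)
  expect_gt(mean(ps["dom", ]), 0.8)
})

test_that("cross-validation separates signal from noise without leakage", {
  set.seed(6)
  n <- 400
  d <- data.frame(event = rbinom(n, 1, 0.25))
  d$score <- d$event * 10 + seq_len(n) / n   # perfectly separating
  cv <- cross_validate(d, "score", k = 4)
  expect_equal(cv$sensitivity, 1)
  expect_equal(cv$specificity, 1)

  # label-independent score: both operating characteristics near chance
  reps <- replicate(10, {
    dd <- data.frame(event = rbinom(n, 1, 0.25), score = rnorm(n))
    cv <- cross_validate(dd, "score", k = 4, seed = 1)
    c(cv$sensitivity, cv$specificity)
  })
  expect_equal(mean(reps), 0.5, tolerance = 0.15)
  # permuting labels of a real cohort destroys performance (no leakage)
  co <- generate_cohort(synth_config(seed = 19, n_patients = 800))
  set.seed(99)
  co$event <- sample(co$event)
  cvp <- cross_validate(co, k = 4)
  expect_lt(cvp$sensitivity + cvp$specificity, 1.25)

  expect_error(cross_validate(d, "score", k = 1), "k must be")
  tiny <- data.frame(event = c(1, rep(0, 20)), score = rnorm(21))
  expect_error(cross_validate(tiny, "score", k = 4), "stratified")
})

test_that("fixed-threshold normal-theory performance matches simulation", {
  perf <- threshold_performance(0.68, 0.15, 0.60, 0.14, n1 = 22, n0 = 151)
  set.seed(10)
  x1 <- rnorm(2e5, 0.68, 0.15)
  x0 <- rnorm(2e5, 0.60, 0.14)
  expect_equal(perf$sensitivity, mean(x1 > perf$threshold), tolerance = 0.01)
  expect_equal(perf$specificity, mean(x0 <= perf$threshold), tolerance = 0.01)
  # explicit threshold override
  p67 <- threshold_performance(0.68, 0.15, 0.60, 0.14, threshold = 0.67)
  expect_equal(p67$threshold, 0.67)
  expect_gt(p67$specificity, p67$sensitivity)
})
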