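#' CHA2DS2-VASc stroke risk score
#'
#' One point each for congestive heart failure, hypertension, diabetes,
#' vascular disease, age 65-74 years and female sex; two points for age >= 75
#' years and for a prior stroke or transient ischemic attack. Range 0-9.
#'
#' @param age Age in years.
#' @param female,chf,hypertension,diabetes,stroke_tia,vascular Logical or
#'   0/1 component flags. All arguments are vectorised and must be free of
#'   missing values.
#' @return Integer score(s) in 0-9.
#' @export
cha2ds2_vasc <- function(age, female, chf, hypertension, diabetes,
                         stroke_tia, vascular) {
  args <- list(age = age, female = female, chf = chf,
               hypertension = hypertension, diabetes = diabetes,
               stroke_tia = stroke_tia, vascular = vascular)
  for (nm in names(args))
    if (anyNA(args[[nm]])) stop_afmse("missing component: ", nm)
  score <- as.integer(chf > 0) + as.integer(hypertension > 0) +
    as.integer(diabetes > 0) + as.integer(vascular > 0) +
    as.integer(female > 0) +
    as.integer(age >= 65 & age < 75) + 2L * as.integer(age >= 75) +
    2L * as.integer(stroke_tia > 0)
  stopifnot(all(score >= 0 & score <= 9))
  score
}

#' Compare a feature between outcome groups
#'
#' Continuous features: per-group mean and SD with a two-sided Student's
#' t-test (equal variances). Categorical features (logical, factor, or 0/1
#' integer flagged via `categorical = TRUE`): chi-squared test, switching to
#' Fisher's exact test when any expected cell count is below 5.
#'
#' @param cohort Data frame with an outcome column.
#' @param feature Feature column name.
#' @param group Outcome column name (default `"event"`).
#' @param categorical Force categorical handling.
#' @return List with per-group summaries, `p`, and the test used.
#' @export
compare_groups <- function(cohort, feature, group = "event",
                           categorical = NULL) {
  g <- as.integer(cohort[[group]] > 0)
  x <- cohort[[feature]]
  keep <- is.finite(g) & !is.na(x)
  g <- g[keep]; x <- x[keep]
  if (length(unique(g)) < 2) stop_afmse("both outcome groups must be non-empty")
  categorical <- categorical %||%
    (is.logical(x) || is.factor(x) || is.character(x))
  if (!categorical) {
    if (sd(x) == 0) {          # degenerate: identical constant groups
      return(list(feature = feature, type = "continuous",
                  mean_1 = mean(x[g == 1]), sd_1 = 0, n_1 = sum(g == 1),
                  mean_0 = mean(x[g == 0]), sd_0 = 0, n_0 = sum(g == 0),
                  p = 1, test = "student_t"))
    }
    tt <- t.test(x[g == 1], x[g == 0], var.equal = TRUE)
    list(feature = feature, type = "continuous",
         mean_1 = mean(x[g == 1]), sd_1 = sd(x[g == 1]), n_1 = sum(g == 1),
         mean_0 = mean(x[g == 0]), sd_0 = sd(x[g == 0]), n_0 = sum(g == 0),
         p = tt$p.value, test = "student_t")
  } else {
    tab <- table(factor(as.character(x)), g)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- chisq.test(tab, correct = FALSE)$p.value
      test <- "chisq"
    }
    list(feature = feature, type = "categorical", table = tab, p = p,
         test = test)
  }
}

#' Spearman rank correlation matrix
#'
#' Pairwise Spearman correlations with p-values and significance stars
#' (* < 0.05, \eqn{\dagger} < 0.01 rendered as **, *** < 0.001). Constant
#' features yield `NA` and are flagged.
#'
#' @param cohort Data frame.
#' @param features Character vector of column names.
#' @return List of matrices `rho`, `p`, `stars`, plus `constant` (names of
#'   degenerate features).
#' @export
correlation_matrix <- function(cohort, features) {
  if (nrow(cohort) < 3) stop_afmse("need at least 3 records")
  k <- length(features)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(features, features))
  constant <- features[vapply(features, function(f)
    sd(cohort[[f]], na.rm = TRUE) == 0, logical(1))]
  for (i in seq_len(k)) {
    rho[i, i] <- if (features[i] %in% constant) NA_real_ else 1
    for (j in seq_len(k)) {
      if (j >= i) next
      if (features[i] %in% constant || features[j] %in% constant) next
      ct <- suppressWarnings(
        cor.test(cohort[[features[i]]], cohort[[features[j]]],
                 method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  list(rho = rho, p = p, stars = stars, constant = constant)
}

#' Multiple regression of an entropy feature on clinical covariates
#'
#' Ordinary least squares with a coefficient table and R-squared. The design
#' matrix is checked for rank deficiency; collinear columns are named in the
#' error.
#'
#' @param cohort Data frame.
#' @param target Response column (default `"mean_en_vlf2"`).
#' @param covariates Covariate column names.
#' @return List with `coefficients` (data frame), `r_squared`, `n`.
#' @export
covariate_regression <- function(cohort, target = "mean_en_vlf2",
                                 covariates = c("age", "female", "chf",
                                                "hypertension", "diabetes",
                                                "stroke_tia", "vascular",
                                                "antithrombotic")) {
  d <- cohort[, c(target, covariates)]
  d <- d[complete.cases(d), ]
  mm <- as.matrix(cbind(`(Intercept)` = 1, d[, covariates, drop = FALSE]))
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop_afmse("rank-deficient design; collinear columns: ",
               paste(bad, collapse = ", "))
  }
  f <- as.formula(paste(target, "~", paste(covariates, collapse = " + ")))
  fit <- lm(f, data = d)
  sm <- summary(fit)
  list(coefficients = as.data.frame(sm$coefficients),
       r_squared = sm$r.squared, n = nrow(d))
}

#' C-statistic (area under the ROC curve) with DeLong confidence interval
#'
#' Discrimination of a score for event-ever-during-follow-up (censoring time
#' is ignored, matching a fixed-horizon reading of the outcome).
#'
#' @param cohort Data frame.
#' @param score Score column name.
#' @param outcome Outcome column name (default `"event"`).
#' @return List with `auc`, `ci` (DeLong 95%), `n_events`.
#' @export
c_statistic <- function(cohort, score, outcome = "event") {
  y <- as.integer(cohort[[outcome]] > 0)
  if (length(unique(y)) < 2) stop_afmse("both outcome classes must be present")
  roc <- pROC::roc(y, cohort[[score]], direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  list(auc = as.numeric(pROC::auc(roc)), ci = ci[c(1, 3)],
       n_events = sum(y))
}

#' Paired DeLong comparison of two scores' C-statistics
#'
#' @param cohort Data frame.
#' @param score1,score2 Score column names.
#' @param outcome Outcome column name.
#' @return List with both AUCs and the DeLong p-value.
#' @export
compare_c <- function(cohort, score1, score2, outcome = "event") {
  y <- as.integer(cohort[[outcome]] > 0)
  r1 <- pROC::roc(y, cohort[[score1]], direction = "<", quiet = TRUE)
  r2 <- pROC::roc(y, cohort[[score2]], direction = "<", quiet = TRUE)
  tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  list(auc1 = as.numeric(pROC::auc(r1)), auc2 = as.numeric(pROC::auc(r2)),
       p = tst$p.value)
}

#' Cox proportional-hazards fit, hazard ratio per 1-SD
#'
#' The feature is standardised to zero mean and unit SD within the analysed
#' subset, so the reported hazard ratio is per 1-SD increment. Adjusters
#' enter untransformed.
#'
#' @param cohort Data frame with `follow_up_months` and `event`.
#' @param feature Feature column name.
#' @param adjusters Adjuster column names (default age, CHA2DS2-VASc score
#'   and antithrombotic use).
#' @param subset Optional logical vector selecting the analysed rows.
#' @return List with `hr`, `ci`, `p`, `log_hr`, `se`, `n`, `n_events`,
#'   `converged`.
#' @export
cox_fit <- function(cohort, feature = "mean_en_vlf2",
                    adjusters = c("age", "cha2ds2_vasc", "antithrombotic"),
                    subset = NULL) {
  d <- if (is.null(subset)) cohort else cohort[subset, , drop = FALSE]
  if (sum(d$event) < 2) stop_afmse("need at least 2 events for a Cox fit")
  d$.z <- as.numeric(scale(d[[feature]]))
  rhs <- paste(c(".z", adjusters), collapse = " + ")
  f <- as.formula(paste("survival::Surv(follow_up_months, event) ~", rhs))
  fit <- survival::coxph(f, data = d)
  sm <- summary(fit)
  co <- sm$coefficients[".z", ]
  list(hr = unname(exp(co["coef"])),
       ci = unname(exp(co["coef"] + c(-1, 1) * 1.96 * co["se(coef)"])),
       p = unname(co["Pr(>|z|)"]),
       log_hr = unname(co["coef"]), se = unname(co["se(coef)"]),
       n = nrow(d), n_events = sum(d$event),
       converged = all(is.finite(co)))
}

#' Adjusted Cox fits in the three study subsets
#'
#' All patients (adjusted for age, CHA2DS2-VASc score and antithrombotic
#' use), patients without antithrombotic treatment (adjusted for age and
#' score) and patients with antithrombotic treatment (full adjustment).
#'
#' @param cohort Data frame.
#' @param feature Feature column name.
#' @return Data frame with one row per subset.
#' @export
cox_table <- function(cohort, feature = "mean_en_vlf2") {
  specs <- list(
    all = list(subset = NULL,
               adj = c("age", "cha2ds2_vasc", "antithrombotic")),
    no_antithrombotic = list(subset = cohort$antithrombotic == 0,
                             adj = c("age", "cha2ds2_vasc")),
    antithrombotic = list(subset = cohort$antithrombotic == 1,
                          adj = c("age", "cha2ds2_vasc"))
  )
  rows <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    res <- tryCatch(cox_fit(cohort, feature, s$adj, s$subset),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(subset = nm, hr = NA, ci_lo = NA, ci_hi = NA,
                        p = NA, n = NA, n_events = NA))
    data.frame(subset = nm, hr = res$hr, ci_lo = res$ci[1],
               ci_hi = res$ci[2], p = res$p, n = res$n,
               n_events = res$n_events)
  })
  do.call(rbind, rows)
}

#' Nelson-Aalen cumulative incidence by dichotomised score
#'
#' Groups the cohort at a threshold of the score (default: the cohort mean of
#' MeanEn_VLF2), estimates the Nelson-Aalen cumulative hazard per group and
#' compares groups with a log-rank test.
#'
#' @param cohort Data frame with `follow_up_months` and `event`.
#' @param score Score column used for dichotomisation.
#' @param threshold Dichotomisation threshold (default: mean of the score).
#' @return List with `curves` (data frame `group`, `time`, `cumhaz`, `n_risk`),
#'   `logrank_p` and `threshold`.
#' @export
cumulative_incidence <- function(cohort, score = "mean_en_vlf2",
                                 threshold = NULL) {
  threshold <- threshold %||% mean(cohort[[score]], na.rm = TRUE)
  grp <- factor(ifelse(cohort[[score]] > threshold, "high", "low"),
                levels = c("low", "high"))
  if (any(table(grp) == 0)) stop_afmse("dichotomisation left an empty group")
  d <- data.frame(time = cohort$follow_up_months, event = cohort$event,
                  grp = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp, data = d,
                          stype = 2, ctype = 1)
  curves <- data.frame(
    group = rep(sub("^grp=", "", names(sf$strata)), sf$strata),
    time = sf$time, cumhaz = sf$cumhaz, n_risk = sf$n.risk)
  lr <- survival::survdiff(survival::Surv(time, event) ~ grp, data = d)
  logrank_p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1,
                             lower.tail = FALSE)
  list(curves = curves, logrank_p = logrank_p, threshold = threshold)
}

#' Stratified k-fold cross-validated sensitivity and specificity
#'
#' Folds are stratified by outcome. On each training set a classification
#' threshold is chosen (Youden index by default, i.e. maximising sensitivity
#' + specificity on the training ROC); held-out subjects are then classified
#' as positive when `score > threshold`, and sensitivity/specificity are
#' pooled over all held-out folds. Thresholds are never evaluated on the fold
#' that chose them.
#'
#' @param cohort Data frame.
#' @param score Score column name (higher = riskier).
#' @param outcome Outcome column name.
#' @param k Number of folds (default 4).
#' @param threshold_rule `"youden"` or a fixed numeric threshold.
#' @param seed Seed for the fold assignment.
#' @return List with pooled `sensitivity`, `specificity`, counts, and the
#'   per-fold thresholds.
#' @export
cross_validate <- function(cohort, score = "mean_en_vlf2", outcome = "event",
                           k = 4, threshold_rule = "youden", seed = 1) {
  y <- as.integer(cohort[[outcome]] > 0)
  x <- cohort[[score]]
  if (k < 2) stop_afmse("k must be >= 2")
  if (sum(y == 1) < k || sum(y == 0) < k)
    stop_afmse("each class needs at least k members for stratified folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  tp <- fp <- tn <- fn <- 0
  thresholds <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    thr <- if (is.numeric(threshold_rule)) threshold_rule
           else youden_threshold(x[tr], y[tr])
    thresholds[f] <- thr
    pred <- x[!tr] > thr
    truth <- y[!tr] == 1
    tp <- tp + sum(pred & truth);  fn <- fn + sum(!pred & truth)
    fp <- fp + sum(pred & !truth); tn <- tn + sum(!pred & !truth)
  }
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn, thresholds = thresholds)
}

# Threshold maximising sensitivity + specificity, evaluated midway between
# consecutive distinct score values.
youden_threshold <- function(x, y) {
  xs <- sort(unique(x))
  cand <- (head(xs, -1) + xs[-1]) / 2
  if (length(cand) == 0) return(xs[1])
  j <- vapply(cand, function(t) {
    sens <- mean(x[y == 1] > t)
    spec <- mean(x[y == 0] <= t)
    sens + spec
  }, numeric(1))
  cand[which.max(j)]
}

#' Sensitivity and specificity of a fixed threshold on two normal score
#' distributions
#'
#' Closed-form performance when event scores are N(mu1, sd1^2) and non-event
#' scores N(mu0, sd0^2), classifying positive above the threshold. With
#' `threshold = NULL` the prevalence-weighted pooled mean
#' `(n1 mu1 + n0 mu0) / (n1 + n0)` is used.
#'
#' @param mu1,sd1 Event-group score distribution.
#' @param mu0,sd0 Non-event-group score distribution.
#' @param n1,n0 Group sizes (used only to pool the default threshold).
#' @param threshold Classification threshold.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_performance <- function(mu1, sd1, mu0, sd0, n1 = 1, n0 = 1,
                                  threshold = NULL) {
  threshold <- threshold %||% ((n1 * mu1 + n0 * mu0) / (n1 + n0))
  list(threshold = threshold,
       sensitivity = 1 - pnorm((threshold - mu1) / sd1),
       specificity = pnorm((threshold - mu0) / sd0))
}
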