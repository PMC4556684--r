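#' Time-domain VRI variability measures
#'
#' Mean interval, SD of all intervals (SDVRI) and SD of the 5-minute window
#' means (SDAVRI). Windows are non-overlapping, anchored at the first interval
#' onset; windows containing less than `min_window_s` seconds of interval time
#' are dropped from the SDAVRI average.
#'
#' @param vri A `vri_series`.
#' @param window_s SDAVRI window length in seconds (default 300).
#' @param min_window_s Minimum covered time for a window to count (default 30).
#' @return List with `mean_vri_ms`, `sdvri_ms`, `sdavri_ms`, `n_windows`.
#' @export
time_domain <- function(vri, window_s = 300, min_window_s = 30) {
  stopifnot(inherits(vri, "vri_series"))
  iv <- vri$interval_ms
  if (length(iv) < 2) stop_afmse("too few intervals for time-domain measures")
  w <- floor((vri$onset_s - vri$onset_s[1]) / window_s)
  cover_s <- tapply(iv / 1000, w, sum)
  means <- tapply(iv, w, mean)
  keep <- cover_s >= min_window_s
  list(mean_vri_ms = mean(iv),
       sdvri_ms = sd(iv),
       sdavri_ms = if (sum(keep) >= 2) sd(means[keep]) else NA_real_,
       n_windows = sum(keep))
}

# Welch power spectral density: Hann-windowed overlapping segments,
# per-segment mean removal, one-sided density in input_units^2 / Hz.
welch_psd <- function(x, fs, nperseg = 2048, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))
  u <- sum(w^2)
  nf <- nperseg %/% 2
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (fs * u)
    acc <- acc + p[2:(nf + 1)]
  }
  psd <- acc / length(starts) * 2          # one-sided
  if (nperseg %% 2 == 0) psd[nf] <- psd[nf] / 2  # Nyquist bin is not doubled
  list(freq = seq_len(nf) * fs / nperseg, psd = psd, df = fs / nperseg)
}

# Full-length periodogram with linear detrend (for the ULF band, which needs
# the finest possible frequency resolution).
periodogram_psd <- function(x, fs) {
  n <- length(x)
  tt <- seq_len(n)
  fit <- lm.fit(cbind(1, tt), x)
  xd <- fit$residuals
  nf <- n %/% 2
  p <- Mod(fft(xd))^2 / (fs * n)
  psd <- 2 * p[2:(nf + 1)]
  if (n %% 2 == 0) psd[nf] <- psd[nf] / 2
  list(freq = seq_len(nf) * fs / n, psd = psd, df = fs / n)
}

#' HRV spectral band definitions (Hz)
#' @export
hrv_bands <- list(
  ulf = c(0, 0.0033),
  vlf = c(0.0033, 0.04),
  lf  = c(0.04, 0.15),
  hf  = c(0.15, 0.40)
)

#' Frequency-domain band powers of the resampled VRI signal
#'
#' Integrates a power spectral density of the 2 Hz series over the
#' conventional HRV bands (ULF < 0.0033 Hz, VLF 0.0033-0.04 Hz, LF
#' 0.04-0.15 Hz, HF 0.15-0.4 Hz) and reports natural logs of the band powers
#' in ms^2. VLF/LF/HF use Welch averaging (1024-s Hann segments, 50%
#' overlap); ULF uses a single full-length periodogram with linear detrend,
#' since Welch segments cannot resolve it. A band is `NA` when the recording
#' cannot hold two Fourier bins inside it; the ULF estimate is additionally
#' flagged unreliable below 22 h.
#'
#' @param u A `uniform_series`.
#' @param method `"welch"` (default, mixed estimator as above) or
#'   `"periodogram"` (single full-length periodogram for all bands; exactly
#'   Parseval-consistent).
#' @return List with `ulf_ln`, `vlf_ln`, `lf_ln`, `hf_ln`, the linear-scale
#'   `powers_ms2` (including `total` and `residual`), and `ulf_reliable`.
#' @export
spectral_powers <- function(u, method = c("welch", "periodogram")) {
  stopifnot(inherits(u, "uniform_series"))
  method <- match.arg(method)
  x <- u$values_ms
  fs <- u$rate_hz
  dur_s <- (length(x) - 1) / fs

  per <- periodogram_psd(x, fs)
  est <- if (method == "welch") welch_psd(x, fs, nperseg = round(1024 * fs)) else per

  # a band is estimable only when the recording holds at least two cycles of
  # its slowest resolvable component and two Fourier bins
  band_power <- function(spec, lo, hi) {
    if (dur_s < 2 / (if (lo > 0) lo else hi)) return(NA_real_)
    sel <- spec$freq > lo & spec$freq <= hi
    if (sum(sel) < 2) return(NA_real_)
    sum(spec$psd[sel]) * spec$df
  }
  # ULF always from the full-length periodogram; other bands from `est`.
  p <- c(
    ulf = band_power(per, hrv_bands$ulf[1], hrv_bands$ulf[2]),
    vlf = band_power(est, hrv_bands$vlf[1], hrv_bands$vlf[2]),
    lf  = band_power(est, hrv_bands$lf[1], hrv_bands$lf[2]),
    hf  = band_power(est, hrv_bands$hf[1], hrv_bands$hf[2])
  )
  total <- sum(est$psd) * est$df
  powers <- c(p, total = total,
              residual = total - sum(p[c("vlf", "lf", "hf")], na.rm = TRUE))
  list(ulf_ln = log(p[["ulf"]]), vlf_ln = log(p[["vlf"]]),
       lf_ln = log(p[["lf"]]), hf_ln = log(p[["hf"]]),
       powers_ms2 = powers,
       ulf_reliable = dur_s >= 22 * 3600)
}

#' Lorenz-plot scattering index
#'
#' Dispersion of the lag-1 return map (interval_n vs interval_(n+1)): the
#' square root of the mean of the two principal-axis variances of the point
#' cloud, i.e. `sqrt(mean(eigenvalues(cov)))`, in ms. For an isotropic cloud
#' of i.i.d. intervals with SD sigma the index is ~ sigma. The exact
#' published computations of this index vary; an alternative definition can
#' be plugged in via `statistic`.
#'
#' @param vri A `vri_series`.
#' @param statistic Optional function `function(x1, x2) -> numeric` replacing
#'   the default principal-axis dispersion, where `x1`, `x2` are the lagged
#'   interval pairs in ms.
#' @param min_intervals Minimum number of intervals required (default 100).
#' @return Scattering index in ms.
#' @export
scattering_index <- function(vri, statistic = NULL, min_intervals = 100) {
  stopifnot(inherits(vri, "vri_series"))
  iv <- vri$interval_ms
  if (length(iv) < min_intervals)
    stop_afmse("at least ", min_intervals, " intervals are required")
  x1 <- iv[-length(iv)]
  x2 <- iv[-1]
  if (!is.null(statistic)) return(statistic(x1, x2))
  cv <- stats::cov(cbind(x1, x2))
  sqrt(mean(eigen(cv, symmetric = TRUE, only.values = TRUE)$values))
}

#' Extract the full per-recording feature set
#'
#' Runs the preprocessing, MSE and HRV stages on one annotated beat series
#' and returns a single feature row: time-domain measures, spectral band
#' powers, Lorenz scattering index, MeanEn and SlopeEn for all five scale
#' bands, plus eligibility bookkeeping.
#'
#' @param beats A `beat_series`.
#' @param m,r Sample entropy parameters.
#' @param min_points Minimum coarse-grained length for a defined scale
#'   (default 200; lower it for recordings much shorter than 24 h).
#' @param ve_policy Passed to [build_vri()].
#' @return One-row data frame.
#' @export
extract_features <- function(beats, m = 2, r = 0.15, min_points = 200,
                             ve_policy = "drop_both") {
  vri <- build_vri(beats, ve_policy = ve_policy)
  elig <- check_eligibility(vri)
  u <- resample_uniform(vri)
  td <- time_domain(vri)
  sp <- spectral_powers(u)
  prof <- mse_profile(u, m = m, r = r, min_points = min_points)
  bs <- mse_band_summaries(prof)

  row <- data.frame(
    mean_vri_ms = td$mean_vri_ms, sdvri_ms = td$sdvri_ms,
    sdavri_ms = td$sdavri_ms,
    n_ve = vri$n_ve,
    ulf_ln = sp$ulf_ln, vlf_ln = sp$vlf_ln, lf_ln = sp$lf_ln,
    hf_ln = sp$hf_ln,
    scattering_index = tryCatch(scattering_index(vri), error = function(e) NA_real_),
    eligible = elig$eligible,
    duration_h = vri$duration_h
  )
  for (i in seq_len(nrow(bs))) {
    b <- tolower(bs$band[i])
    row[[paste0("mean_en_", b)]] <- bs$mean_en[i]
    row[[paste0("slope_en_", b)]] <- bs$slope_en[i]
  }
  row
}
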