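#' Scale bands of the MSE profile (seconds)
#'
#' Band bounds correspond to the conventional HRV spectral bands translated to
#' time scales: HF 2.5-6.5 s, LF 6.5-25 s, VLF 25-300 s, with the VLF range
#' split into VLF1 25-90 s and VLF2 90-300 s. Bands are closed on both ends.
#'
#' @export
mse_bands <- list(
  HF   = c(2.5, 6.5),
  LF   = c(6.5, 25),
  VLF  = c(25, 300),
  VLF1 = c(25, 90),
  VLF2 = c(90, 300)
)

#' Coarse-grain a series by non-overlapping block averaging
#'
#' Replaces the series by the means of consecutive, non-overlapping blocks of
#' `tau` samples; a trailing partial block is discarded, so the output length
#' is `floor(length(x) / tau)`.
#'
#' @param x Numeric vector.
#' @param tau Integer block length (scale factor), `>= 1`.
#' @return Numeric vector of block means.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1) stop_afmse("tau must be a positive integer")
  n <- length(x)
  if (tau > n) stop_afmse("tau exceeds the series length")
  if (tau == 1L) return(as.numeric(x))
  nb <- n %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy of a series
#'
#' SampEn(m, r) = -ln(A/B), where B is the number of pairs of distinct
#' m-length templates within Chebyshev distance `< tol` of each other and A
#' the number of those pairs still matching when both templates are extended
#' by one sample. Self-matches are excluded; the inequality is strict. When
#' no template pair matches (B = 0) or no extended pair matches (A = 0) the
#' entropy is undefined and `NA` is returned with `defined = FALSE`.
#'
#' @param x Numeric vector, length `>= m + 2`.
#' @param m Pattern length (default 2).
#' @param r Similarity factor as a fraction of a reference SD (default 0.15).
#' @param tolerance_abs Absolute tolerance. When supplied it overrides `r`;
#'   otherwise `tol = r * sd_reference`.
#' @param sd_reference Reference SD used to convert `r` into an absolute
#'   tolerance; defaults to `sd(x)`. In a multiscale profile this is held at
#'   the scale-1 SD so the tolerance is fixed across scales.
#' @return Numeric scalar (NA when undefined), with attributes `A`, `B`
#'   (match counts) and `defined`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.15,
                           tolerance_abs = NULL, sd_reference = NULL) {
  x <- as.numeric(x)
  if (length(x) < m + 2) stop_afmse("series too short for pattern length m")
  tol <- tolerance_abs %||% (r * (sd_reference %||% sd(x)))
  if (!is.finite(tol) || tol <= 0)
    stop_afmse("tolerance must be positive (constant series have zero SD)")
  cnt <- sampen_counts(x, as.integer(m), tol)
  a <- cnt[["A"]]; b <- cnt[["B"]]
  defined <- a > 0 && b > 0
  out <- if (defined) -log(a / b) else NA_real_
  structure(out, A = a, B = b, defined = defined)
}

#' Default scale grid for the MSE profile
#'
#' Log-spaced scales (default 20 per decade) over `scale_range` seconds,
#' snapped to an integer number of samples at `rate_hz` and de-duplicated.
#'
#' @param scale_range Numeric length-2, in seconds. Default `c(2.5, 300)`.
#' @param per_decade Grid density. Default 20.
#' @param rate_hz Sampling rate of the uniform series. Default 2 Hz.
#' @return Data frame with columns `tau` (samples) and `scale_s` (seconds).
#' @export
mse_scale_grid <- function(scale_range = c(2.5, 300), per_decade = 20,
                           rate_hz = 2) {
  if (length(scale_range) != 2 || scale_range[1] <= 0 ||
      scale_range[2] <= scale_range[1])
    stop_afmse("scale_range must be increasing and positive")
  lo <- log10(scale_range[1]); hi <- log10(scale_range[2])
  n <- max(2, ceiling((hi - lo) * per_decade) + 1)
  scales <- 10^seq(lo, hi, length.out = n)
  tau <- unique(pmax(1L, as.integer(round(scales * rate_hz))))
  data.frame(tau = tau, scale_s = tau / rate_hz)
}

#' Multiscale entropy profile on the time-scale axis
#'
#' Computes sample entropy of block-averaged (coarse-grained) versions of a
#' uniformly resampled interval series, with the scale axis in seconds
#' (`scale_s = tau / rate_hz`). The similarity tolerance defaults to
#' `r * SD(scale-1 series)` held fixed across scales; `r_reference =
#' "per_scale"` instead re-normalises at every scale.
#'
#' @param u A `uniform_series` (or plain numeric vector, assumed sampled at
#'   `rate_hz`).
#' @param m,r Sample entropy parameters (defaults 2 and 0.15).
#' @param scales Data frame from [mse_scale_grid()], or `NULL` for the default
#'   grid over 2.5-300 s.
#' @param min_points Scales whose coarse-grained series has fewer points are
#'   flagged undefined (default 200).
#' @param r_reference `"scale1"` (default) or `"per_scale"`.
#' @param rate_hz Sampling rate when `u` is a bare vector.
#' @return An `mse_profile` data frame with columns `scale_s`, `tau`,
#'   `sampen`, `n_points`, `defined`.
#' @export
mse_profile <- function(u, m = 2, r = 0.15, scales = NULL, min_points = 200,
                        r_reference = c("scale1", "per_scale"), rate_hz = 2) {
  if (inherits(u, "uniform_series")) {
    x <- u$values_ms
    rate_hz <- u$rate_hz
  } else x <- as.numeric(u)
  r_reference <- match.arg(r_reference)
  scales <- scales %||% mse_scale_grid(rate_hz = rate_hz)
  if (nrow(scales) == 0) stop_afmse("empty scale grid")

  sd1 <- sd(x)
  out <- data.frame(scale_s = scales$scale_s, tau = scales$tau,
                    sampen = NA_real_, n_points = NA_integer_,
                    defined = FALSE)
  for (i in seq_len(nrow(scales))) {
    tau <- scales$tau[i]
    if (tau > length(x)) next
    cg <- coarse_grain(x, tau)
    out$n_points[i] <- length(cg)
    if (length(cg) < max(min_points, m + 2)) next
    tol <- if (r_reference == "scale1") r * sd1 else r * sd(cg)
    if (!is.finite(tol) || tol <= 0) next
    se <- sample_entropy(cg, m = m, tolerance_abs = tol)
    out$sampen[i] <- as.numeric(se)
    out$defined[i] <- attr(se, "defined")
  }
  class(out) <- c("mse_profile", "data.frame")
  out
}

#' Band summary of an MSE profile: MeanEn and SlopeEn
#'
#' MeanEn is the unweighted mean of the sample entropy over the grid scales
#' falling inside the (closed) band; SlopeEn is the ordinary least-squares
#' slope of sample entropy against log10(scale in seconds) over the same
#' points. Note the sign convention: slopes against log10(frequency) would be
#' the negation.
#'
#' @param profile An `mse_profile`.
#' @param band Band name (see [mse_bands]) or a numeric length-2 range in
#'   seconds.
#' @return List with `band`, `mean_en`, `slope_en`, `n_scales`. Summaries are
#'   `NA` when fewer than 2 defined scales fall inside the band.
#' @export
band_summary <- function(profile, band = "VLF2") {
  if (is.character(band)) {
    if (!band %in% names(mse_bands)) stop_afmse("unknown band: ", band)
    rng <- mse_bands[[band]]
    nm <- band
  } else {
    rng <- as.numeric(band)
    nm <- sprintf("%g-%g s", rng[1], rng[2])
  }
  sel <- profile$defined & profile$scale_s >= rng[1] & profile$scale_s <= rng[2]
  if (sum(sel) < 2)
    return(list(band = nm, mean_en = NA_real_, slope_en = NA_real_,
                n_scales = sum(sel)))
  y <- profile$sampen[sel]
  lx <- log10(profile$scale_s[sel])
  list(band = nm,
       mean_en = mean(y),
       slope_en = sum((lx - mean(lx)) * (y - mean(y))) / sum((lx - mean(lx))^2),
       n_scales = sum(sel))
}

#' All five band summaries of a profile
#'
#' @param profile An `mse_profile`.
#' @return Data frame with one row per band (HF, LF, VLF, VLF1, VLF2).
#' @export
mse_band_summaries <- function(profile) {
  rows <- lapply(names(mse_bands), function(b) {
    s <- band_summary(profile, b)
    data.frame(band = b, mean_en = s$mean_en, slope_en = s$slope_en,
               n_scales = s$n_scales)
  })
  do.call(rbind, rows)
}
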