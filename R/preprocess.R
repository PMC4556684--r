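#' Construct an annotated beat series
#'
#' A beat series is the raw input of the pipeline: QRS onset times in seconds
#' from the start of the recording, a beat label per onset, and a wall-clock
#' anchor for the recording start (needed by the diurnal analysis).
#'
#' @param onsets_s Numeric vector of beat onset times in seconds, strictly
#'   increasing.
#' @param labels Character vector, one of `"N"` (normally conducted), `"V"`
#'   (ventricular ectopic) or `"A"` (artifact/noise). Defaults to all `"N"`.
#' @param start_clock Wall-clock time of day of the first sample,
#'   `"HH:MM:SS"`.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(onsets_s, labels = NULL, start_clock = "00:00:00") {
  onsets_s <- as.numeric(onsets_s)
  if (length(onsets_s) < 1) stop_afmse("beat series is empty")
  if (is.unsorted(onsets_s, strictly = TRUE))
    stop_afmse("beat onsets must be strictly increasing")
  if (is.null(labels)) labels <- rep("N", length(onsets_s))
  labels <- as.character(labels)
  if (length(labels) != length(onsets_s))
    stop_afmse("labels must have one entry per beat onset")
  if (!all(labels %in% c("N", "V", "A")))
    stop_afmse("beat labels must be one of 'N', 'V', 'A'")
  structure(
    list(onsets_s = onsets_s, labels = labels,
         start_clock = clock_to_seconds(start_clock)),
    class = "beat_series"
  )
}

clock_to_seconds <- function(x) {
  if (is.numeric(x)) {
    if (x < 0 || x >= 86400) stop_afmse("clock anchor must be within one day")
    return(x)
  }
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) != 3 || anyNA(p)) stop_afmse("clock anchor must be 'HH:MM:SS'")
  p[1] * 3600 + p[2] * 60 + p[3]
}

seconds_to_clock <- function(s) {
  s <- round(s %% 86400)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Read / write beat annotation CSV files
#'
#' The on-disk dialect is a plain CSV with header `onset_s,label` and an
#' optional leading comment line `# start=HH:MM:SS` carrying the wall-clock
#' anchor of the recording start.
#'
#' @param path File path.
#' @param beats A `beat_series` object (for writing).
#' @return `read_beats_csv()` returns a `beat_series`.
#' @export
read_beats_csv <- function(path) {
  first <- readLines(path, n = 1L)
  start <- "00:00:00"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("start=([0-9]{2}:[0-9]{2}:[0-9]{2})", first))[[1]]
    if (length(m) == 2) start <- m[2]
  }
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(d)))
    stop_afmse("beat CSV must have columns 'onset_s' and 'label': ", path)
  beat_series(d$onset_s, d$label, start_clock = start)
}

#' @rdname read_beats_csv
#' @export
write_beats_csv <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# start=%s", seconds_to_clock(beats$start_clock)), con)
  writeLines("onset_s,label", con)
  writeLines(sprintf("%.6f,%s", beats$onsets_s, beats$labels), con)
  invisible(path)
}

#' Build a ventricular response interval (VRI) series from beat annotations
#'
#' Intervals between successive beats, with intervals adjacent to ectopic
#' (`V`) or artifact (`A`) beats removed. Each interval is anchored at the
#' onset of its terminating beat (the usual HRV tachogram convention).
#'
#' @param beats A `beat_series`.
#' @param ve_policy How intervals touching a non-`N` beat are handled:
#'   `"drop_both"` (default) removes both the interval ending at and the one
#'   starting at the beat; `"drop_ending"` removes only the interval ending
#'   there; `"keep"` retains all intervals.
#' @param gap_flag_s Runs of consecutively dropped time longer than this many
#'   seconds are reported in the `gaps` element (they are bridged, not
#'   imputed). Default 10 s.
#' @return An object of class `vri_series` with elements `onset_s` (terminating
#'   beat onset), `interval_ms`, `n_total_beats`, `n_ve`, `ve_fraction`,
#'   `artifact_fraction` (by time), `duration_h`, `start_clock` and `gaps`.
#' @export
build_vri <- function(beats,
                      ve_policy = c("drop_both", "drop_ending", "keep"),
                      gap_flag_s = 10) {
  stopifnot(inherits(beats, "beat_series"))
  ve_policy <- match.arg(ve_policy)
  n <- length(beats$onsets_s)
  if (n < 2) stop_afmse("at least 2 beats are needed to form intervals")

  on <- beats$onsets_s
  lab <- beats$labels
  dt_s <- diff(on)                      # interval i ends at beat i+1
  end_lab <- lab[-1]                    # label of terminating beat
  start_lab <- lab[-n]                  # label of starting beat

  bad <- switch(ve_policy,
    drop_both   = end_lab != "N" | start_lab != "N",
    drop_ending = end_lab != "N",
    keep        = rep(FALSE, n - 1)
  )
  # Artifact fraction is counted by time (intervals touching an 'A' beat),
  # matching an exclusion rule expressed as a fraction of monitoring time.
  art <- end_lab == "A" | start_lab == "A"
  total_s <- on[n] - on[1]
  artifact_fraction <- sum(dt_s[art]) / total_s

  gaps <- data.frame(start_s = numeric(0), length_s = numeric(0))
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (g in which(r$values)) {
      glen <- on[ends[g] + 1] - on[starts[g]]
      if (glen > gap_flag_s)
        gaps <- rbind(gaps, data.frame(start_s = on[starts[g]], length_s = glen))
    }
  }

  structure(
    list(onset_s = on[-1][!bad],
         interval_ms = dt_s[!bad] * 1000,
         n_total_beats = n,
         n_ve = sum(lab == "V"),
         ve_fraction = sum(lab == "V") / n,
         artifact_fraction = artifact_fraction,
         duration_h = total_s / 3600,
         start_clock = beats$start_clock,
         gaps = gaps),
    class = "vri_series"
  )
}

#' Check a VRI series against the study eligibility rules
#'
#' A recording is eligible when it has at least 22 hours of data, ventricular
#' ectopy is not more than 5% of total beats, and artifact/noise is not more
#' than 5% of the monitoring time. The report never throws: ineligible series
#' can still be analysed (e.g. short synthetic fixtures).
#'
#' @param vri A `vri_series`.
#' @param min_hours,max_ve_fraction,max_artifact_fraction Rule thresholds.
#' @return A list with `eligible` (logical) and `reasons` (character vector,
#'   subset of `"duration"`, `"ventricular_ectopy"`, `"artifact"`).
#' @export
check_eligibility <- function(vri, min_hours = 22,
                              max_ve_fraction = 0.05,
                              max_artifact_fraction = 0.05) {
  stopifnot(inherits(vri, "vri_series"))
  reasons <- character(0)
  if (vri$duration_h < min_hours) reasons <- c(reasons, "duration")
  if (vri$ve_fraction > max_ve_fraction) reasons <- c(reasons, "ventricular_ectopy")
  if (vri$artifact_fraction > max_artifact_fraction) reasons <- c(reasons, "artifact")
  list(eligible = length(reasons) == 0, reasons = reasons,
       duration_h = vri$duration_h, ve_fraction = vri$ve_fraction,
       artifact_fraction = vri$artifact_fraction)
}

#' Resample a VRI series to a uniform 2 Hz signal
#'
#' Piecewise-linear interpolation of interval length (ms) against the onset of
#' the terminating beat, evaluated on a regular grid from the first to the
#' last onset. The grid has `floor(span * rate_hz) + 1` samples, i.e. both
#' endpoints are included and a partial final step is discarded.
#'
#' @param vri A `vri_series`.
#' @param rate_hz Resampling rate; the analysis convention is 2 Hz.
#' @return An object of class `uniform_series` with `values_ms`, `rate_hz`,
#'   `start_s` and `start_clock`.
#' @export
resample_uniform <- function(vri, rate_hz = 2) {
  stopifnot(inherits(vri, "vri_series"))
  if (length(vri$interval_ms) < 2)
    stop_afmse("at least 2 intervals are needed for interpolation")
  t0 <- vri$onset_s[1]
  t1 <- vri$onset_s[length(vri$onset_s)]
  grid <- t0 + seq(0, floor((t1 - t0) * rate_hz)) / rate_hz
  vals <- approx(vri$onset_s, vri$interval_ms, xout = grid)$y
  structure(
    list(values_ms = vals, rate_hz = rate_hz, start_s = t0,
         start_clock = vri$start_clock),
    class = "uniform_series"
  )
}
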