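# Independent oracles used across the test files. These deliberately avoid
# the package's own counting code paths.

# Naive sample entropy template-match counts: full pairwise comparison via
# outer products. O(N^2) memory/time; only for short series.
sampen_oracle <- function(x, m, tol) {
  nt <- length(x) - m
  idx <- seq_len(nt)
  match_at <- function(k) abs(outer(x[idx + k - 1], x[idx + k - 1], "-")) < tol
  Bm <- Reduce(`&`, lapply(seq_len(m), match_at))
  Am <- Bm & match_at(m + 1)
  # subtract the diagonal (self matches), halve to count unordered pairs
  c(A = (sum(Am) - nt) / 2, B = (sum(Bm) - nt) / 2)
}

sampen_oracle_value <- function(x, m, tol) {
  cnt <- sampen_oracle(x, m, tol)
  if (cnt["A"] == 0 || cnt["B"] == 0) return(NA_real_)
  unname(-log(cnt["A"] / cnt["B"]))
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Analytic scale-1 sample entropy of i.i.d. Gaussian noise at similarity
# factor r (fraction of the SD): -ln P(|X - Y| < r sd) = -ln erf(r / 2).
sampen_iid_gaussian <- function(r) -log(erf(r / 2))

# Hand-enumerated Nelson-Aalen cumulative hazard: sum of d_i / n_i over
# distinct event times.
nelson_aalen_hand <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time))
  data.frame(
    time = ut,
    cumhaz = cumsum(vapply(ut, function(t)
      sum(event[time == t]) / sum(time >= t), numeric(1)))
  )
}

# Beat series with constant interval spacing (seconds), all N labels.
constant_beats <- function(interval_s, n, start_clock = "00:00:00") {
  beat_series(seq(0, by = interval_s, length.out = n),
              start_clock = start_clock)
}

# Uniform series wrapper for raw vectors.
as_uniform <- function(x, rate_hz = 2, start_clock = "00:00:00") {
  structure(list(values_ms = x, rate_hz = rate_hz, start_s = 0,
                 start_clock = afmse:::clock_to_seconds(start_clock)),
            class = "uniform_series")
}
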