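# Independent brute-force oracle for the yin estimator: the squared
# difference function is evaluated directly at every integer lag (no FFT,
# no cumulative-energy shortcuts), normalized to the CMND, and the lag is
# selected and refined by a self-contained reimplementation of the
# selection rule. Shares no code with yin_f0().
yin_oracle_lag <- function(x, window, ap_threshold = 0.1) {
  tau_max <- window %/% 2L
  nint <- window - tau_max
  d <- numeric(tau_max)
  for (tau in seq_len(tau_max)) {
    d[tau] <- sum((x[seq_len(nint)] - x[seq_len(nint) + tau])^2)
  }
  dp <- d * seq_len(tau_max) / pmax(cumsum(d), 1e-300)
  vertex <- function(v, i) {
    if (i <= 1L || i >= length(v)) return(c(0, v[i]))
    den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
    if (abs(den) < 1e-12) return(c(0, v[i]))
    off <- 0.5 * (v[i - 1L] - v[i + 1L]) / den
    off <- max(-0.5, min(0.5, off))
    c(off, v[i] - 0.25 * (v[i - 1L] - v[i + 1L]) * off)
  }
  tau <- NA_integer_
  for (i in 2:(tau_max - 1L)) {
    if (dp[i] <= dp[i - 1L] && dp[i] <= dp[i + 1L] &&
        vertex(dp, i)[2] < ap_threshold) { tau <- i; break }
  }
  if (is.na(tau)) tau <- which.min(dp)
  tau + vertex(d, tau)[1]
}

# closed-form squared magnitude response of an analog Butterworth low-pass
butterworth_gain <- function(f, cutoff, order) {
  sqrt(1 / (1 + (f / cutoff)^(2 * order)))
}
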