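#' Fundamental frequency by the yin algorithm
#'
#' Classic autocorrelation-family pitch estimation: per analysis frame, the
#' squared difference function
#' `d(tau) = sum_j (x_j - x_{j+tau})^2` is normalized to the cumulative
#' mean normalized difference (CMND)
#' `d'(tau) = d(tau) * tau / sum_{u<=tau} d(u)`, the first dip of the CMND
#' below `ap_threshold` is located (extended to its local minimum), and
#' the lag is refined by parabolic interpolation of the raw difference
#' function around that minimum (the CMND itself is asymmetric around its
#' minima and would bias the refinement). The
#' aperiodicity of a frame is the CMND value at the chosen lag; frames are
#' flagged valid only when signal power reaches `power_floor`, aperiodicity
#' stays at or below `ap_threshold`, and the estimate does not exceed a
#' quarter of the sampling rate - above fs/4 the estimator is unreliable
#' and [ridge_f0()] should be used instead (see [select_engine()]).
#'
#' The difference function is computed exactly (via FFT cross-correlation
#' plus cumulative energy terms); lags run from 1 to `floor(window / 2)`,
#' with the integration length `window - floor(window / 2)` so every term
#' stays inside the frame.
#'
#' @param x numeric signal (e.g. a demeaned glottal opening waveform in mm,
#'   or calibrated sound in Pa). A `signal_trace` supplies `fs` and the
#'   time origin.
#' @param fs sampling rate, Hz.
#' @param window analysis window, samples; must satisfy
#'   `window >= 2 * fs / f0_min` for the lowest frequency of interest.
#' @param hop hop between frames, samples. For glottal opening waveforms
#'   sampled at the video frame rate the conventional hop is 10 frames; for
#'   raw audio a larger hop (default `window %/% 2`) is typical.
#' @param ap_threshold absolute CMND threshold (default 0.1).
#' @param power_floor minimum frame mean-square power for a valid estimate
#'   (default 0: no gating).
#' @param t0 time of the first sample, s (taken from a trace if given).
#' @return An `fo_track`: data frame with columns `time` (frame centers,
#'   s), `f0` (Hz), `aperiodicity`, `power`, `valid`; attributes `fs`,
#'   `engine = "yin"` and the parameters used.
#' @export
yin_f0 <- function(x, fs = trace_fs(x), window, hop = NULL,
                   ap_threshold = 0.1, power_floor = 0,
                   t0 = if (inherits(x, "signal_trace")) trace_t0(x) else 0) {
  force(fs); force(t0)
  x <- as.numeric(x)
  n <- length(x)
  window <- as.integer(window)
  if (window > n) stop("invalid parameter: window longer than signal")
  if (window < 8L) stop("invalid parameter: window too short")
  if (is.null(hop)) hop <- window %/% 2L
  tau_max <- window %/% 2L
  nint <- window - tau_max
  starts <- seq(1L, n - window + 1L, by = hop)
  L <- stats::nextn(window + tau_max, c(2, 3, 5))
  res <- vapply(starts, function(s) {
    fr <- x[s:(s + window - 1L)]
    seg <- fr[seq_len(nint)]
    # cross term c(tau) = sum_j fr[j] * fr[j + tau], j = 1..nint
    FR <- stats::fft(c(fr, numeric(L - window)))
    SG <- stats::fft(c(seg, numeric(L - nint)))
    cc <- Re(stats::fft(FR * Conj(SG), inverse = TRUE)) / L
    taus <- seq_len(tau_max)
    e <- cumsum(fr^2)
    # energy of fr[(1+tau)..(nint+tau)]
    e2 <- e[taus + nint] - e[taus]
    d <- (e[nint] + e2 - 2 * cc[taus + 1L])
    d[d < 0] <- 0                      # numerical guard
    dp <- d * taus / pmax(cumsum(d), .Machine$double.xmin)
    pick <- yin_pick(dp, d, ap_threshold)
    c(fs / pick[1], pick[2], mean(fr^2))
  }, numeric(3))
  f0 <- res[1, ]; ap <- res[2, ]; pw <- res[3, ]
  valid <- pw >= power_floor & ap <= ap_threshold &
    f0 <= fs / 4 & is.finite(f0) & f0 > 0
  out <- data.frame(time = t0 + (starts - 1 + window / 2) / fs,
                    f0 = f0, aperiodicity = ap, power = pw, valid = valid)
  structure(out, fs = fs, engine = "yin",
            params = list(window = window, hop = hop,
                          ap_threshold = ap_threshold,
                          power_floor = power_floor),
            class = c("fo_track", "data.frame"))
}

# Choose the yin lag: the smallest-lag local minimum of the CMND whose
# parabolically interpolated dip value falls below the threshold (global
# minimum as fallback). The interpolated value matters: when the true
# period falls halfway between integer lags the sampled CMND straddles the
# dip and can sit above the threshold while the dip itself is deep -
# testing the sampled value instead causes octave-down errors whenever a
# period multiple lands nearer an integer lag. The lag is then refined on
# the raw difference function (the CMND's cumulative normalization is
# asymmetric around minima and would bias the refinement); the reported
# aperiodicity is the interpolated dip value. Returns
# c(refined_lag, aperiodicity).
yin_pick <- function(dp, d, ap_threshold) {
  nt <- length(dp)
  dip_val <- function(i) {
    off <- parab_offset(dp, i)
    max(0, dp[i] - 0.25 * (dp[max(1L, i - 1L)] - dp[min(nt, i + 1L)]) * off)
  }
  interior <- 2:(nt - 1L)
  mins <- interior[dp[interior] <= dp[interior - 1L] &
                   dp[interior] <= dp[interior + 1L]]
  tau <- NA_integer_; ap <- NA_real_
  for (i in mins) {
    v <- dip_val(i)
    if (v < ap_threshold) { tau <- i; ap <- v; break }
  }
  if (is.na(tau)) {
    tau <- which.min(dp)
    ap <- dip_val(tau)
  }
  c(tau + parab_offset(d, tau), ap)
}

# offset in [-0.5, 0.5] of the parabola vertex through v[i-1], v[i], v[i+1]
parab_offset <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(0)
  a <- v[i - 1L]; b <- v[i]; cc <- v[i + 1L]
  den <- a - 2 * b + cc
  if (abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (a - cc) / den))
}

#' @export
print.fo_track <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<fo_track> %d frames (%d valid), engine %s\n",
              nrow(x), nv, attr(x, "engine")))
  if (nv) cat(sprintf("  valid f0: %.5g - %.5g Hz (median %.5g)\n",
                      min(x$f0[x$valid]), max(x$f0[x$valid]),
                      stats::median(x$f0[x$valid])))
  invisible(x)
}
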