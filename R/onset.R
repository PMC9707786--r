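#' Running RMS amplitude of a signal
#'
#' Centered moving root-mean-square over a window of `window_s` seconds,
#' computed with cumulative sums. Used for sound-onset detection and call
#' segmentation.
#'
#' @param x numeric vector or `signal_trace`.
#' @param fs sampling rate, Hz (taken from the trace if omitted).
#' @param window_s window length, s.
#' @return Numeric vector of the same length as `x`.
#' @export
running_rms <- function(x, fs = trace_fs(x), window_s = 1e-3) {
  k <- max(1L, round(window_s * fs))
  cs <- cumsum(c(0, as.numeric(x)^2))
  n <- length(x)
  h1 <- k %/% 2L
  lo <- pmax(0L, seq_len(n) - 1L - h1)
  hi <- pmin(n, lo + k)
  lo <- pmin(lo, hi - 1L)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Detect phonation onset in the sound signal
#'
#' Onset is the first time the running RMS of the calibrated sound crosses
#' the threshold (default 0.2 mPa) and stays above it for at least
#' `hold_s` - the debounce rejects isolated clicks. Returns `NA` when the
#' threshold is never crossed (no phonation).
#'
#' @param sound a [sound_trace()] in Pa.
#' @param threshold amplitude criterion, Pa (default `2e-4`, i.e. 0.2 mPa).
#' @param power_window_s RMS window, s.
#' @param hold_s minimum time the RMS must remain above threshold, s.
#' @return Onset time in seconds (trigger-relative), or `NA_real_`; the
#'   RMS value at onset is attached as attribute `rms_at_onset`.
#' @export
detect_sound_onset <- function(sound, threshold = 2e-4,
                               power_window_s = 1e-3, hold_s = 2e-3) {
  stopifnot(inherits(sound, "sound_trace"))
  fs <- trace_fs(sound)
  rms <- running_rms(sound, fs, power_window_s)
  above <- rms >= threshold
  if (!any(above)) return(NA_real_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  need <- max(1L, round(hold_s * fs))
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_real_)
  i <- starts[ok[1]]
  out <- trace_t0(sound) + (i - 1) / fs
  attr(out, "rms_at_onset") <- rms[i]
  out
}

#' Phonation threshold pressure and pressure speed at onset
#'
#' PTP and S_ptp are defined as the (500 Hz low-pass filtered) bronchial
#' pressure and its rate of change at the time the sound amplitude crosses
#' the 0.2 mPa criterion. Pressure and sound must be synchronized: same
#' sampling rate and same trigger-relative alignment.
#'
#' @param pressure a [pressure_trace()], kPa (raw; filtering is applied
#'   internally unless `filter = FALSE`).
#' @param sound a [sound_trace()], Pa.
#' @param threshold sound amplitude criterion, Pa.
#' @param power_window_s,hold_s onset-detector settings, see
#'   [detect_sound_onset()].
#' @param cutoff_hz,order pressure filter settings, see
#'   [lowpass_pressure()].
#' @param filter set `FALSE` if `pressure` is already filtered.
#' @return An object of class `onset_result`: list with `detected`,
#'   `onset_time` (s), `ptp` (kPa), `s_ptp` (kPa/s), `threshold_used` (Pa).
#'   When no onset is detected, `ptp` and `s_ptp` are `NA`.
#' @export
compute_ptp <- function(pressure, sound, threshold = 2e-4,
                        power_window_s = 1e-3, hold_s = 2e-3,
                        cutoff_hz = 500, order = 6L, filter = TRUE) {
  stopifnot(inherits(pressure, "pressure_trace"),
            inherits(sound, "sound_trace"))
  if (abs(trace_fs(pressure) - trace_fs(sound)) > 1e-9)
    stop("invalid parameter: pressure and sound sampling rates differ")
  if (abs(length(pressure) - length(sound)) > 1L)
    stop("invalid parameter: pressure and sound lengths misaligned")
  filt <- if (filter) lowpass_pressure(pressure, cutoff_hz, order) else pressure
  onset <- detect_sound_onset(sound, threshold, power_window_s, hold_s)
  if (is.na(onset)) {
    res <- list(detected = FALSE, onset_time = NA_real_, ptp = NA_real_,
                s_ptp = NA_real_, threshold_used = threshold)
  } else {
    spd <- pressure_speed(filt)
    ptp <- stats::approx(trace_times(filt), as.numeric(filt),
                         xout = onset, rule = 2)$y
    s_ptp <- stats::approx(trace_times(spd), as.numeric(spd),
                           xout = onset, rule = 2)$y
    res <- list(detected = TRUE, onset_time = as.numeric(onset), ptp = ptp,
                s_ptp = s_ptp, threshold_used = threshold)
  }
  structure(res, class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "<onset_result> onset at %.4f s: PTP = %.3f kPa, S_ptp = %.3f kPa/s\n",
      x$onset_time, x$ptp, x$s_ptp))
  } else {
    cat("<onset_result> no phonation onset detected\n")
  }
  invisible(x)
}
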