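#' Synthesize harmonic sound locked to the glottal oscillation
#'
#' Generates the microphone signal of a synthetic trial: a harmonic series
#' whose instantaneous fundamental equals the kinematic `f0(t)` by
#' construction (phase integrates the same frequency profile from the same
#' onset), with amplitude following a linear attack envelope after each
#' oscillation-onset and Gaussian sensor noise. Harmonics are truncated
#' below the Nyquist frequency. Before onset the signal is noise only.
#'
#' @param f0prof an [f0_profile()] shared with the kinematics.
#' @param episodes two-column matrix or data.frame of episode start/end
#'   times, s (e.g. from the truth of [simulate_kinematics()] or from
#'   [phonation_intervals()]); may have zero rows (silent trial).
#' @param fs sampling rate, Hz.
#' @param duration total duration, s.
#' @param amp_peak peak amplitude of the fundamental, Pa.
#' @param amp_rise_s attack time over which amplitude ramps 0 to
#'   `amp_peak`, s.
#' @param n_harmonics number of harmonics (amplitudes fall off as 1/h);
#'   harmonics at or above `0.95 * fs / 2` are dropped.
#' @param noise_sd sensor noise sd, Pa.
#' @param pressure_fun optional function of time giving pressure in kPa
#'   (needed for `ramp_locked` f0 profiles).
#' @param delay_s optional microphone propagation delay, s (default 0; the
#'   44 mm larynx-microphone distance of the physical setup corresponds to
#'   about 0.13 ms and is ignored by default).
#' @param seed optional integer seed for the noise.
#' @return A [sound_trace()] in Pa.
#' @export
synthesize_sound <- function(f0prof, episodes, fs, duration,
                             amp_peak = 0.02, amp_rise_s = 0.05,
                             n_harmonics = 3L, noise_sd = 2e-5,
                             pressure_fun = NULL, delay_s = 0,
                             seed = NULL) {
  if (fs <= 0 || duration <= 0) stop("invalid parameter: fs, duration > 0")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  episodes <- as.matrix(episodes)
  if (nrow(episodes)) {
    for (e in seq_len(nrow(episodes))) {
      on <- episodes[e, 1]; off <- episodes[e, 2]
      idx <- which(t >= on & t < off)
      if (!length(idx)) next
      f0 <- f0_eval(f0prof, t[idx], t_onset = on, pressure_fun = pressure_fun)
      fmax <- max(f0)
      phase <- 2 * pi * (cumsum(f0) - f0) / fs
      env <- pmin(1, (t[idx] - on) / amp_rise_s)
      seg <- numeric(length(idx))
      for (h in seq_len(n_harmonics)) {
        if (h * fmax >= 0.95 * fs / 2) break
        seg <- seg + sin(h * phase) / h
      }
      x[idx] <- x[idx] + amp_peak * env * seg
    }
  }
  if (delay_s > 0) {
    k <- round(delay_s * fs)
    if (k > 0) x <- c(numeric(k), x)[seq_len(n)]
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  sound_trace(x, fs = fs)
}

#' Phonation intervals of a pressure protocol
#'
#' Applies the two-condition onset rule (see [simulate_kinematics()]) to a
#' pressure trace and returns the time intervals during which the synthetic
#' larynx oscillates. Used to synchronize sound synthesis with kinematics
#' without rendering any video.
#'
#' @param pressure a [pressure_trace()].
#' @param ptp_true threshold pressure, kPa.
#' @param rate_gate minimum pressure speed, kPa/s, or `NULL`.
#' @return Data frame with columns `start`, `end` (s) and attributes
#'   `onset_pressure`, `onset_pressure_speed` of the first episode.
#' @export
phonation_intervals <- function(pressure, ptp_true, rate_gate = NULL) {
  p <- as.numeric(pressure)
  fs <- trace_fs(pressure)
  tt <- trace_times(pressure)
  spd_mid <- diff(p) * fs
  spd <- c(spd_mid[1], 0.5 * (spd_mid[-1] + spd_mid[-length(spd_mid)]),
           spd_mid[length(spd_mid)])
  ep <- phonation_episodes(p, spd, ptp_true, rate_gate)
  if (!any(ep > 0L)) {
    out <- data.frame(start = numeric(0), end = numeric(0))
  } else {
    out <- do.call(rbind, lapply(seq_len(max(ep)), function(id) {
      idx <- range(which(ep == id))
      data.frame(start = tt[idx[1]], end = tt[idx[2]] + 1 / fs)
    }))
    first <- which(ep == 1L)[1]
    attr(out, "onset_pressure") <- p[first]
    attr(out, "onset_pressure_speed") <- spd[first]
  }
  out
}
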