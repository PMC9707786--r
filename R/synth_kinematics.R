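#' Kinematic profile of the synthetic oscillating glottis
#'
#' Describes the prescribed motion of the two tissue edges bounding the
#' glottal opening at `n_lines` anterior-posterior (AP) scan lines. The
#' opening at line i is
#' `w_i(t) = slit_px + A_i * (1 - cos(phi(t) + delta_i)) * env(t)`,
#' with phase `phi` integrating the instantaneous fundamental frequency
#' `f0(t)` from oscillation onset, an AP phase lag `delta_i` emulating a
#' mucosal-wave-like travelling component, and a short onset envelope
#' `env` growing linearly over `onset_cycles` cycles so oscillation starts
#' smoothly from the closed state. Amplitudes follow a raised-cosine AP
#' profile peaking at `peak_line` so the AP position of maximal mean
#' opening is known by construction.
#'
#' @param duration video duration, s.
#' @param fps frame rate, frames/s. Must satisfy `fps >= 4 * max(f0)`.
#' @param f0 fundamental-frequency profile from [f0_profile()], or a single
#'   number for a constant f0, Hz.
#' @param amplitude_px peak half-amplitude of the opening at the peak line,
#'   pixels (peak opening width is `slit_px + 2 * amplitude_px`).
#' @param n_lines number of AP scan lines, 8 to 10.
#' @param phase_lag_total total AP phase lag from first to last line,
#'   radians (default 0.3 * pi; the AP phase relation is a free choice of
#'   the generator, not a measured quantity).
#' @param peak_line 1-based index of the line with maximal amplitude
#'   (default the middle line).
#' @param slit_px residual slit width when not phonating, pixels.
#' @param center_x glottal midline column, pixels (0-based image
#'   coordinates).
#' @param onset_cycles cycles over which the oscillation amplitude grows at
#'   episode onset.
#' @return An object of class `kinematic_profile`.
#' @export
kinematic_profile <- function(duration, fps, f0, amplitude_px = 12,
                              n_lines = 9L, phase_lag_total = 0.3 * pi,
                              peak_line = NULL, slit_px = 1,
                              center_x = 64, onset_cycles = 3) {
  if (n_lines < 8L || n_lines > 10L)
    stop("invalid parameter: n_lines must be 8..10")
  if (is.numeric(f0)) f0 <- f0_profile("constant", f0 = f0)
  if (!inherits(f0, "f0_profile")) stop("f0 must be an f0_profile")
  fmax <- f0_max(f0, duration)
  if (fmax <= 0) stop("f0 must be positive")
  if (fps < 4 * fmax)
    stop(sprintf("sampling inadequacy: fps %g < 4 x max f0 %g", fps, fmax))
  if (is.null(peak_line)) peak_line <- (n_lines + 1L) %/% 2L
  i <- seq_len(n_lines)
  amp <- amplitude_px * (0.35 + 0.65 * cos(pi / 2 *
           (i - peak_line) / max(peak_line - 1, n_lines - peak_line, 1))^2)
  structure(list(duration = duration, fps = fps, f0 = f0,
                 amplitude_px = amp, n_lines = as.integer(n_lines),
                 phase_offsets = -phase_lag_total *
                   (i - 1) / max(n_lines - 1, 1),
                 peak_line = as.integer(peak_line), slit_px = slit_px,
                 center_x = center_x, onset_cycles = onset_cycles),
            class = "kinematic_profile")
}

#' Fundamental-frequency profiles for the generator
#'
#' @param type `"constant"` (`f0`), `"sweep"` (linear from `from` to `to`
#'   Hz over `span_s` seconds after oscillation onset, then held), or
#'   `"ramp_locked"` (`f0 = base + slope_hz_per_kpa * (p - p_ref)` follows
#'   the driving pressure).
#' @param ... profile parameters, see `type`.
#' @return An `f0_profile` object; evaluate with `f0_eval(profile, t,
#'   t_onset, pressure_fun)`.
#' @export
f0_profile <- function(type = c("constant", "sweep", "ramp_locked"), ...) {
  type <- match.arg(type)
  p <- list(...)
  defaults <- switch(type,
    constant = list(f0 = 2000),
    sweep = list(from = 1800, to = 2300, span_s = 0.1),
    ramp_locked = list(base = 2000, slope_hz_per_kpa = 150, p_ref = 4))
  p <- modify_defaults(defaults, p)
  structure(c(list(type = type), p), class = "f0_profile")
}

f0_eval <- function(prof, t, t_onset = 0, pressure_fun = NULL) {
  switch(prof$type,
    constant = rep(prof$f0, length(t)),
    sweep = {
      u <- pmax(0, pmin(1, (t - t_onset) / prof$span_s))
      prof$from + (prof$to - prof$from) * u
    },
    ramp_locked = {
      if (is.null(pressure_fun))
        stop("ramp_locked f0 profile needs the pressure")
      prof$base + prof$slope_hz_per_kpa * (pressure_fun(t) - prof$p_ref)
    })
}

f0_max <- function(prof, duration) {
  switch(prof$type,
    constant = prof$f0,
    sweep = max(prof$from, prof$to),
    ramp_locked = prof$base + abs(prof$slope_hz_per_kpa) * 8)
}

# Oscillation episodes under the two-condition onset rule: an episode can
# only *start* where pressure >= ptp AND (if rate_gate is set) pressure
# speed >= rate_gate; once started it persists while pressure >= ptp.
# p, speed: vectors on a common time grid. Returns integer episode id per
# sample (0 = not phonating).
phonation_episodes <- function(p, speed, ptp, rate_gate = NULL) {
  sustained <- p >= ptp
  gate_ok <- if (is.null(rate_gate)) sustained else sustained & speed >= rate_gate
  ep <- integer(length(p))
  if (!any(sustained)) return(ep)
  r <- rle(sustained)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  id <- 0L
  for (k in which(r$values)) {
    g <- which(gate_ok[starts[k]:ends[k]])
    if (length(g)) {
      id <- id + 1L
      ep[(starts[k] + g[1] - 1L):ends[k]] <- id
    }
  }
  ep
}

#' Simulate prescribed glottal-edge kinematics
#'
#' Evaluates the kinematic profile against a driving pressure, applying the
#' two-condition onset rule observed for vocal membranes: oscillation starts
#' only where pressure reaches `ptp_true` and, when `rate_gate` is given,
#' the rate of pressure change also reaches `rate_gate` (kPa/s); it then
#' persists while pressure stays above `ptp_true`. With a gate that the
#' protocol never satisfies (e.g. a 50 kPa/s gate under a 1 kPa/s ramp) the
#' glottis stays closed and `onset_time` is `NA` - that is a valid result,
#' not an error.
#'
#' @param profile a [kinematic_profile()].
#' @param pressure a [pressure_trace()] covering the simulated window.
#' @param ptp_true true phonation threshold pressure, kPa.
#' @param rate_gate minimum pressure speed for oscillation onset, kPa/s, or
#'   `NULL` for no rate requirement.
#' @param t_start trigger-relative time of the first video frame, s.
#' @return A list of class `glottal_kinematics`: matrices `left_x`,
#'   `right_x` (`frames x n_lines`, pixel coordinates of the two edges),
#'   `times`, `phonating`, `f0_hz` (instantaneous f0 per frame, `NA` when
#'   closed), and a `truth` list (`onset_time`, `onset_pressure`,
#'   `onset_pressure_speed`, `ptp_true`, `rate_gate`).
#' @export
simulate_kinematics <- function(profile, pressure, ptp_true,
                                rate_gate = NULL, t_start = 0) {
  stopifnot(inherits(profile, "kinematic_profile"),
            inherits(pressure, "pressure_trace"))
  fps <- profile$fps
  nf <- round(profile$duration * fps)
  t <- t_start + (seq_len(nf) - 1) / fps
  pt <- trace_times(pressure)
  if (t[1] < pt[1] - 1e-9 || t[nf] > pt[length(pt)] + 1e-9)
    stop("video window extends beyond the pressure trace")
  pfun <- stats::approxfun(pt, as.numeric(pressure), rule = 2)
  p <- pfun(t)
  # pressure speed on the frame grid (central differences of the analytic
  # trace; synthetic pressure is noise-free unless asked otherwise)
  ps <- as.numeric(pressure)
  spd_mid <- diff(ps) * trace_fs(pressure)
  spd <- stats::approx(pt[-length(pt)] + 0.5 / trace_fs(pressure),
                       spd_mid, xout = t, rule = 2)$y
  ep <- phonation_episodes(p, spd, ptp_true, rate_gate)
  phon <- ep > 0L
  f0 <- rep(NA_real_, nf)
  phase <- rep(NA_real_, nf)
  env <- rep(0, nf)
  if (any(phon)) {
    for (id in seq_len(max(ep))) {
      idx <- which(ep == id)
      f0i <- f0_eval(profile$f0, t[idx], t_onset = t[idx[1]],
                     pressure_fun = pfun)
      f0[idx] <- f0i
      # phase integrates 2*pi*f0 from episode onset
      phase[idx] <- 2 * pi * (cumsum(f0i) - f0i) / fps
      cyc <- phase[idx] / (2 * pi)
      env[idx] <- pmin(1, cyc / profile$onset_cycles)
    }
  }
  nl <- profile$n_lines
  w <- matrix(profile$slit_px, nf, nl)
  if (any(phon)) {
    ii <- which(phon)
    for (l in seq_len(nl)) {
      w[ii, l] <- profile$slit_px + profile$amplitude_px[l] *
        (1 - cos(phase[ii] + profile$phase_offsets[l])) * env[ii]
    }
  }
  onset_idx <- if (any(phon)) which(phon)[1] else NA_integer_
  truth <- list(
    onset_time = if (is.na(onset_idx)) NA_real_ else t[onset_idx],
    onset_pressure = if (is.na(onset_idx)) NA_real_ else p[onset_idx],
    onset_pressure_speed = if (is.na(onset_idx)) NA_real_ else spd[onset_idx],
    ptp_true = ptp_true, rate_gate = rate_gate)
  structure(list(left_x = profile$center_x - w / 2,
                 right_x = profile$center_x + w / 2,
                 times = t, phonating = phon, f0_hz = f0,
                 profile = profile, truth = truth),
            class = "glottal_kinematics")
}
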