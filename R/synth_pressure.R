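#' Generate bronchial pressure protocols
#'
#' Produces the two driving-pressure protocols used on excised larynges: a
#' slow linear ramp (default 0 to 6 kPa at 1 kPa/s, the protocol used to
#' measure phonation threshold pressure of the ventricular folds) and trains
#' of fast pressure pulses (default 4 trapezoidal pulses of 300 ms between
#' 0 and 4 kPa, the protocol that elicits vocal membrane oscillation). The
#' ramp is exact: between its start and end the analytic slope equals
#' `rate` at every sample. Pulse rise/fall rate is `(peak - floor) /
#' rise_time` and is recorded in the protocol attributes so synthetic trials
#' can carry it as ground truth.
#'
#' @param protocol `"slow_ramp"` or `"fast_pulses"`.
#' @param params named list overriding protocol defaults. Slow ramp:
#'   `start` (kPa, default 0; the experiments sometimes started at 3),
#'   `end` (kPa, default 6), `rate` (kPa/s, default 1), `pre_hold_s`,
#'   `post_hold_s` (flat segments before/after the ramp, default 0).
#'   Fast pulses: `n_pulses` (4), `width_s` (0.3), `floor` (0 kPa),
#'   `peak` (4 kPa), `rise_s` (0.03, giving ~133 kPa/s), `gap_s` (0.2),
#'   `lead_s` (0.1).
#' @param fs sampling rate, Hz.
#' @param noise_sd additive Gaussian noise, kPa (default 0).
#' @param seed optional integer seed used when `noise_sd > 0`.
#' @return A [pressure_trace()] with attribute `protocol` (a list recording
#'   every protocol parameter, including `rise_rate_kpa_s` for pulses and
#'   the ramp time span).
#' @examples
#' p <- generate_pressure("slow_ramp", fs = 1000)
#' length(p)            # 6001 samples: 6 s inclusive of both endpoints
#' @export
generate_pressure <- function(protocol = c("slow_ramp", "fast_pulses"),
                              params = list(), fs, noise_sd = 0,
                              seed = NULL) {
  protocol <- match.arg(protocol)
  if (!is.numeric(fs) || fs <= 0) stop("invalid parameter: fs must be > 0")
  if (protocol == "slow_ramp") {
    p <- modify_defaults(list(start = 0, end = 6, rate = 1,
                              pre_hold_s = 0, post_hold_s = 0), params)
    if (p$rate <= 0) stop("invalid parameter: rate must be > 0")
    if (p$end < p$start) stop("invalid parameter: end below start")
    ramp_s <- (p$end - p$start) / p$rate
    dur <- p$pre_hold_s + ramp_s + p$post_hold_s
    t <- seq(0, dur, by = 1 / fs)
    x <- ifelse(t < p$pre_hold_s, p$start,
                ifelse(t < p$pre_hold_s + ramp_s,
                       p$start + p$rate * (t - p$pre_hold_s), p$end))
    proto <- c(list(name = "slow_ramp", ramp_start_s = p$pre_hold_s,
                    ramp_end_s = p$pre_hold_s + ramp_s), p)
  } else {
    p <- modify_defaults(list(n_pulses = 4L, width_s = 0.3, floor = 0,
                              peak = 4, rise_s = 0.03, gap_s = 0.2,
                              lead_s = 0.1), params)
    if (p$width_s <= 0) stop("invalid parameter: width_s must be > 0")
    if (p$rise_s <= 0 || 2 * p$rise_s > p$width_s)
      stop("invalid parameter: rise_s must be in (0, width_s/2]")
    dur <- p$lead_s + p$n_pulses * (p$width_s + p$gap_s)
    t <- seq(0, dur, by = 1 / fs)
    x <- rep(p$floor, length(t))
    for (k in seq_len(p$n_pulses)) {
      on <- p$lead_s + (k - 1) * (p$width_s + p$gap_s)
      # trapezoid: rise, plateau, fall
      seg <- pmax(0, pmin(1, pmin((t - on) / p$rise_s,
                                  (on + p$width_s - t) / p$rise_s)))
      x <- pmax(x, p$floor + (p$peak - p$floor) * seg)
    }
    proto <- c(list(name = "fast_pulses",
                    rise_rate_kpa_s = (p$peak - p$floor) / p$rise_s), p)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + stats::rnorm(length(x), sd = noise_sd)
  }
  out <- pressure_trace(x, fs = fs)
  attr(out, "protocol") <- proto
  out
}

modify_defaults <- function(defaults, params) {
  if (length(params)) {
    unknown <- setdiff(names(params), names(defaults))
    if (length(unknown))
      stop("unknown protocol parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(params)] <- params
  }
  defaults
}
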