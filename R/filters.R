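#' Zero-phase low-pass filtering of bronchial pressure
#'
#' Applies a 6th-order Butterworth low-pass at 500 Hz forward and backward
#' (zero phase) to remove high-frequency fluctuations before computing the
#' pressure speed. Zero-phase application matters: a causal single pass
#' would delay the trace and bias the pressure read off at sound onset.
#'
#' The filter is realized as a cascade of three zero-phase biquads
#' (second-order sections). At the acquisition rates used here the
#' normalized cutoff is tiny (500 Hz at 250 kHz is 0.004 of Nyquist) and a
#' direct-form order-6 recursion is numerically unstable in double
#' precision; the SOS cascade is exact. Signal ends are extended by odd
#' reflection before filtering so that constant and ramp segments pass
#' through unchanged (DC gain 1 to ~1e-11).
#'
#' @param trace a [pressure_trace()]; `fs` must exceed `2 * cutoff_hz`.
#' @param cutoff_hz cutoff frequency, Hz (default 500).
#' @param order filter order; must be even (default 6).
#' @return A filtered [pressure_trace()] with the same fs and t0.
#' @export
lowpass_pressure <- function(trace, cutoff_hz = 500, order = 6L) {
  stopifnot(inherits(trace, "pressure_trace"))
  fs <- trace_fs(trace)
  if (fs <= 2 * cutoff_hz)
    stop("invalid parameter: fs must exceed twice the cutoff")
  y <- zerophase_butter(as.numeric(trace), fs, cutoff_hz, order)
  out <- pressure_trace(y, fs = fs, t0 = trace_t0(trace))
  attr(out, "protocol") <- attr(trace, "protocol")
  attr(out, "filtered") <- list(cutoff_hz = cutoff_hz, order = order)
  out
}

# Butterworth low-pass as second-order sections (bilinear transform of the
# analog prototype pole pairs), applied forward-backward with odd-reflection
# end padding.
butter_sos <- function(order, wc) {
  if (order %% 2L != 0L) stop("order must be even")
  warped <- tan(pi * wc / 2)
  theta <- pi / 2 + (2 * seq_len(order / 2) - 1) * pi / (2 * order)
  lapply(theta, function(th) {
    p <- warped * complex(real = cos(th), imaginary = sin(th))
    a0 <- 1 - 2 * Re(p) + Mod(p)^2
    list(b = Mod(p)^2 * c(1, 2, 1) / a0,
         a = c(1, (2 * Mod(p)^2 - 2) / a0,
               (1 + 2 * Re(p) + Mod(p)^2) / a0))
  })
}

zerophase_butter <- function(x, fs, cutoff_hz, order = 6L) {
  n <- length(x)
  sos <- butter_sos(order, cutoff_hz / (fs / 2))
  npad <- min(n - 1L, ceiling(16 * fs / cutoff_hz))
  y <- if (npad > 0L)
    c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  else x
  for (s in sos) y <- signal::filtfilt(filt = s$b, a = s$a, y)
  y[(npad + 1):(npad + n)]
}

#' Rate of change of bronchial pressure
#'
#' First difference of the (filtered) pressure multiplied by the
#' acquisition rate, giving kPa/s. The result has one sample fewer than the
#' input and is time-stamped at the midpoints between input samples.
#'
#' @param filtered a [pressure_trace()], normally from [lowpass_pressure()].
#' @return A `signal_trace` of pressure speed in kPa/s.
#' @export
pressure_speed <- function(filtered) {
  stopifnot(inherits(filtered, "pressure_trace"))
  fs <- trace_fs(filtered)
  new_trace(diff(as.numeric(filtered)) * fs, fs = fs,
            t0 = trace_t0(filtered) + 0.5 / fs,
            class = "speed_trace", unit = "kPa/s")
}
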