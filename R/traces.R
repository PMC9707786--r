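#' Calibrated 1-D signal traces
#'
#' `pressure_trace()` and `sound_trace()` wrap a numeric sample vector
#' together with its sampling rate and trigger-alignment offset. Pressure is
#' bronchial (subglottal) pressure in kilopascal; sound is calibrated sound
#' pressure in pascal. All analysis functions in the package accept and
#' return these light-weight containers so that sampling-rate bookkeeping is
#' never implicit.
#'
#' @param samples numeric vector of samples (kPa for pressure, Pa for sound).
#' @param fs sampling rate, Hz. Must be positive.
#' @param t0 time of the first sample relative to the acquisition trigger,
#'   seconds.
#' @param mic_distance_mm microphone-to-source distance, mm (metadata only;
#'   no propagation-delay correction is applied by default).
#' @return An object of class `pressure_trace` or `sound_trace`; both
#'   inherit from `signal_trace`.
#' @examples
#' p <- pressure_trace(seq(0, 6, length.out = 100), fs = 100)
#' trace_times(p)[1:3]
#' @export
pressure_trace <- function(samples, fs, t0 = 0) {
  new_trace(samples, fs, t0, "pressure_trace", unit = "kPa")
}

#' @rdname pressure_trace
#' @export
sound_trace <- function(samples, fs, t0 = 0, mic_distance_mm = NA_real_) {
  x <- new_trace(samples, fs, t0, "sound_trace", unit = "Pa")
  attr(x, "mic_distance_mm") <- mic_distance_mm
  x
}

new_trace <- function(samples, fs, t0, class, unit) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("trace samples must be finite")
  structure(as.numeric(samples), fs = fs, t0 = t0, unit = unit,
            class = c(class, "signal_trace"))
}

#' @rdname pressure_trace
#' @param x a `signal_trace`.
#' @export
trace_fs <- function(x) attr(x, "fs")

#' @rdname pressure_trace
#' @export
trace_t0 <- function(x) attr(x, "t0")

#' @rdname pressure_trace
#' @export
trace_times <- function(x) {
  attr(x, "t0") + (seq_along(x) - 1) / attr(x, "fs")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g Hz (%.4g s), unit %s, t0 = %g s\n",
              class(x)[1], length(x), attr(x, "fs"),
              length(x) / attr(x, "fs"), attr(x, "unit"), attr(x, "t0")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' @rdname pressure_trace
#' @param from,to absolute time window `[from, to)`, s; `trace_window()`
#'   subsets a trace to it, updating `t0` to the first retained sample.
#' @export
trace_window <- function(x, from, to) {
  tt <- trace_times(x)
  keep <- which(tt >= from - 1e-12 & tt < to - 1e-12)
  if (length(keep) == 0L) stop("time window contains no samples")
  out <- unclass(x)[keep]
  attributes(out) <- NULL
  structure(out, fs = attr(x, "fs"), t0 = tt[keep[1]],
            unit = attr(x, "unit"), class = class(x))
}
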