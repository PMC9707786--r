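#' Regression of sound f0 on vibration f0
#'
#' Ordinary least squares (with intercept) of the sound fundamental on the
#' vibration fundamental, over analysis frames valid in both tracks. A
#' slope of 1 with r-squared near 1 demonstrates that the imaged tissue
#' vibration produces the recorded sound. Tracks are paired by nearest
#' time within half the smaller hop.
#'
#' @param f0_vibration,f0_sound `fo_track` objects (see [yin_f0()]).
#' @param max_dt pairing tolerance, s (default half the vibration hop).
#' @return A `regression_result`: `slope`, `intercept`, `r_squared`, `n`,
#'   `residual_sd`, plus the paired points in `$points`.
#' @export
identity_regression <- function(f0_vibration, f0_sound, max_dt = NULL) {
  v <- f0_vibration[f0_vibration$valid, ]
  s <- f0_sound[f0_sound$valid, ]
  if (is.null(max_dt)) {
    dv <- if (nrow(v) > 1) stats::median(diff(v$time)) else Inf
    ds <- if (nrow(s) > 1) stats::median(diff(s$time)) else Inf
    max_dt <- min(dv, ds) / 2
  }
  if (nrow(v) == 0L || nrow(s) == 0L)
    stop("insufficient data: no valid analysis frames in common")
  brk <- if (nrow(s) > 1) c(-Inf, s$time[-nrow(s)] + diff(s$time) / 2)
         else -Inf
  j <- findInterval(v$time, brk)
  j[j < 1L] <- 1L
  dt <- abs(s$time[j] - v$time)
  keep <- dt <= max_dt
  pts <- data.frame(time = v$time[keep], f0_vibration = v$f0[keep],
                    f0_sound = s$f0[j[keep]])
  if (nrow(pts) < 3L)
    stop("insufficient data: fewer than 3 shared valid frames")
  if (stats::var(pts$f0_vibration) == 0)
    stop("insufficient data: vibration f0 has no variance")
  fit <- stats::lm(f0_sound ~ f0_vibration, data = pts)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, n = nrow(pts),
                 residual_sd = sm$sigma, points = pts),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> slope %.4f, intercept %.4g Hz, r^2 %.4f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Five-number summary of an f0 distribution
#'
#' Minimum, quartiles and maximum of a collection of f0 values, matching
#' range-whisker boxplots (whiskers are the full range; nothing is trimmed
#' as an outlier). Quartiles use linear interpolation between closest
#' order statistics (`stats::quantile` type 7).
#'
#' @param f0_values numeric vector, Hz; must be non-empty.
#' @return A `range_summary`: `minimum`, `q1`, `median`, `q3`, `maximum`,
#'   `n`.
#' @export
fo_range_summary <- function(f0_values) {
  f0_values <- f0_values[is.finite(f0_values)]
  if (length(f0_values) == 0L) stop("insufficient data: no f0 values")
  q <- stats::quantile(f0_values, c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = 7)
  structure(list(minimum = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 maximum = q[5], n = length(f0_values)),
            class = "range_summary")
}

#' @export
print.range_summary <- function(x, ...) {
  cat(sprintf(
    "<range_summary> n = %d: min %.4g | q1 %.4g | med %.4g | q3 %.4g | max %.4g Hz\n",
    x$n, x$minimum, x$q1, x$median, x$q3, x$maximum))
  invisible(x)
}

#' Segment calls in a continuous recording
#'
#' Returns the time intervals where the running RMS amplitude exceeds
#' `floor_pa`, with intervals separated by less than `min_gap_s` merged.
#' Intended for extracting short social-call segments from longer
#' recordings before f0 analysis.
#'
#' @param sound a [sound_trace()], Pa.
#' @param min_gap_s gaps shorter than this merge adjacent intervals, s.
#' @param floor_pa RMS amplitude floor, Pa.
#' @param window_s RMS window, s.
#' @return Data frame with columns `start`, `end` (s, trigger-relative);
#'   zero rows for silence.
#' @export
segment_calls <- function(sound, min_gap_s = 0.01, floor_pa = 2e-4,
                          window_s = 5e-4) {
  stopifnot(inherits(sound, "sound_trace"))
  fs <- trace_fs(sound)
  rms <- running_rms(sound, fs, window_s)
  above <- rms > floor_pa
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  # merge across short gaps
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if ((iv[k, 1] - last[2]) / fs < min_gap_s) {
        merged[[length(merged)]][2] <- iv[k, 2]
      } else merged[[length(merged) + 1L]] <- iv[k, ]
    }
  }
  m <- do.call(rbind, merged)
  data.frame(start = trace_t0(sound) + (m[, 1] - 1) / fs,
             end = trace_t0(sound) + m[, 2] / fs)
}

#' Scatter plot of the vibration-sound identity regression
#'
#' @param x a `regression_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.regression_result <- function(x, ...) {
  graphics::plot(x$points$f0_vibration, x$points$f0_sound,
                 xlab = "f0 vibration (Hz)", ylab = "f0 sound (Hz)",
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.6),
                 ...)
  graphics::abline(0, 1, lty = 3, col = "gray40")
  graphics::abline(x$intercept, x$slope, col = "firebrick")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "slope %.3f, r^2 %.3f (n=%d)", x$slope, x$r_squared, x$n))
  invisible(x)
}
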