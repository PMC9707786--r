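#' Build a glottovibrogram
#'
#' A glottovibrogram (GVG) is the glottal opening width as a function of
#' time and anterior-posterior (AP) position. It can be assembled from the
#' threshold path (a list of per-frame [glottal_width_profile()] results,
#' or directly from a stack plus threshold) or from the edge-tracking path
#' (an `edge_tracks` object, width per line = `right_x - left_x`).
#' Undefined edge-track values spanning at most `max_gap` consecutive
#' frames are linearly interpolated and counted in `n_interpolated`;
#' longer gaps raise an error naming the affected frames, and a line with
#' no defined values at all is a degenerate input.
#'
#' @param x an `edge_tracks` object, or a numeric matrix `frames x AP`
#'   of widths in pixels.
#' @param fps frame rate, Hz.
#' @param pixel_scale mm per pixel.
#' @param t0 time of the first frame, s.
#' @param ap_rows 0-based AP row indices of the columns of `x`.
#' @param source `"threshold"` or `"edges"` (set automatically for
#'   `edge_tracks` input).
#' @param max_gap longest run of undefined frames interpolated silently.
#' @return A `glottovibrogram`: list with `width` (time x AP matrix, mm),
#'   `width_px`, `times` (s), `ap_mm`, `ap_rows`, `source`,
#'   `n_interpolated`.
#' @export
build_gvg <- function(x, fps, pixel_scale = 1, t0 = 0, ap_rows = NULL,
                      source = "threshold", max_gap = 3L) {
  if (inherits(x, "edge_tracks")) {
    w <- x$right_x - x$left_x
    ap_rows <- x$line_rows
    fps <- x$fps; t0 <- x$t0; pixel_scale <- x$pixel_scale
    source <- "edges"
  } else {
    w <- as.matrix(x)
    if (is.null(ap_rows)) ap_rows <- seq_len(ncol(w)) - 1L
  }
  n_interp <- 0L
  for (j in seq_len(ncol(w))) {
    col <- w[, j]
    nas <- is.na(col)
    if (all(nas))
      stop(sprintf("degenerate input: AP line %d has no defined widths", j))
    if (any(nas)) {
      r <- rle(nas)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      bad <- which(r$values & r$lengths > max_gap)
      if (length(bad))
        stop(sprintf(
          "edge-track gap longer than %d frames on line %d (frames %s)",
          max_gap, j,
          paste(sprintf("%d-%d", starts[bad], ends[bad]), collapse = ", ")))
      w[, j] <- stats::approx(which(!nas), col[!nas], xout = seq_along(col),
                              rule = 2)$y
      n_interp <- n_interp + sum(nas)
    }
  }
  w[w < 0] <- 0
  structure(list(width = w * pixel_scale, width_px = w,
                 times = t0 + (seq_len(nrow(w)) - 1) / fps,
                 ap_mm = ap_rows * pixel_scale, ap_rows = ap_rows,
                 fps = fps, source = source, n_interpolated = n_interp),
            class = "glottovibrogram")
}

#' Threshold-path glottovibrogram straight from a frame stack
#'
#' Convenience wrapper running [segment_glottis_threshold()] and
#' [glottal_width_profile()] on every frame.
#'
#' @param stack a preprocessed [frame_stack()].
#' @param threshold gray threshold from the trial metadata.
#' @param margin_correct how to remove the dilation margin before widths
#'   are measured: `"erode"` (default) applies the exact adjoint erosion,
#'   which also undoes the slope-dependent vertical smear of the dilation;
#'   a number subtracts that many pixels from each non-empty row (see
#'   [dilation_margin()]); `"none"` leaves the margin in.
#' @return A `glottovibrogram` (source `"threshold"`).
#' @export
gvg_from_threshold <- function(stack, threshold, margin_correct = "erode") {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  nr <- dim(stack$pixels)[1]
  margin_px <- if (is.numeric(margin_correct)) margin_correct else 0
  w <- matrix(0, nf, nr)
  for (f in seq_len(nf)) {
    m <- segment_glottis_threshold(stack$pixels[, , f], threshold)
    if (identical(margin_correct, "erode")) {
      m$mask <- erode_line(erode_line(m$mask, "vertical"), "horizontal")
    }
    w[f, ] <- glottal_width_profile(m, pixel_scale = 1,
                                    margin_px = margin_px)$width_px
  }
  build_gvg(w, fps = stack$fps, pixel_scale = stack$pixel_scale,
            t0 = stack$t0, ap_rows = seq_len(nr) - 1L, source = "threshold")
}

#' @export
print.glottovibrogram <- function(x, ...) {
  cat(sprintf(
    "<glottovibrogram> %d frames x %d AP positions (%s path), %.4g s @ %g fps\n",
    nrow(x$width), ncol(x$width), x$source,
    nrow(x$width) / x$fps, x$fps))
  if (x$n_interpolated)
    cat(sprintf("  %d interpolated frame/line values\n", x$n_interpolated))
  invisible(x)
}

#' AP position of maximal mean opening
#'
#' The anterior-posterior index at which the time-averaged opening is
#' maximal; the opening waveform used for vibration f0 is extracted there.
#' Exact ties resolve to the anterior-most (smallest) index.
#'
#' @param gvg a `glottovibrogram`.
#' @return 1-based column index into `gvg$width`.
#' @export
max_opening_position <- function(gvg) {
  stopifnot(inherits(gvg, "glottovibrogram"))
  which.max(colMeans(gvg$width))
}

#' Extract the opening waveform at one AP position
#'
#' Slice of the glottovibrogram at a single AP column, as a 1-D signal at
#' the video frame rate. The mean-removed copy is what the yin pitch
#' analysis consumes (the estimator is offset-invariant on periodic
#' signals; demeaning simply removes the DC term from the power gate).
#'
#' @param gvg a `glottovibrogram`.
#' @param ap_index 1-based AP column (default [max_opening_position()]).
#' @param demean subtract the mean (default FALSE).
#' @return A `signal_trace` in mm at the frame rate, with attribute
#'   `ap_index`.
#' @export
opening_waveform <- function(gvg, ap_index = max_opening_position(gvg),
                             demean = FALSE) {
  stopifnot(inherits(gvg, "glottovibrogram"))
  if (ap_index < 1L || ap_index > ncol(gvg$width))
    stop("invalid parameter: ap_index out of range")
  w <- gvg$width[, ap_index]
  if (demean) w <- w - mean(w)
  out <- new_trace(w, fs = gvg$fps, t0 = gvg$times[1],
                   class = "opening_trace", unit = "mm")
  attr(out, "ap_index") <- ap_index
  out
}

#' Write a glottovibrogram as CSV
#'
#' Matrix layout with one header row of AP positions (mm) and a leading
#' column of frame times (s).
#'
#' @param gvg a `glottovibrogram`.
#' @param path output file.
#' @export
write_gvg_csv <- function(gvg, path) {
  d <- data.frame(time_s = gvg$times, gvg$width)
  names(d)[-1] <- sprintf("ap_%0.4f_mm", gvg$ap_mm)
  data.table::fwrite(d, path)
  invisible(path)
}

#' Plot a glottovibrogram heatmap
#'
#' @param x a `glottovibrogram`.
#' @param ... passed to [graphics::image()].
#' @export
plot.glottovibrogram <- function(x, ...) {
  graphics::image(x$times, x$ap_mm, x$width,
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "time (s)", ylab = "AP position (mm)",
                  main = sprintf("glottovibrogram (%s)", x$source), ...)
  invisible(x)
}
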