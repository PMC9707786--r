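#' Render synthetic glottis video frames
#'
#' Turns per-line edge kinematics into an 8-bit grayscale video. Edge
#' positions are linearly interpolated between scan-line rows to form an
#' elongated opening between two brighter tissue edges. Two appearance
#' modes are supported:
#'
#' * `"opaque"` - ventricular-fold-like scenes: every pixel of the opening
#'   is rendered at the dark `glottis` gray, so the opening is exactly the
#'   sub-threshold region and gray-threshold segmentation is valid.
#' * `"translucent"` - vocal-membrane-like scenes: a `membrane_px`-wide band
#'   inside each true edge is rendered at the `membrane` gray, which is
#'   nearly the surrounding-fold gray (the membrane lies over tissue of
#'   almost the same brightness). Only the central part of the opening is
#'   dark, so simple thresholding systematically under-reports the true
#'   aperture - the failure mode that motivates scan-line edge tracking.
#'   A thin darker rim (`rim_px` at the `rim` gray) marks the membrane
#'   edge itself, emulating the edge-on darkening of a thin tissue margin;
#'   it is what a gradient-based tracker can lock onto.
#'
#' Pixel `j` (0-based center coordinates) belongs to the aperture of a row
#' when `left <= j < right`; an integer-valued edge therefore sits exactly
#' on the boundary between two pixels, at `j - 0.5`.
#'
#' @param kin a `glottal_kinematics` object from [simulate_kinematics()].
#' @param mode `"opaque"` or `"translucent"`.
#' @param size frame size `c(rows, cols)` in pixels, default `c(64, 128)`.
#' @param gray_levels named list: `background` (fold tissue, default 160),
#'   `glottis` (40), `membrane` (158), `rim` (100); 8-bit levels.
#' @param noise_sd additive Gaussian gray noise (sd, gray levels), clipped
#'   to `[0, 255]`.
#' @param membrane_px,rim_px translucent-mode band widths, pixels.
#' @param line_margin fraction of image height left above the first and
#'   below the last scan line.
#' @param pixel_scale mm per pixel recorded in the stack metadata.
#' @param seed optional integer seed for the noise.
#' @return A [frame_stack()] with `line_rows` set to the 0-based scan-line
#'   rows used for rendering.
#' @export
render_frames <- function(kin, mode = c("opaque", "translucent"),
                          size = c(64L, 128L),
                          gray_levels = list(background = 160, glottis = 40,
                                             membrane = 158, rim = 100),
                          noise_sd = 0, membrane_px = 6, rim_px = 2,
                          line_margin = 0.15, pixel_scale = 0.02,
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(kin, "glottal_kinematics"))
  rows <- as.integer(size[1]); cols <- as.integer(size[2])
  nl <- kin$profile$n_lines
  if (rows < 3L * nl)
    stop("invalid parameter: frame height too small for n_lines")
  g <- modify_defaults(list(background = 160, glottis = 40,
                            membrane = 158, rim = 100), gray_levels)
  if (mode == "opaque" && g$glottis >= g$background)
    stop("opaque mode requires glottis gray < fold gray")
  line_rows <- round(seq(line_margin * (rows - 1),
                         (1 - line_margin) * (rows - 1), length.out = nl))
  nf <- length(kin$times)
  span <- line_rows[1]:line_rows[nl]
  # pixel-center column index per (row-in-span, col)
  jmat <- matrix(0:(cols - 1), length(span), cols, byrow = TRUE)
  if (!is.null(seed)) set.seed(seed)
  px <- array(as.integer(round(g$background)), dim = c(rows, cols, nf))
  base <- matrix(g$background, rows, cols)
  for (f in seq_len(nf)) {
    L <- stats::approx(line_rows, kin$left_x[f, ], xout = span)$y
    R <- stats::approx(line_rows, kin$right_x[f, ], xout = span)$y
    fr <- base
    sub <- fr[span + 1L, , drop = FALSE]
    inside <- jmat >= L & jmat < R
    if (mode == "opaque") {
      sub[inside] <- g$glottis
    } else {
      sub[inside] <- g$glottis
      memb <- inside & (jmat < L + membrane_px | jmat >= R - membrane_px)
      sub[memb] <- g$membrane
      rim <- inside & (jmat < L + rim_px | jmat >= R - rim_px)
      sub[rim] <- g$rim
    }
    fr[span + 1L, ] <- sub
    if (noise_sd > 0)
      fr <- fr + stats::rnorm(length(fr), sd = noise_sd)
    px[, , f] <- as.integer(pmax(0, pmin(255, round(fr))))
  }
  frame_stack(px, fps = kin$profile$fps, pixel_scale = pixel_scale,
              t0 = kin$times[1], line_rows = line_rows)
}
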