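#' Rotate and crop a frame stack
#'
#' Rotates each frame about the image center (bilinear interpolation) so
#' the glottal midline is vertical, then crops to a row/column box. With
#' `rotation_deg = 0` and a full-frame box this is the identity.
#'
#' @param stack a [frame_stack()].
#' @param rotation_deg rotation angle, degrees counter-clockwise.
#' @param crop_box `list(rows = c(first, last), cols = c(first, last))`
#'   (1-based, inclusive) or `NULL` for no crop.
#' @return The preprocessed [frame_stack()] with updated metadata;
#'   `line_rows` are shifted by the row crop when present.
#' @export
preprocess <- function(stack, rotation_deg = 0, crop_box = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  px <- stack$pixels
  d <- dim(px)
  if (rotation_deg != 0) {
    px <- rotate_stack(px, rotation_deg, fill = stats::median(px))
  }
  line_rows <- stack$line_rows
  if (!is.null(crop_box)) {
    r <- crop_box$rows; cc <- crop_box$cols
    if (is.null(r)) r <- c(1L, d[1])
    if (is.null(cc)) cc <- c(1L, d[2])
    if (r[1] < 1L || r[2] > d[1] || cc[1] < 1L || cc[2] > d[2] ||
        r[1] > r[2] || cc[1] > cc[2])
      stop("invalid parameter: empty or out-of-bounds crop box")
    px <- px[r[1]:r[2], cc[1]:cc[2], , drop = FALSE]
    if (!is.null(line_rows)) {
      line_rows <- line_rows - (r[1] - 1L)
      line_rows <- line_rows[line_rows >= 0 & line_rows <= diff(r)]
    }
  }
  frame_stack(px, fps = stack$fps, pixel_scale = stack$pixel_scale,
              t0 = stack$t0,
              rotation_deg = stack$rotation_deg + rotation_deg,
              line_rows = line_rows)
}

# bilinear rotation of every frame about the image center, keeping the
# input geometry (inverse mapping; out-of-frame samples get `fill`)
rotate_stack <- function(px, angle_deg, fill = 0) {
  d <- dim(px)
  th <- angle_deg * pi / 180
  cr <- (d[1] + 1) / 2; cc <- (d[2] + 1) / 2
  rr <- matrix(seq_len(d[1]), d[1], d[2]) - cr
  ccm <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cc
  # inverse rotation of output coordinates into the input image
  sr <- cr + cos(th) * rr + sin(th) * ccm
  sc <- cc - sin(th) * rr + cos(th) * ccm
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  out <- array(fill, dim = d)
  get <- function(slice, r, c) {
    ok <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
    v <- rep(fill, length(r))
    v[ok] <- slice[cbind(r[ok], c[ok])]
    v
  }
  for (f in seq_len(d[3])) {
    sl <- px[, , f]
    v <- (1 - fr) * (1 - fc) * get(sl, r0, c0) +
         (1 - fr) * fc       * get(sl, r0, c0 + 1) +
         fr       * (1 - fc) * get(sl, r0 + 1, c0) +
         fr       * fc       * get(sl, r0 + 1, c0 + 1)
    out[, , f] <- v
  }
  out
}

#' Threshold segmentation of the glottis
#'
#' The glottis is defined as all pixels strictly below a manually set gray
#' threshold. The binary image is dilated with a 2-pixel line horizontally
#' and then vertically, holes are filled, and the largest connected
#' component is retained (ties broken toward the darker component). The
#' dilation enlarges the region by one pixel per direction; that margin is
#' deliberately not subtracted here - measure it with [dilation_margin()]
#' and correct widths explicitly if needed.
#'
#' @param frame numeric matrix of gray values (one video frame).
#' @param threshold gray threshold; pixels `< threshold` are glottis.
#' @return A `glottal_mask`: list with logical `mask`, `threshold_used`,
#'   and `closed` flag (`TRUE` when no pixel fell below the threshold).
#' @export
segment_glottis_threshold <- function(frame, threshold) {
  stopifnot(is.matrix(frame))
  if (threshold < 0 || threshold > 255)
    stop("invalid parameter: threshold outside gray range")
  bw <- frame < threshold
  if (!any(bw)) {
    return(structure(list(mask = bw, threshold_used = threshold,
                          closed = TRUE), class = "glottal_mask"))
  }
  bw <- dilate_line(bw, "horizontal")
  bw <- dilate_line(bw, "vertical")
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(t(bw * 1))))
  bw <- t(filled) > 0
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bw)))))
  nl <- max(lab)
  if (nl > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = nl)
    keep <- which(sizes == max(sizes))
    if (length(keep) > 1L) {
      darkness <- vapply(keep, function(k) mean(frame[lab == k]), numeric(1))
      keep <- keep[which.min(darkness)]
    }
    bw <- lab == keep[1]
  }
  structure(list(mask = bw, threshold_used = threshold, closed = FALSE),
            class = "glottal_mask")
}

# binary dilation by a 2-pixel line; the second structuring-element pixel
# extends the region by one pixel in +x (horizontal) or +y (vertical)
dilate_line <- function(bw, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  out <- bw
  if (direction == "horizontal") {
    out[, -1] <- out[, -1] | bw[, -ncol(bw)]
  } else {
    out[-1, ] <- out[-1, ] | bw[-nrow(bw), ]
  }
  out
}

# erosion by the same 2-pixel line: the exact adjoint of dilate_line, used
# to undo the dilation margin (including its slope-dependent vertical
# smear) before measuring widths
erode_line <- function(bw, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  out <- bw
  if (direction == "horizontal") {
    out[, -ncol(bw)] <- bw[, -ncol(bw)] & bw[, -1]
    out[, ncol(bw)] <- FALSE
  } else {
    out[-nrow(bw), ] <- bw[-nrow(bw), ] & bw[-1, ]
    out[nrow(bw), ] <- FALSE
  }
  out
}

#' Dilation margin of the threshold pipeline
#'
#' Measures, on a noiseless calibration fixture of known width, how many
#' pixels the dilate-and-fill sequence adds to a row width. With the
#' 2-pixel line elements used here the margin is 1 pixel; the function
#' exists so the number is measured, not assumed.
#'
#' @param width_px,height_px size of the calibration rectangle, px.
#' @return Margin in pixels (numeric).
#' @export
dilation_margin <- function(width_px = 20L, height_px = 10L) {
  fr <- matrix(200, height_px + 20L, width_px + 20L)
  fr[10L + seq_len(height_px), 10L + seq_len(width_px)] <- 30
  m <- segment_glottis_threshold(fr, 100)
  mid <- rowSums(m$mask)[10L + height_px %/% 2L]
  as.numeric(mid - width_px)
}

#' Suggest a gray threshold (Otsu)
#'
#' Automatic threshold suggestion for operator guidance. It is never
#' applied silently: the analysis always uses the threshold recorded in
#' the trial metadata.
#'
#' @param frame numeric matrix of gray values in `[0, 255]`.
#' @return Suggested threshold (gray level).
#' @export
suggest_threshold <- function(frame) {
  h <- tabulate(as.integer(frame) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # with an empty gray range between the two populations the criterion is
  # flat over the whole gap; suggest its midpoint
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  mean(range(best)) - 1
}

#' Glottal width profile of a mask
#'
#' Width per anterior-posterior row: the count of mask pixels in each image
#' row (row 0 anterior), scaled by the pixel size. The margin added by the
#' dilation step (see [dilation_margin()]) can be removed explicitly with
#' `margin_px`; rows that are zero stay zero.
#'
#' @param mask a `glottal_mask` from [segment_glottis_threshold()].
#' @param pixel_scale mm per pixel.
#' @param margin_px margin to subtract from non-empty rows (default 0).
#' @return Data frame with `row` (0-based AP index), `width_px`,
#'   `width_mm`.
#' @export
glottal_width_profile <- function(mask, pixel_scale = 1, margin_px = 0) {
  stopifnot(inherits(mask, "glottal_mask"))
  w <- rowSums(mask$mask)
  if (margin_px > 0) w <- ifelse(w > 0, pmax(0, w - margin_px), 0)
  data.frame(row = seq_along(w) - 1L, width_px = w,
             width_mm = w * pixel_scale)
}
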