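#' High-speed video frame stacks
#'
#' A `frame_stack` holds a grayscale high-speed video as an integer array
#' `rows x cols x frames` (gray levels 0-255) plus the acquisition metadata
#' the analysis needs: frame rate, spatial scale, the rotation already
#' applied to make the glottal midline vertical, and the trigger-relative
#' time of the first frame.
#'
#' @param pixels numeric array `rows x cols x frames` of gray values in
#'   `[0, 255]`; a single matrix is treated as a one-frame stack.
#' @param fps frame rate, frames per second.
#' @param pixel_scale spatial scale, mm per pixel.
#' @param t0 trigger-relative time of the first frame, seconds.
#' @param rotation_deg rotation (degrees, counter-clockwise) already applied
#'   to the pixel data.
#' @param line_rows optional integer vector of scan-line rows (0-based, used
#'   by [track_edges_scanlines()]).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(pixels, fps, pixel_scale = 1, t0 = 0,
                        rotation_deg = 0, line_rows = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("pixels must be a rows x cols x frames array")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (!is.numeric(pixel_scale) || pixel_scale <= 0)
    stop("pixel_scale must be positive")
  structure(list(pixels = pixels, fps = fps, pixel_scale = pixel_scale,
                 t0 = t0, rotation_deg = rotation_deg,
                 line_rows = line_rows),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px @ %g fps (%.4g s), %.4g mm/px\n",
    d[3], d[1], d[2], x$fps, d[3] / x$fps, x$pixel_scale))
  if (x$rotation_deg != 0)
    cat(sprintf("  rotation applied: %g deg\n", x$rotation_deg))
  invisible(x)
}

#' @rdname frame_stack
#' @param x a `frame_stack`.
#' @export
n_frames <- function(x) dim(x$pixels)[3]

#' @rdname frame_stack
#' @export
frame_times <- function(x) x$t0 + (seq_len(n_frames(x)) - 1) / x$fps

#' Read and write frame stacks as multi-page TIFF
#'
#' Frames are stored 8-bit grayscale. `write_frames()` is deterministic:
#' identical pixel data produces byte-identical files.
#'
#' @param stack a `frame_stack`.
#' @param path file path of a multi-page TIFF.
#' @return `read_frames()` returns the pixel array; metadata must come from
#'   the trial metadata JSON (see [load_trial()]).
#' @export
write_frames <- function(stack, path) {
  px <- stack$pixels
  frames <- lapply(seq_len(dim(px)[3]),
                   function(i) px[, , i, drop = TRUE] / 255)
  tiff::writeTIFF(frames, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    arr[, , i] <- as.integer(round(p * 255))
  }
  arr
}
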