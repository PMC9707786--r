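#' Scan-line edge tracking of the vocal membrane
#'
#' Deterministic replacement for learned pose estimation, honoring the
#' same output contract: left/right membrane-edge x-positions on 8 to 10
#' equidistant horizontal scan lines, fixed vertically to their line rows.
#' On each line and frame the two edges are located among the
#' opposite-signed local extrema of the (lightly smoothed) horizontal gray
#' gradient inside a tracking gate around the previous frame's positions.
#' Within the gate the *outermost* extremum exceeding the contrast floor
#' is taken (on the first frame the gate spans the whole line): the
#' membrane edge is by definition the outer boundary of the aperture, and
#' in translucent scenes the inner membrane-glottis transition is stronger
#' than the true edge and must not capture the track. Positions are
#' refined to subpixel precision by a parabolic fit; an integer-valued
#' edge between two pixels is reported at the half-integer boundary.
#' Lines without a qualifying extremum keep the predicted position with
#' confidence 0; a line losing contrast for more than `gate_frames`
#' consecutive frames is flagged as a gap.
#'
#' @param stack a preprocessed [frame_stack()].
#' @param n_lines number of scan lines (8-10); ignored when the stack
#'   already carries `line_rows`.
#' @param line_rows optional explicit 0-based scan-line rows.
#' @param gate_px half-width of the tracking gate, px.
#' @param smooth_px box-smoothing width applied to each line before the
#'   gradient, px (odd).
#' @param contrast_floor minimum gradient magnitude (gray units per px)
#'   for a confident detection.
#' @param conf_scale gradient magnitude mapped to confidence 1.
#' @param gate_frames consecutive low-confidence frames tolerated before a
#'   gap is flagged.
#' @return An `edge_tracks` object: `line_rows` (0-based), matrices
#'   `left_x`, `right_x`, `confidence` (`frames x n_lines`; subpixel,
#'   0-based pixel-center coordinates), logical `gap` matrix, `fps`,
#'   `t0`, `pixel_scale`.
#' @export
track_edges_scanlines <- function(stack, n_lines = 9L, line_rows = NULL,
                                  gate_px = 6, smooth_px = 3,
                                  contrast_floor = 8, conf_scale = 50,
                                  gate_frames = 3L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(line_rows)) line_rows <- stack$line_rows
  if (is.null(line_rows)) {
    if (n_lines < 8L || n_lines > 10L)
      stop("invalid parameter: n_lines must be 8..10")
    d <- dim(stack$pixels)
    line_rows <- round(seq(0.15 * (d[1] - 1), 0.85 * (d[1] - 1),
                           length.out = n_lines))
  }
  n_lines <- length(line_rows)
  px <- stack$pixels
  nf <- dim(px)[3]; ncols <- dim(px)[2]
  left <- right <- conf <- matrix(NA_real_, nf, n_lines)
  lost <- integer(n_lines)
  gap <- matrix(FALSE, nf, n_lines)
  ker <- rep(1 / smooth_px, smooth_px)
  for (l in seq_len(n_lines)) {
    row <- line_rows[l] + 1L
    prevL <- prevR <- NA_real_
    for (f in seq_len(nf)) {
      prof <- as.numeric(px[row, , f])
      sm <- stats::filter(prof, ker, sides = 2)
      # candidates come from the smoothed gradient (noise robustness);
      # subpixel refinement uses the raw gradient, which localizes narrow
      # features (the translucent rim) without the smoothing bias
      g <- c(NA, diff(sm, lag = 2) / 2, NA)
      gr <- c(NA, diff(prof, lag = 2) / 2, NA)
      if (is.na(prevL) || is.na(prevR)) {
        hit <- scan_outermost(g, gr, contrast_floor)
      } else {
        hit <- scan_gated(g, gr, prevL, prevR, gate_px, contrast_floor)
      }
      if (!any(is.na(hit[1:2]))) {
        prevL <- hit[1]; prevR <- hit[2]
        left[f, l] <- hit[1]; right[f, l] <- hit[2]
        conf[f, l] <- min(1, hit[3] / conf_scale)
        lost[l] <- 0L
      } else {
        # keep the prediction; flag once the track has been lost too long
        left[f, l] <- prevL; right[f, l] <- prevR
        conf[f, l] <- 0
        lost[l] <- lost[l] + 1L
        if (lost[l] > gate_frames) gap[f, l] <- TRUE
      }
    }
  }
  structure(list(line_rows = line_rows, left_x = left, right_x = right,
                 confidence = conf, gap = gap, fps = stack$fps,
                 t0 = stack$t0, pixel_scale = stack$pixel_scale),
            class = "edge_tracks")
}

# The membrane edge is the *outer* boundary of the aperture: within any
# search window the edge is the outermost local gradient extremum of the
# correct sign exceeding the contrast floor, never simply the strongest -
# in translucent scenes the inner membrane-glottis transition is stronger
# than the true outer edge and must not capture the track.

# local minima (most negative) / maxima of g inside a 1-based index window
local_extrema <- function(g, win, minimum = TRUE) {
  s <- if (minimum) g else -g
  i <- win[win >= 2L & win <= length(g) - 1L]
  i <- i[!is.na(s[i]) & !is.na(s[i - 1L]) & !is.na(s[i + 1L])]
  i[s[i] <= s[i - 1L] & s[i] <= s[i + 1L]]
}

# full-line scan used when no prior position exists:
# outermost opposite-signed extrema above the floor.
# Returns c(left, right, min_gradient_magnitude), 0-based, or NAs.
scan_outermost <- function(g, gr, floor_) {
  n <- length(g)
  neg <- local_extrema(g, seq_len(n), minimum = TRUE)
  neg <- neg[g[neg] <= -floor_]
  pos <- local_extrema(g, seq_len(n), minimum = FALSE)
  pos <- pos[g[pos] >= floor_]
  if (!length(neg) || !length(pos)) return(c(NA, NA, NA))
  li <- neg[1]; ri <- pos[length(pos)]
  if (li >= ri) return(c(NA, NA, NA))
  c(refine_extremum(gr, li, minimum = TRUE),
    refine_extremum(gr, ri, minimum = FALSE),
    min(abs(g[li]), abs(g[ri])))
}

# gated scan around the previous frame's positions: outermost qualifying
# extremum inside each gate window
scan_gated <- function(g, gr, prevL, prevR, gate, floor_) {
  n <- length(g)
  winL <- max(1L, round(prevL) + 1L - gate):min(n, round(prevL) + 1L + gate)
  winR <- max(1L, round(prevR) + 1L - gate):min(n, round(prevR) + 1L + gate)
  neg <- local_extrema(g, winL, minimum = TRUE)
  neg <- neg[g[neg] <= -floor_]
  pos <- local_extrema(g, winR, minimum = FALSE)
  pos <- pos[g[pos] >= floor_]
  if (!length(neg) || !length(pos)) return(c(NA, NA, NA))
  li <- neg[1]; ri <- pos[length(pos)]
  c(refine_extremum(gr, li, minimum = TRUE),
    refine_extremum(gr, ri, minimum = FALSE),
    min(abs(g[li]), abs(g[ri])))
}

# parabolic subpixel refinement of a gradient extremum near 1-based index
# i (re-centered on the raw gradient's own extremum within one pixel);
# returns a 0-based coordinate
refine_extremum <- function(g, i, minimum = TRUE) {
  n <- length(g)
  s <- if (minimum) g else -g
  nb <- max(2L, i - 1L):min(n - 1L, i + 1L)
  nb <- nb[!is.na(s[nb])]
  if (length(nb)) i <- nb[which.min(s[nb])]
  if (i <= 1L || i >= n || is.na(s[i - 1L]) || is.na(s[i + 1L]))
    return(i - 1)
  a <- s[i - 1L]; b <- s[i]; cc <- s[i + 1L]
  den <- a - 2 * b + cc
  off <- if (abs(den) < 1e-12) 0 else 0.5 * (a - cc) / den
  (i - 1) + max(-0.5, min(0.5, off))
}

#' @export
print.edge_tracks <- function(x, ...) {
  cat(sprintf(
    "<edge_tracks> %d frames x %d lines (rows %s), mean confidence %.2f\n",
    nrow(x$left_x), length(x$line_rows),
    paste(x$line_rows, collapse = ","), mean(x$confidence, na.rm = TRUE)))
  invisible(x)
}

#' Import externally produced edge coordinates
#'
#' Adapter for edge detections produced outside the package (e.g. by a
#' learned pose estimator): a CSV with columns `frame`, `line_row`,
#' `left_x`, `right_x` and optional `confidence` is converted to the same
#' `edge_tracks` structure returned by [track_edges_scanlines()].
#'
#' @param path CSV file path.
#' @param fps,t0,pixel_scale acquisition metadata of the source video.
#' @return An `edge_tracks` object.
#' @export
edge_tracks_from_csv <- function(path, fps, t0 = 0, pixel_scale = 1) {
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("frame", "line_row", "left_x", "right_x")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("edge CSV missing column(s): ", paste(miss, collapse = ", "))
  if (!"confidence" %in% names(d)) d$confidence <- 1
  rows <- sort(unique(d$line_row))
  frames <- sort(unique(d$frame))
  idx <- function(v, u) match(v, u)
  left <- right <- conf <- matrix(NA_real_, length(frames), length(rows))
  ij <- cbind(idx(d$frame, frames), idx(d$line_row, rows))
  left[ij] <- d$left_x; right[ij] <- d$right_x; conf[ij] <- d$confidence
  structure(list(line_rows = rows, left_x = left, right_x = right,
                 confidence = conf,
                 gap = matrix(FALSE, length(frames), length(rows)),
                 fps = fps, t0 = t0, pixel_scale = pixel_scale),
            class = "edge_tracks")
}

#' Write edge tracks to CSV
#'
#' Long-format CSV (`frame`, `line_row`, `left_x`, `right_x`,
#' `confidence`), the inverse of [edge_tracks_from_csv()].
#'
#' @param tracks an `edge_tracks` object.
#' @param path output file.
#' @export
write_edge_tracks <- function(tracks, path) {
  nf <- nrow(tracks$left_x); nl <- length(tracks$line_rows)
  d <- data.frame(
    frame = rep(seq_len(nf), nl),
    line_row = rep(tracks$line_rows, each = nf),
    left_x = as.vector(tracks$left_x),
    right_x = as.vector(tracks$right_x),
    confidence = as.vector(tracks$confidence))
  data.table::fwrite(d, path)
  invisible(path)
}
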