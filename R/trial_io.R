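#' Load a trial bundle from disk
#'
#' A trial is one directory holding a metadata JSON plus the video, sound
#' and pressure files it names (the layout written by [make_trial()]).
#' Metadata is validated on load: missing required fields and
#' inconsistent sampling rates raise schema errors naming the offending
#' field, because silent desynchronization is the main hazard in
#' multimodal pipelines.
#'
#' @param path trial directory.
#' @return A `trial_bundle`: `trial_id`, `metadata`, `frames`
#'   ([frame_stack()]), `sound`, `pressure` (traces), `truth` (list, when
#'   a truth JSON is present), `path`.
#' @export
load_trial <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop("schema error: no metadata.json in ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("fps", "fs_sound", "fs_pressure", "pixel_scale",
                "gray_threshold", "rotation_deg", "t0")
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("schema error: metadata missing field(s) ",
         paste(sprintf('"%s"', miss), collapse = ", "))
  num <- c("fps", "fs_sound", "fs_pressure", "pixel_scale")
  for (f in num) if (!is.numeric(meta[[f]]) || meta[[f]] <= 0)
    stop(sprintf('schema error: field "%s" must be a positive number', f))
  if (abs(meta$fs_sound - meta$fs_pressure) > 1e-9)
    stop(sprintf(
      'schema error: "fs_sound" (%g) and "fs_pressure" (%g) differ',
      meta$fs_sound, meta$fs_pressure))
  files <- list(frames = "frames.tif", sound = "sound.csv",
                pressure = "pressure.csv")
  for (f in names(files)) {
    if (!file.exists(file.path(path, files[[f]])))
      stop("schema error: missing trial file ", files[[f]])
  }
  px <- read_frames(file.path(path, "frames.tif"))
  frames <- frame_stack(px, fps = meta$fps, pixel_scale = meta$pixel_scale,
                        t0 = meta$t0, rotation_deg = 0,
                        line_rows = if (!is.null(meta$line_rows))
                          as.integer(meta$line_rows) else NULL)
  snd <- data.table::fread(file.path(path, "sound.csv"), data.table = FALSE)
  sound <- sound_trace(snd$sound_pa, fs = meta$fs_sound,
                       t0 = snd$time_s[1])
  prs <- data.table::fread(file.path(path, "pressure.csv"),
                           data.table = FALSE)
  pressure <- pressure_trace(prs$pressure_kpa, fs = meta$fs_pressure,
                             t0 = prs$time_s[1])
  truth <- NULL
  if (file.exists(file.path(path, "truth.json")))
    truth <- jsonlite::read_json(file.path(path, "truth.json"),
                                 simplifyVector = TRUE)
  structure(list(trial_id = if (!is.null(meta$trial_id)) meta$trial_id
                            else basename(path),
                 metadata = meta, frames = frames, sound = sound,
                 pressure = pressure, truth = truth, path = path),
            class = "trial_bundle")
}

#' Run the full analysis pipeline on one trial
#'
#' Segmentation (gray threshold in `"ventricular"` mode, scan-line edge
#' tracking in `"membrane"` mode) -> glottovibrogram -> opening waveform
#' at the AP position of maximal mean opening -> vibration f0 (yin, hop 10
#' frames) -> sound resampled to the frame rate and analyzed with the
#' engine chosen by [select_engine()] -> identity regression of sound f0
#' on vibration f0 -> phonation threshold pressure at the 0.2 mPa sound
#' onset. Any stage failure is re-raised with the stage name and trial id.
#' Every numeric parameter influencing a result is recorded in the
#' provenance log of the report.
#'
#' @param bundle a `trial_bundle` from [load_trial()] (a
#'   `synthetic_trial` from [make_trial()] is also accepted).
#' @param mode `"ventricular"` (threshold path) or `"membrane"` (edge
#'   tracking path).
#' @param params named list of stage-parameter overrides; see the
#'   provenance log of a default run for the available names.
#' @return A `glottal_report`: `gvg`, `vib_track`, `sound_track`,
#'   `regression` (or `NULL` with `$regression_note` when not estimable),
#'   `onset` (`onset_result`), `ap_index`, `engine`, `provenance`,
#'   `trial_id`.
#' @export
run_pipeline <- function(bundle, mode = c("ventricular", "membrane"),
                         params = list()) {
  mode <- match.arg(mode)
  if (inherits(bundle, "synthetic_trial")) {
    meta <- list(trial_id = bundle$recipe$name,
                 gray_threshold = bundle$recipe$gray_threshold,
                 rotation_deg = 0,
                 expected_f0_range = bundle$recipe$expected_f0_range,
                 n_lines = bundle$recipe$n_lines)
    bundle <- list(trial_id = bundle$recipe$name, metadata = meta,
                   frames = bundle$frames, sound = bundle$sound,
                   pressure = bundle$pressure, truth = bundle$truth)
  }
  meta <- bundle$metadata
  trial_id <- bundle$trial_id
  p <- modify_defaults(list(
    crop_box = NULL, margin_correct = "erode", yin_window = NULL,
    yin_hop = 10L,
    ap_threshold = 0.1, power_floor_vib = 0, power_floor_sound = 0,
    onset_threshold_pa = 2e-4, power_window_s = 1e-3, hold_s = 2e-3,
    lp_cutoff_hz = 500, lp_order = 6L, gate_px = 6, smooth_px = 3,
    contrast_floor = 8, ridge_penalty = 0.5, ridge_nfft = 2048L), params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for trial '%s': %s",
                   name, trial_id, conditionMessage(e)), call. = FALSE))
  }
  stack <- stage("preprocess",
    preprocess(bundle$frames, rotation_deg = -meta$rotation_deg,
               crop_box = p$crop_box))
  gvg <- if (mode == "ventricular") {
    stage("segmentation",
      gvg_from_threshold(stack, meta$gray_threshold,
                         margin_correct = p$margin_correct))
  } else {
    stage("segmentation", {
      tracks <- track_edges_scanlines(
        stack, n_lines = if (!is.null(meta$n_lines)) meta$n_lines else 9L,
        gate_px = p$gate_px, smooth_px = p$smooth_px,
        contrast_floor = p$contrast_floor)
      build_gvg(tracks)
    })
  }
  ap_index <- stage("gvg", max_opening_position(gvg))
  wave <- stage("gvg", opening_waveform(gvg, ap_index, demean = TRUE))
  fps <- stack$fps
  rng <- meta$expected_f0_range
  if (is.null(rng)) rng <- c(fps / 100, fps / 4)
  if (is.null(p$yin_window)) {
    p$yin_window <- max(32L, as.integer(2^ceiling(log2(4 * fps / rng[1]))))
  }
  vib <- stage("vibration f0",
    yin_f0(wave, fs = fps, window = p$yin_window, hop = p$yin_hop,
           ap_threshold = p$ap_threshold,
           power_floor = p$power_floor_vib))
  engine <- select_engine(rng, fps)
  sound_track <- stage("sound f0", {
    snd_win <- trace_window(bundle$sound, stack$t0,
                            stack$t0 + n_frames(stack) / fps)
    if (engine == "yin") {
      s_res <- resample_to_framerate(snd_win, fps = fps)
      yin_f0(s_res, fs = fps, window = p$yin_window, hop = p$yin_hop,
             ap_threshold = p$ap_threshold,
             power_floor = p$power_floor_sound)
    } else {
      ridge_f0(snd_win, nfft = p$ridge_nfft, penalty = p$ridge_penalty,
               fmin = rng[1] / 2, fmax = min(trace_fs(snd_win) / 2,
                                             rng[2] * 1.5),
               power_floor = p$power_floor_sound)
    }
  })
  regression <- NULL; regression_note <- NULL
  reg_try <- try(identity_regression(vib, sound_track), silent = TRUE)
  if (inherits(reg_try, "try-error")) {
    regression_note <- attr(reg_try, "condition")$message
  } else regression <- reg_try
  onset <- stage("onset",
    compute_ptp(bundle$pressure, bundle$sound,
                threshold = p$onset_threshold_pa,
                power_window_s = p$power_window_s, hold_s = p$hold_s,
                cutoff_hz = p$lp_cutoff_hz, order = p$lp_order))
  provenance <- c(list(trial_id = trial_id, mode = mode, engine = engine,
                       fps = fps, gray_threshold = meta$gray_threshold,
                       rotation_deg = meta$rotation_deg,
                       ap_index = ap_index,
                       expected_f0_range = rng),
                  p[!vapply(p, is.null, logical(1))])
  structure(list(gvg = gvg, vib_track = vib, sound_track = sound_track,
                 regression = regression,
                 regression_note = regression_note, onset = onset,
                 ap_index = ap_index, engine = engine,
                 provenance = provenance, trial_id = trial_id),
            class = "glottal_report")
}

#' @export
print.glottal_report <- function(x, ...) {
  cat(sprintf("<glottal_report> trial '%s' (engine %s)\n",
              x$trial_id, x$engine))
  print(x$gvg)
  print(x$vib_track)
  if (!is.null(x$regression)) print(x$regression)
  else if (!is.null(x$regression_note))
    cat("  regression not estimated:", x$regression_note, "\n")
  print(x$onset)
  invisible(x)
}

#' One-row summary of a trial report
#'
#' @param object a `glottal_report`.
#' @param ... unused.
#' @return Data frame with `trial_id`, `ptp_kpa`, `s_ptp_kpa_s`,
#'   `onset_s`, `detected`, `f0_vib_median_hz`, `slope`, `r_squared`.
#' @export
summary.glottal_report <- function(object, ...) {
  v <- object$vib_track
  data.frame(
    trial_id = object$trial_id,
    ptp_kpa = object$onset$ptp,
    s_ptp_kpa_s = object$onset$s_ptp,
    onset_s = object$onset$onset_time,
    detected = object$onset$detected,
    f0_vib_median_hz = if (any(v$valid))
      stats::median(v$f0[v$valid]) else NA_real_,
    slope = if (!is.null(object$regression))
      object$regression$slope else NA_real_,
    r_squared = if (!is.null(object$regression))
      object$regression$r_squared else NA_real_)
}
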