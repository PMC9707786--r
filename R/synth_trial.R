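#' Built-in synthetic trial recipes
#'
#' Recipes bundle a pressure protocol, kinematic profile, rendering mode
#' and acoustic settings into reproducible study conditions:
#'
#' * `"ventricular-slow"` - ventricular-fold-like trial: slow 0-6 kPa ramp
#'   at 1 kPa/s, threshold 4 kPa, opaque rendering at 20,000 fps, f0
#'   sweeping 1.8-2.3 kHz after onset (the f0 rise that accompanies the
#'   still-increasing driving pressure).
#' * `"membrane-fast"` - vocal-membrane-like trial: four fast 300 ms
#'   pressure pulses between 0 and 4 kPa, threshold 3.2 kPa with a
#'   50 kPa/s rate gate, translucent rendering at 125,000 fps, f0 sweeping
#'   13.5-16.5 kHz.
#' * `"membrane-fast-opaque"` - as `"membrane-fast"` but rendered opaque
#'   (for cross-validating the two segmentation paths at high f0).
#' * `"membrane-slow"` - the same larynx driven by the slow 1 kPa/s ramp:
#'   the 50 kPa/s rate gate is never satisfied, the membranes never
#'   oscillate and the trial contains no phonation onset.
#'
#' @param name recipe name.
#' @param ... named overrides of any recipe field.
#' @return A `trial_recipe` (named list).
#' @export
trial_recipe <- function(name = c("ventricular-slow", "membrane-fast",
                                  "membrane-fast-opaque", "membrane-slow"),
                         ...) {
  name <- match.arg(name)
  base <- list(
    name = name, fs = 250000, pixel_scale = 0.02, video_s = 0.1,
    pre_trigger_s = 0.005, n_lines = 9L, size = c(48L, 96L),
    amplitude_px = 12, center_x = 48, noise_sd = 2,
    gray_threshold = 100, amp_peak = 0.02, amp_rise_s = 0.05,
    n_harmonics = 3L, sound_noise_sd = 2e-5)
  spec <- switch(name,
    "ventricular-slow" = list(
      protocol = "slow_ramp", protocol_params = list(),
      ptp_true = 4, rate_gate = NULL, fps = 20000,
      f0 = f0_profile("sweep", from = 1800, to = 2300, span_s = 0.08),
      mode = "opaque", expected_f0_range = c(1500, 3000)),
    "membrane-fast" = list(
      protocol = "fast_pulses", protocol_params = list(),
      ptp_true = 3.2, rate_gate = 50, fps = 125000, video_s = 0.05,
      f0 = f0_profile("sweep", from = 13500, to = 16500, span_s = 0.04),
      mode = "translucent", expected_f0_range = c(10000, 20000)),
    "membrane-fast-opaque" = list(
      protocol = "fast_pulses", protocol_params = list(),
      ptp_true = 3.2, rate_gate = 50, fps = 125000, video_s = 0.05,
      f0 = f0_profile("sweep", from = 13500, to = 16500, span_s = 0.04),
      mode = "opaque", expected_f0_range = c(10000, 20000)),
    "membrane-slow" = list(
      protocol = "slow_ramp", protocol_params = list(),
      ptp_true = 3.2, rate_gate = 50, fps = 125000, video_s = 0.02,
      f0 = f0_profile("sweep", from = 13500, to = 16500, span_s = 0.04),
      mode = "translucent", expected_f0_range = c(10000, 20000)))
  rec <- utils::modifyList(c(base, spec), list(...))
  structure(rec, class = "trial_recipe")
}

#' Generate a complete synthetic trial
#'
#' Produces a fully synchronized bundle - high-speed video, calibrated
#' sound, bronchial pressure and a ground-truth record - under the study
#' conditions of a [trial_recipe()]. The pressure protocol is generated
#' first; the two-condition onset rule determines the phonation episodes;
#' sound and kinematics integrate the same f0 profile from the same onset,
#' so vibration and sound share their fundamental by construction. The
#' camera is "triggered" `pre_trigger_s` before phonation onset (or at the
#' trial midpoint when the recipe never phonates). Deterministic: the same
#' `(recipe, seed)` produces identical trials, and identical files when
#' `out_dir` is given.
#'
#' @param recipe a [trial_recipe()] (or recipe name).
#' @param seed integer seed for all stochastic components.
#' @param out_dir optional directory; when given, the trial is written as
#'   `frames.tif` (8-bit multi-page), `sound.csv` (`time_s`, `sound_pa`),
#'   `pressure.csv` (`time_s`, `pressure_kpa`), `metadata.json`,
#'   `truth.json` and `truth_edges.csv`.
#' @return A `synthetic_trial`: list with `frames` ([frame_stack()]),
#'   `sound`, `pressure` (traces), `kinematics`, `truth` (onset time /
#'   pressure / pressure speed, per-frame f0, recipe echo), and `paths`
#'   when written.
#' @export
make_trial <- function(recipe, seed = 1L, out_dir = NULL) {
  if (is.character(recipe)) recipe <- trial_recipe(recipe)
  stopifnot(inherits(recipe, "trial_recipe"))
  set.seed(seed)
  pressure <- generate_pressure(recipe$protocol, recipe$protocol_params,
                                fs = recipe$fs)
  eps <- phonation_intervals(pressure, recipe$ptp_true, recipe$rate_gate)
  duration <- length(pressure) / recipe$fs
  pfun <- stats::approxfun(trace_times(pressure), as.numeric(pressure),
                           rule = 2)
  sound <- synthesize_sound(recipe$f0, eps, fs = recipe$fs,
                            duration = duration,
                            amp_peak = recipe$amp_peak,
                            amp_rise_s = recipe$amp_rise_s,
                            n_harmonics = recipe$n_harmonics,
                            noise_sd = recipe$sound_noise_sd,
                            pressure_fun = pfun, seed = seed + 1L)
  t_start <- if (nrow(eps)) max(0, eps$start[1] - recipe$pre_trigger_s)
             else max(0, duration / 2 - recipe$video_s / 2)
  video_s <- min(recipe$video_s, duration - t_start)
  prof <- kinematic_profile(duration = video_s, fps = recipe$fps,
                            f0 = recipe$f0,
                            amplitude_px = recipe$amplitude_px,
                            n_lines = recipe$n_lines,
                            center_x = recipe$center_x)
  kin <- simulate_kinematics(prof, pressure, recipe$ptp_true,
                             recipe$rate_gate, t_start = t_start)
  frames <- render_frames(kin, mode = recipe$mode, size = recipe$size,
                          noise_sd = recipe$noise_sd,
                          pixel_scale = recipe$pixel_scale,
                          seed = seed + 2L)
  truth <- c(kin$truth, list(
    f0_hz = kin$f0_hz, frame_times = kin$times,
    phonating = kin$phonating,
    episodes = eps,
    onset_pressure_speed_protocol =
      attr(pressure, "protocol")$rise_rate_kpa_s,
    recipe_name = recipe$name, seed = seed))
  trial <- structure(list(frames = frames, sound = sound,
                          pressure = pressure, kinematics = kin,
                          truth = truth, recipe = recipe),
                     class = "synthetic_trial")
  if (!is.null(out_dir)) trial$paths <- write_trial(trial, out_dir)
  trial
}

write_trial <- function(trial, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec <- trial$recipe
  paths <- list(
    frames = file.path(out_dir, "frames.tif"),
    sound = file.path(out_dir, "sound.csv"),
    pressure = file.path(out_dir, "pressure.csv"),
    metadata = file.path(out_dir, "metadata.json"),
    truth = file.path(out_dir, "truth.json"),
    truth_edges = file.path(out_dir, "truth_edges.csv"))
  write_frames(trial$frames, paths$frames)
  data.table::fwrite(data.frame(time_s = trace_times(trial$sound),
                                sound_pa = as.numeric(trial$sound)),
                     paths$sound)
  data.table::fwrite(data.frame(time_s = trace_times(trial$pressure),
                                pressure_kpa = as.numeric(trial$pressure)),
                     paths$pressure)
  meta <- list(trial_id = basename(out_dir), fps = rec$fps,
               fs_sound = rec$fs, fs_pressure = rec$fs,
               pixel_scale = rec$pixel_scale,
               gray_threshold = rec$gray_threshold, rotation_deg = 0,
               t0 = trial$frames$t0, mode = rec$mode,
               n_lines = rec$n_lines,
               line_rows = trial$frames$line_rows,
               expected_f0_range = rec$expected_f0_range,
               recipe_name = rec$name)
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  tr <- trial$truth
  jsonlite::write_json(
    list(onset_time = tr$onset_time, onset_pressure = tr$onset_pressure,
         onset_pressure_speed = tr$onset_pressure_speed,
         ptp_true = tr$ptp_true, rate_gate = tr$rate_gate,
         recipe_name = tr$recipe_name, seed = tr$seed),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  kin <- trial$kinematics
  nl <- ncol(kin$left_x)
  edges <- data.frame(
    frame = rep(seq_len(nrow(kin$left_x)), nl),
    line_row = rep(trial$frames$line_rows, each = nrow(kin$left_x)),
    left_x = as.vector(kin$left_x), right_x = as.vector(kin$right_x))
  data.table::fwrite(edges, paths$truth_edges)
  paths
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> recipe %s (seed %d)\n",
              x$recipe$name, x$truth$seed))
  print(x$frames)
  if (is.na(x$truth$onset_time)) {
    cat("  no phonation onset (gate never satisfied)\n")
  } else {
    cat(sprintf("  onset %.4f s at %.3f kPa, %.3g kPa/s\n",
                x$truth$onset_time, x$truth$onset_pressure,
                x$truth$onset_pressure_speed))
  }
  invisible(x)
}
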