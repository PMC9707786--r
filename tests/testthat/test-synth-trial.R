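test_that("identical recipe and seed produce byte-identical trial files", {
  rec <- trial_recipe("ventricular-slow", video_s = 0.01)
  d1 <- file.path(tempdir(), "det-a", "trial")
  d2 <- file.path(tempdir(), "det-b", "trial")
  t1 <- make_trial(rec, seed = 5, out_dir = d1)
  t2 <- make_trial(rec, seed = 5, out_dir = d2)
  for (k in names(t1$paths)) {
    expect_identical(readBin(t1$paths[[k]], "raw", 2e8),
                     readBin(t2$paths[[k]], "raw", 2e8),
                     label = sprintf("file %s", k))
  }
  unlink(c(dirname(d1), dirname(d2)), recursive = TRUE)
})

test_that("trial truth is synchronized across modalities", {
  tr <- make_trial(trial_recipe("ventricular-slow", video_s = 0.01),
                   seed = 3)
  expect_equal(trace_fs(tr$sound), trace_fs(tr$pressure))
  expect_equal(tr$truth$onset_pressure, 4, tolerance = 1e-3)
  expect_equal(tr$truth$onset_time, tr$truth$episodes$start[1])
  # camera triggered just before onset; onset inside the video window
  ft <- frame_times(tr$frames)
  expect_true(tr$truth$onset_time >= ft[1] &&
              tr$truth$onset_time <= ft[length(ft)])
  # acoustic/kinematic lock: during phonation the sound fundamental and
  # the opening waveform agree to within one cycle per 10 ms window
  kin <- tr$kinematics
  w <- kin$right_x[, 5] - kin$left_x[, 5]
  phon <- which(kin$phonating)
  wd <- w - mean(w[phon])
  zc_w <- sum(wd[phon][-1] >= 0 & wd[phon][-length(phon)] < 0)
  snd <- trace_window(tr$sound, kin$times[phon[1]],
                      kin$times[phon[length(phon)]])
  zc_s_t <- yin_f0(snd, window = 1024, hop = 512)
  dur <- length(phon) / tr$frames$fps
  cycles_sound <- mean(zc_s_t$f0[zc_s_t$valid]) * dur
  # one cycle per 10 ms window, plus one for endpoint quantization
  expect_lt(abs(zc_w - cycles_sound), 1 + dur / 0.01)
})

test_that("the rate-gated recipe under a slow ramp never phonates", {
  tr <- make_trial("membrane-slow", seed = 2)
  expect_true(is.na(tr$truth$onset_time))
  expect_equal(nrow(tr$truth$episodes), 0L)
  expect_true(is.na(detect_sound_onset(tr$sound)))
})

test_that("trial bundles survive a disk round trip", {
  d <- file.path(tempdir(), "roundtrip", "trial")
  tr <- make_trial(trial_recipe("ventricular-slow", video_s = 0.01),
                   seed = 5, out_dir = d)
  b <- load_trial(d)
  expect_identical(b$frames$pixels, tr$frames$pixels)
  expect_equal(as.numeric(b$sound), as.numeric(tr$sound),
               tolerance = 1e-12)
  expect_equal(b$metadata$gray_threshold, 100)
  expect_equal(b$truth$ptp_true, 4)
  unlink(dirname(d), recursive = TRUE)
})
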