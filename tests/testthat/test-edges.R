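test_that("edge tracks match truth within 0.5 px on noiseless opaque video", {
  kin <- small_kinematics()
  fr <- small_opaque_stack()
  et <- track_edges_scanlines(fr)
  open <- open_frames(kin, min_width = 6)
  eL <- abs(et$left_x - kin$left_x)[open]
  eR <- abs(et$right_x - kin$right_x)[open]
  expect_lte(max(eL, eR), 0.5)
})

test_that("threshold and edge paths agree on opaque fixtures", {
  kin <- small_kinematics()
  fr <- small_opaque_stack()
  et <- track_edges_scanlines(fr)
  g_thr <- gvg_from_threshold(fr, 100)
  w_thr <- g_thr$width_px[, et$line_rows + 1L]
  w_edg <- et$right_x - et$left_x
  open <- open_frames(kin, min_width = 6)
  expect_lte(max(abs(w_thr - w_edg)[open]), 1.5)
})

test_that("edge tracking recovers translucent membranes where thresholding fails", {
  kin <- small_kinematics()
  fr <- small_translucent_stack()
  et <- track_edges_scanlines(fr)
  open <- open_frames(kin)                 # aperture clear of the bands
  true_w <- (kin$right_x - kin$left_x)
  edge_w <- et$right_x - et$left_x
  g_thr <- gvg_from_threshold(fr, 70)
  thr_w <- g_thr$width_px[, et$line_rows + 1L]
  # threshold under-reports systematically ...
  expect_lt(mean(thr_w[open]), 0.7 * mean(true_w[open]))
  # ... while the tracker stays within a pixel of the truth
  expect_lte(mean(abs(edge_w - true_w)[open]), 1)
  eL <- abs(et$left_x - kin$left_x)[open]
  eR <- abs(et$right_x - kin$right_x)[open]
  expect_lte(mean(c(eL, eR)), 1)
})

test_that("static closed-glottis frames give constant tracks", {
  prof <- kinematic_profile(duration = 1e-3, fps = 20000, f0 = 2000,
                            center_x = 48)
  pr <- pressure_trace(rep(0, 500), fs = 250000)
  kin <- simulate_kinematics(prof, pr, ptp_true = 4)   # never opens
  fr <- render_frames(kin, "opaque", size = c(48L, 96L))
  et <- track_edges_scanlines(fr)
  expect_equal(max(apply(et$left_x, 2, stats::var)), 0)
  expect_equal(max(apply(et$right_x, 2, stats::var)), 0)
})

test_that("edge-track CSV export and import round-trip", {
  fr <- small_opaque_stack()
  et <- track_edges_scanlines(fr)
  f <- tempfile(fileext = ".csv")
  write_edge_tracks(et, f)
  et2 <- edge_tracks_from_csv(f, fps = fr$fps, t0 = fr$t0,
                              pixel_scale = fr$pixel_scale)
  expect_equal(et2$left_x, et$left_x, tolerance = 1e-9)
  expect_equal(et2$right_x, et$right_x, tolerance = 1e-9)
  expect_equal(et2$line_rows, et$line_rows)
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("frame,foo", "1,2"), f2)
  expect_error(edge_tracks_from_csv(f2, fps = 1), "missing column")
  unlink(c(f, f2))
})
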