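test_that("a constant opening yields a constant glottovibrogram", {
  w <- matrix(10, 200, 9)
  g <- build_gvg(w, fps = 20000, pixel_scale = 0.02)
  expect_true(all(g$width == 0.2))
  expect_equal(diff(g$times), rep(1 / 20000, 199))
  wave <- opening_waveform(g, 1)
  expect_equal(as.numeric(wave), rep(0.2, 200))
  expect_equal(as.numeric(opening_waveform(g, 1, demean = TRUE)),
               rep(0, 200))
})

test_that("column-wise dominant frequency matches the generator", {
  kin <- small_kinematics()
  fr <- small_opaque_stack()
  g <- gvg_from_threshold(fr, 100)
  for (j in fr$line_rows + 1L) {
    col <- g$width_px[, j] - mean(g$width_px[, j])
    sp <- Mod(fft(col))[2:(length(col) %/% 2)]
    fdom <- which.max(sp) * g$fps / length(col)
    expect_lt(abs(fdom - 2000), g$fps / length(col) + 1e-9)
  }
  # both paths agree in dominant frequency to within one FFT bin
  et <- track_edges_scanlines(fr)
  g2 <- build_gvg(et)
  col2 <- g2$width_px[, 5] - mean(g2$width_px[, 5])
  sp2 <- Mod(fft(col2))[2:(length(col2) %/% 2)]
  expect_equal(which.max(sp2), which.max(
    Mod(fft(g$width_px[, et$line_rows[5] + 1] -
            mean(g$width_px[, et$line_rows[5] + 1])))[2:(nrow(g$width) %/% 2)]))
})

test_that("short edge-track dropouts are interpolated and counted", {
  w <- matrix(rep(sin(2 * pi * (1:100) / 10) + 2, 9), 100, 9)
  w[41:42, 3] <- NA
  g <- build_gvg(w, fps = 1000)
  expect_equal(g$n_interpolated, 2L)
  expect_false(anyNA(g$width))
  # interpolation is linear between the flanking frames
  expect_equal(g$width[41, 3],
               w[40, 3] + (w[43, 3] - w[40, 3]) / 3, tolerance = 1e-9)
})

test_that("gaps longer than the limit fail loudly, naming the frames", {
  w <- matrix(5, 50, 9); w[10:15, 2] <- NA
  expect_error(build_gvg(w, fps = 1000), "10-15")
  w2 <- matrix(5, 50, 9); w2[, 4] <- NA
  expect_error(build_gvg(w2, fps = 1000), "degenerate")
})

test_that("max opening position follows the amplitude profile and tie rule", {
  g1 <- build_gvg(matrix(3, 10, 1), fps = 100)
  expect_equal(max_opening_position(g1), 1L)
  # generator amplitude peaks at the middle line (5 of 9)
  kin <- small_kinematics()
  et_w <- kin$right_x - kin$left_x
  g2 <- build_gvg(et_w, fps = 20000)
  expect_equal(max_opening_position(g2), 5L)
  # exact tie resolves to the anterior-most column
  g3 <- build_gvg(cbind(rep(2, 10), rep(2, 10), rep(1, 10)), fps = 100)
  expect_equal(max_opening_position(g3), 1L)
})

test_that("waveform is a slice: bounded by its column's maximum", {
  kin <- small_kinematics()
  fr <- small_opaque_stack()
  g <- gvg_from_threshold(fr, 100)
  ap <- max_opening_position(g)
  wave <- opening_waveform(g, ap)
  expect_lte(max(wave), max(g$width[, ap]))
  expect_error(opening_waveform(g, 0), "ap_index")
})

test_that("waveform period equals fps / f0 in frames", {
  fr <- small_opaque_stack()
  g <- gvg_from_threshold(fr, 100)
  wave <- as.numeric(opening_waveform(g, demean = TRUE))
  settled <- wave[101:400]
  up <- which(settled[-1] >= 0 & settled[-length(settled)] < 0)
  expect_true(all(abs(diff(up) - 10) <= 1))
})

test_that("GVG CSV export has the declared layout", {
  g <- build_gvg(matrix(1:20 / 10, 10, 2), fps = 100, pixel_scale = 0.5,
                 ap_rows = c(3L, 7L))
  f <- tempfile(fileext = ".csv")
  write_gvg_csv(g, f)
  d <- data.table::fread(f, data.table = FALSE)
  expect_equal(dim(d), c(10L, 3L))
  expect_equal(d$time_s, g$times)
  unlink(f)
})
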