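test_that("preprocess with no rotation and full crop is the identity", {
  fr <- small_opaque_stack()
  out <- preprocess(fr, rotation_deg = 0, crop_box = NULL)
  expect_identical(out$pixels, fr$pixels)
  d <- dim(fr$pixels)
  out2 <- preprocess(fr, crop_box = list(rows = c(1, d[1]),
                                         cols = c(1, d[2])))
  expect_identical(out2$pixels, fr$pixels)
})

test_that("90-degree rotation swaps a bar's orientation, preserving length", {
  px <- array(200, dim = c(40, 40, 1))
  px[18:22, 6:35, 1] <- 30                       # horizontal bar 30 x 5
  st <- frame_stack(px, fps = 1000)
  rot <- preprocess(st, rotation_deg = 90)
  m <- rot$pixels[, , 1] < 100
  expect_true(all(abs(range(colSums(m)[colSums(m) > 0]) - 30) <= 1))
  expect_true(all(abs(range(rowSums(m)[rowSums(m) > 0]) - 5) <= 1))
})

test_that("rotation round trip preserves threshold widths", {
  fr <- small_opaque_stack()
  sub <- frame_stack(fr$pixels[, , 1:10, drop = FALSE], fps = fr$fps,
                     pixel_scale = fr$pixel_scale, line_rows = fr$line_rows)
  back <- preprocess(preprocess(sub, 7), -7)
  g0 <- gvg_from_threshold(sub, 100)
  g1 <- gvg_from_threshold(back, 100)
  expect_lte(max(abs(g0$width_px - g1$width_px)), 1)
})

test_that("empty crop boxes are rejected", {
  fr <- small_opaque_stack()
  expect_error(preprocess(fr, crop_box = list(rows = c(10, 5))), "crop")
  expect_error(preprocess(fr, crop_box = list(cols = c(0, 10))), "crop")
})

test_that("a frame with no sub-threshold pixels yields a flagged empty mask", {
  m <- segment_glottis_threshold(matrix(200, 20, 30), 100)
  expect_true(m$closed)
  expect_false(any(m$mask))
  expect_true(all(glottal_width_profile(m)$width_px == 0))
})

test_that("the dilation margin is measured, and widths correct for it", {
  expect_equal(dilation_margin(), 1)
  fr <- matrix(160, 30, 60); fr[8:24, 21:40] <- 40
  m <- segment_glottis_threshold(fr, 100)
  raw <- glottal_width_profile(m)$width_px[15]
  corrected <- glottal_width_profile(m, margin_px = 1)$width_px[15]
  expect_equal(raw, 20 + 1)
  expect_equal(corrected, 20)
  # mm scaling
  expect_equal(glottal_width_profile(m, pixel_scale = 0.01,
                                     margin_px = 1)$width_mm[15], 0.20)
})

test_that("bright speckles inside the opening are absorbed by filling", {
  fr <- matrix(160, 30, 60); fr[8:24, 21:40] <- 40
  fr[15, 30] <- 250                              # 1-px bright speckle
  m <- segment_glottis_threshold(fr, 100)
  expect_true(m$mask[15, 30])                    # hole filled
  # mask is simply connected: one component, complement un-holed
  lab <- EBImage::bwlabel(EBImage::Image(t(m$mask)))
  expect_equal(max(lab), 1)
  filled_again <- EBImage::fillHull(EBImage::Image(t(m$mask * 1)))
  expect_equal(sum(filled_again > 0), sum(m$mask))  # idempotent re-fill
})

test_that("raising the threshold never shrinks the sub-threshold region", {
  fr <- small_opaque_stack()$pixels[, , 5]
  areas <- vapply(c(45, 80, 120, 161),
                  function(th) sum(fr < th), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("width profiles are invariant to border padding", {
  fr <- matrix(160, 30, 60); fr[8:24, 21:40] <- 40
  m1 <- segment_glottis_threshold(fr, 100)
  pad <- matrix(160, 40, 80); pad[6:35, 11:70] <- fr
  m2 <- segment_glottis_threshold(pad, 100)
  w1 <- glottal_width_profile(m1)$width_px
  w2 <- glottal_width_profile(m2)$width_px
  expect_equal(w1[w1 > 0], w2[w2 > 0])
})

test_that("largest component is kept, darker component wins exact ties", {
  fr <- matrix(160, 30, 60)
  fr[5:10, 10:19] <- 40        # 6 x 10, dark
  fr[20:25, 35:44] <- 80       # 6 x 10, less dark
  m <- segment_glottis_threshold(fr, 100)
  expect_true(all(m$mask[5:10, 10:19]))
  expect_false(any(m$mask[20:25, 35:44]))
})

test_that("Otsu suggestion lands between the two gray populations", {
  fr <- small_opaque_stack()$pixels[, , 250]
  th <- suggest_threshold(fr)
  expect_gt(th, 40); expect_lt(th, 160)
})
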