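test_that("resampling preserves tones, constants and the identity case", {
  fs <- 250000; t <- seq(0, 0.05 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10000 * t)
  y <- resample_to_framerate(x, fs = fs, fps = 125000)
  expect_length(y, ceiling(length(x) / 2))
  t2 <- (seq_along(y) - 1) / 125000
  mid <- 1000:5000
  expect_lt(max(abs(y[mid] - sin(2 * pi * 10000 * t2[mid]))), 0.005)
  cc <- resample_to_framerate(rep(2.5, 10000), fs = fs, fps = 20000)
  expect_equal(cc, rep(2.5, 800), tolerance = 1e-3)
  expect_equal(resample_to_framerate(x, fs = fs, fps = fs), x)
  expect_error(resample_to_framerate(x, fs = fs, fps = 2 * fs), "fps")
  # traces keep class, rate and alignment
  tr <- sound_trace(x, fs = fs, t0 = 1.5)
  tr2 <- resample_to_framerate(tr, fps = 25000)
  expect_s3_class(tr2, "sound_trace")
  expect_equal(trace_fs(tr2), 25000)
  expect_equal(trace_t0(tr2), 1.5)
})

test_that("resampling then yin matches yin at the original rate", {
  fs <- 250000; t <- seq(0, 0.2 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 3000 * t)
  a <- yin_f0(x, fs = fs, window = 1024, hop = 512)
  y <- resample_to_framerate(x, fs = fs, fps = 20000)
  b <- yin_f0(y, fs = 20000, window = 128, hop = 41)
  fa <- median(a$f0[a$valid]); fb <- median(b$f0[b$valid])
  expect_lt(abs(fa - fb) / fa, 0.01)
})

test_that("identity regression recovers slope, intercept and r-squared", {
  mk <- function(f0) {
    structure(data.frame(time = seq_along(f0) / 100, f0 = f0,
                         aperiodicity = 0, power = 1, valid = TRUE),
              fs = 100, engine = "yin", class = c("fo_track", "data.frame"))
  }
  f <- seq(1000, 2000, length.out = 50)
  same <- identity_regression(mk(f), mk(f))
  expect_equal(same$slope, 1, tolerance = 1e-12)
  expect_equal(same$intercept, 0, tolerance = 1e-9)
  expect_equal(same$r_squared, 1)
  expect_equal(same$n, 50L)
  # octave-error detector: doubled sound track gives slope 2
  oct <- identity_regression(mk(f), mk(2 * f))
  expect_equal(oct$slope, 2, tolerance = 1e-12)
  expect_error(identity_regression(mk(f[1:2]), mk(f[1:2])),
               "insufficient")
  expect_error(identity_regression(mk(rep(1500, 10)), mk(rep(1500, 10))),
               "variance")
})

test_that("f0 range summaries match order statistics", {
  s <- fo_range_summary(c(1, 2, 3, 4, 5) * 1000)
  expect_equal(s$minimum, 1000); expect_equal(s$median, 3000)
  expect_equal(s$maximum, 5000); expect_equal(s$n, 5L)
  one <- fo_range_summary(4200)
  expect_true(all(unlist(one[c("minimum", "q1", "median", "q3",
                               "maximum")]) == 4200))
  set.seed(77)
  big <- fo_range_summary(runif(10000, 1000, 5000))
  expect_lt(abs(big$median - 3000), 50)
  expect_true(big$minimum <= big$q1 && big$q1 <= big$median &&
              big$median <= big$q3 && big$q3 <= big$maximum)
  expect_error(fo_range_summary(numeric(0)), "insufficient")
})

test_that("call segmentation finds bursts and merges across short gaps", {
  fs <- 250000
  expect_equal(nrow(segment_calls(sound_trace(numeric(5000), fs = fs))), 0L)
  x <- tone_burst(3000, fs, dur = 0.002, amp = 5e-3, t_on = 0.01,
                  t_total = 0.1) +
       tone_burst(3000, fs, dur = 0.002, amp = 5e-3, t_on = 0.06,
                  t_total = 0.1)
  iv <- segment_calls(sound_trace(x, fs = fs))
  expect_equal(nrow(iv), 2L)
  # starts within one RMS window of the true burst onsets
  expect_lt(max(abs(iv$start - c(0.01, 0.06))), 1e-3)
  # gaps below min_gap merge
  iv2 <- segment_calls(sound_trace(x, fs = fs), min_gap_s = 0.1)
  expect_equal(nrow(iv2), 1L)
})

test_that("an agonistic-call-like burst yields the right f0 distribution", {
  fs <- 250000
  x <- tone_burst(3000, fs, dur = 0.002, amp = 5e-3, t_on = 0.005,
                  t_total = 0.02)
  snd <- sound_trace(x, fs = fs)
  iv <- segment_calls(snd)
  expect_equal(nrow(iv), 1L)
  seg <- trace_window(snd, iv$start[1], iv$end[1])
  tr <- yin_f0(seg, window = 400, hop = 50)
  expect_lt(abs(median(tr$f0[tr$valid]) - 3000) / 3000, 0.05)
})
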