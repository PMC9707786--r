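test_that("low-pass filtering has unit DC gain and a flat passband", {
  fs <- 250000
  const <- pressure_trace(rep(3, 100000), fs = fs)
  expect_lt(max(abs(as.numeric(lowpass_pressure(const)) - 3)), 1e-9)
  t <- seq(0, 0.5, by = 1 / fs)
  s50 <- pressure_trace(sin(2 * pi * 50 * t), fs = fs)
  y <- as.numeric(lowpass_pressure(s50))
  mid <- round(length(t) * 0.3):round(length(t) * 0.7)
  # forward-backward pass: gain is the squared Butterworth magnitude
  expect_equal(max(abs(y[mid])), butterworth_gain(50, 500, 6)^2,
               tolerance = 1e-3)
})

test_that("stopband attenuation matches the squared Butterworth response", {
  fs <- 250000
  t <- seq(0, 0.2, by = 1 / fs)
  s5k <- pressure_trace(sin(2 * pi * 5000 * t), fs = fs)
  y <- as.numeric(lowpass_pressure(s5k))
  mid <- round(length(t) * 0.3):round(length(t) * 0.7)
  # two passes of a 6th-order filter one decade above cutoff: >= 120 dB
  expect_lt(max(abs(y[mid])), 1e-6)
  expect_error(lowpass_pressure(pressure_trace(1:10, fs = 900)), "cutoff")
})

test_that("pressure speed is the first difference times the rate", {
  fs <- 250000
  ramp <- lowpass_pressure(generate_pressure("slow_ramp", fs = fs))
  spd <- pressure_speed(ramp)
  tt <- trace_times(spd)
  mid <- as.numeric(spd)[tt > 0.5 & tt < 5.5]
  expect_lt(max(abs(mid - 1)), 0.05 * 1)        # 1 kPa/s within 5%
  const <- pressure_trace(rep(2, 1000), fs = 1000)
  expect_true(all(pressure_speed(const) == 0))
  t <- seq(0, 1, by = 1 / fs)
  sine <- pressure_trace(sin(2 * pi * 10 * t), fs = fs)
  spd2 <- pressure_speed(sine)
  m <- round(length(t) * 0.3):round(length(t) * 0.7)
  expect_equal(max(abs(as.numeric(spd2)[m])), 2 * pi * 10,
               tolerance = 0.005)
})

test_that("zero-phase filtering does not displace a pressure step", {
  fs <- 250000
  x <- c(rep(0, 50000), rep(4, 50000))
  y <- as.numeric(lowpass_pressure(pressure_trace(x, fs = fs)))
  # half-amplitude crossing stays at the step location within the
  # filter's settling half-width (~ fs / cutoff samples)
  cross <- which(y >= 2)[1]
  expect_lt(abs(cross - 50001), fs / 500)
})

test_that("sound onset detection honors threshold, debounce and silence", {
  fs <- 250000
  silent <- sound_trace(numeric(50000), fs = fs)
  expect_true(is.na(detect_sound_onset(silent)))
  # linear amplitude ramp 0 -> 2 mPa over 100 ms: RMS crosses 0.2 mPa
  t <- (0:(0.1 * fs - 1)) / fs
  amp <- 2e-3 * t / 0.1
  snd <- sound_trace(amp * sin(2 * pi * 5000 * t), fs = fs)
  onset <- detect_sound_onset(snd)
  expect_false(is.na(onset))
  rms_at <- attr(onset, "rms_at_onset")
  # window bias bound: the RMS changes by slope * window across the window
  bias <- 2e-3 / 0.1 * 1e-3
  expect_lt(abs(rms_at - 2e-4), bias + 1e-6)
  # a 0.5 ms click is rejected by the 2 ms hold
  click <- numeric(50000)
  click[10000:10125] <- 1e-3 * sin(2 * pi * 5000 * t[1:126])
  expect_true(is.na(detect_sound_onset(sound_trace(click, fs = fs))))
})

test_that("PTP and S_ptp are read off at the sound onset", {
  fs <- 250000
  p <- generate_pressure("slow_ramp", fs = fs)
  eps <- phonation_intervals(p, ptp_true = 4)
  s <- synthesize_sound(f0_profile("sweep"), eps, fs = fs,
                        duration = length(p) / fs, seed = 31)
  res <- compute_ptp(p, s)
  expect_true(res$detected)
  expect_equal(res$ptp, 4, tolerance = 0.05 / 4)
  expect_equal(res$s_ptp, 1, tolerance = 0.05)
  expect_equal(res$threshold_used, 2e-4)
})

test_that("fast-pulse onsets capture the configured pressure rise rate", {
  fs <- 250000
  p <- generate_pressure("fast_pulses", fs = fs)
  eps <- phonation_intervals(p, ptp_true = 3.2, rate_gate = 50)
  s <- synthesize_sound(f0_profile("sweep", from = 13500, to = 16500),
                        eps, fs = fs, duration = length(p) / fs, seed = 8)
  res <- compute_ptp(p, s)
  expect_true(res$detected)
  rise <- attr(p, "protocol")$rise_rate_kpa_s
  expect_equal(res$s_ptp, rise, tolerance = 0.10)
  expect_equal(res$ptp, 3.2, tolerance = 0.1 / 3.2)
})

test_that("a no-onset trial reports detected = FALSE with NA values", {
  fs <- 250000
  p <- generate_pressure("slow_ramp", fs = fs)
  s <- synthesize_sound(f0_profile("constant"),
                        data.frame(start = numeric(0), end = numeric(0)),
                        fs = fs, duration = length(p) / fs, seed = 4)
  res <- compute_ptp(p, s)
  expect_false(res$detected)
  expect_true(is.na(res$ptp) && is.na(res$s_ptp))
})

test_that("misaligned or mismatched traces are rejected", {
  p <- pressure_trace(1:1000 / 100, fs = 10000)
  s <- sound_trace(numeric(1000), fs = 20000)
  expect_error(compute_ptp(p, s), "sampling rates")
  s2 <- sound_trace(numeric(500), fs = 10000)
  expect_error(compute_ptp(p, s2), "misaligned")
})

test_that("PTP is recovered across thresholds and seeds", {
  # property: mean absolute PTP error over seeded ramps stays tiny
  fs <- 250000
  errs <- vapply(1:4, function(k) {
    set.seed(k)
    ptp_true <- runif(1, 2, 6)
    p <- generate_pressure("slow_ramp", fs = fs)
    eps <- phonation_intervals(p, ptp_true = ptp_true)
    s <- synthesize_sound(f0_profile("sweep"), eps, fs = fs,
                          duration = length(p) / fs, seed = k)
    abs(compute_ptp(p, s)$ptp - ptp_true)
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})
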