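test_that("slow ramp onset occurs when pressure reaches the threshold", {
  prof <- kinematic_profile(duration = 0.02, fps = 20000, f0 = 2000)
  pr <- generate_pressure("slow_ramp", fs = 250000)
  kin <- simulate_kinematics(prof, pr, ptp_true = 4, t_start = 3.99)
  expect_equal(kin$truth$onset_time, 4, tolerance = 1e-4)
  expect_equal(kin$truth$onset_pressure, 4, tolerance = 1e-3)
  expect_equal(kin$truth$onset_pressure_speed, 1, tolerance = 1e-2)
})

test_that("constant f0 gives an opening waveform with period fps / f0", {
  kin <- small_kinematics()     # 2 kHz at 20,000 fps -> 10 frames
  w <- kin$right_x[, 5] - kin$left_x[, 5]
  # after the onset envelope has settled, peaks must be 10 frames apart
  settled <- w[101:400]
  peaks <- which(diff(sign(diff(settled))) == -2) + 1
  expect_equal(unique(diff(peaks)), 10L)
})

test_that("an unsatisfiable rate gate yields no onset at all", {
  prof <- kinematic_profile(duration = 0.02, fps = 20000, f0 = 2000)
  pr <- generate_pressure("slow_ramp", fs = 250000)
  kin <- simulate_kinematics(prof, pr, ptp_true = 3, rate_gate = 50,
                             t_start = 3)
  expect_true(is.na(kin$truth$onset_time))
  expect_false(any(kin$phonating))
  # closed: constant minimal slit everywhere
  expect_equal(max(kin$right_x - kin$left_x), prof$slit_px)
})

test_that("swept f0 tracks fps / f0(t) in instantaneous period", {
  prof <- kinematic_profile(duration = 0.02, fps = 125000,
                            f0 = f0_profile("sweep", from = 10000,
                                            to = 20000, span_s = 0.02),
                            amplitude_px = 10)
  pr <- pressure_trace(rep(5, 6000), fs = 250000)
  kin <- simulate_kinematics(prof, pr, ptp_true = 4)
  w <- kin$right_x[, 5] - kin$left_x[, 5]
  wd <- w - mean(w)
  up <- which(wd[-1] >= 0 & wd[-length(wd)] < 0)  # upward zero crossings
  periods <- diff(up)
  mid_t <- kin$times[up[-length(up)]] + periods / (2 * prof$fps)
  expected <- prof$fps / approx(kin$times, kin$f0_hz, xout = mid_t)$y
  keep <- mid_t > 0.0015                      # past the onset envelope
  expect_true(all(abs(periods[keep] - expected[keep]) <= 1))
})

test_that("sampling adequacy is enforced at construction", {
  expect_error(kinematic_profile(duration = 0.1, fps = 7000, f0 = 2000),
               "sampling")
  expect_error(kinematic_profile(duration = 0.1, fps = 20000, f0 = 2000,
                                 n_lines = 7L), "n_lines")
})

test_that("edge positions stay inside the rendered frame", {
  kin <- small_kinematics()
  fr <- small_opaque_stack()
  d <- dim(fr$pixels)
  expect_true(all(kin$left_x >= 0 & kin$right_x <= d[2] - 1))
  expect_true(all(kin$left_x <= kin$right_x))
})
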