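# Shared fixtures, built once per test run and memoized. Kept small:
# short videos are enough for unit-level checks; the acceptance tests
# build their own full-length trials.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# constant-pressure kinematics at 2 kHz / 20 kfps, phonating throughout
small_kinematics <- function() {
  fixture("kin2k", function() {
    prof <- kinematic_profile(duration = 0.02, fps = 20000, f0 = 2000,
                              center_x = 48)
    pr <- pressure_trace(rep(5, 10000), fs = 250000)
    simulate_kinematics(prof, pr, ptp_true = 4)
  })
}

small_opaque_stack <- function() {
  fixture("stack2k", function()
    render_frames(small_kinematics(), "opaque", size = c(48L, 96L)))
}

small_translucent_stack <- function() {
  fixture("stack2k_tl", function()
    render_frames(small_kinematics(), "translucent", size = c(48L, 96L),
                  noise_sd = 2, seed = 41))
}

# frames (per line) where the true aperture clears the membrane bands
open_frames <- function(kin, min_width = 14) {
  (kin$right_x - kin$left_x) > min_width
}

# harmonic tone burst in Pa for call-segmentation tests
tone_burst <- function(f0, fs, dur, amp, t_on, t_total, n_harm = 3) {
  n <- round(t_total * fs)
  t <- (0:(n - 1)) / fs
  x <- numeric(n)
  idx <- which(t >= t_on & t < t_on + dur)
  for (h in seq_len(n_harm))
    x[idx] <- x[idx] + (amp / h) * sin(2 * pi * h * f0 * (t[idx] - t_on))
  x
}
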