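# Synthetic session generator: trajectories, planted structure, artifacts.

test_that("tap trajectories have the prescribed pulse structure", {
  p <- tap_params(n_trials = 1, trial_length_sd = 0)
  tr <- generate_tap_trajectory(p, seed = 4)
  s <- tr$trial_bounds[1, 1]; e <- tr$trial_bounds[1, 2]
  seg <- tr$angle[s:e]
  pk <- tapdecode:::find_peaks(seg, 0.1)
  expect_equal(length(pk), 3)            # three taps per trial
  expect_true(all(seg[pk] > p$rest_angle + 0.9 * 37.2))
  # outside trials the trace rests at rest_angle
  expect_true(all(tr$angle[1:(s - 2)] == p$rest_angle))
  # degenerate: extension == rest gives a flat trace
  p0 <- tap_params(rest_angle = 0, extension_angle = 0, n_trials = 2)
  tr0 <- generate_tap_trajectory(p0, seed = 4)
  expect_true(all(tr0$angle == 0))
  expect_error(generate_tap_trajectory(p), "seed")
  expect_error(tap_params(rest_angle = 5, extension_angle = 0), ">=")
})

test_that("measured tapping speed matches the planted trial length", {
  # subject-1-like pacing: 1.43 s trials -> ~2.1 taps/s
  p <- tap_params(trial_length_mean = 1.43, trial_length_sd = 0.12,
                  n_trials = 40, inter_trial_rest_mean = 3)
  tr <- generate_tap_trajectory(p, seed = 9)
  pad <- 40L
  w <- cbind(tr$trial_bounds[, 1] - pad, tr$trial_bounds[, 2] + pad)
  tt <- trial_table(tr$angle, w, rate = 100)
  expect_equal(mean(tt$tapping_speed), 3 / 1.43, tolerance = 0.05)
})

test_that("trial statistics of generated sessions match the parameters", {
  p <- tap_params(n_trials = 100)
  tr <- generate_tap_trajectory(p, seed = 12)
  pad <- 40L
  w <- cbind(tr$trial_bounds[, 1] - pad, tr$trial_bounds[, 2] + pad)
  tt <- trial_table(tr$angle, w, rate = 100)
  # within 3 standard errors over 100 trials (plus one sample of slack on
  # the trial length, whose 5% bounds sit just inside the true pulse train)
  se <- p$trial_length_sd / sqrt(nrow(tt))
  expect_lt(abs(mean(tt$trial_length) - p$trial_length_mean), 3 * se + 0.02)
  expect_lt(abs(mean(tt$rest_position) - p$rest_angle), 0.1)
  expect_lt(abs(mean(tt$extension_angle) - p$extension_angle), 0.3)
  expect_true(all(tt$valid))
})

test_that("generated kinematics keep 95% of power below 3 Hz", {
  p <- tap_params(n_trials = 60)
  tr <- generate_tap_trajectory(p, seed = 21)
  psd <- multitaper_psd(tr$angle, 100)
  expect_lte(freq_at_cumulative_power(psd$freq, psd$psd, 0.95), 3)
})

test_that("sessions are reproducible and glove output is quantized", {
  s1 <- small_session(snr = 1, seed = 71)
  s2 <- generate_session(small_tap(12),
                         coupling_spec(default_coupled_channels(small_montage(), 3),
                                       c(50, 100, 150), snr = 1),
                         seed = 71, montage = small_montage())
  expect_identical(s1$eeg$samples, s2$eeg$samples)
  expect_identical(s1$glove$angle, s2$glove$angle)
  # glove: 0.93 degree grid, sampling intervals within [1/70, 1/35]
  expect_true(all(abs(s1$glove$angle / 0.93 -
                        round(s1$glove$angle / 0.93)) < 1e-9))
  dt <- diff(s1$glove$time)
  dt <- dt[-length(dt)]                  # final sample closes the record
  expect_true(all(dt >= 1 / 70 - 1e-12 & dt <= 1 / 35 + 1e-12))
  expect_error(generate_session(small_tap(2)), "seed")
})

test_that("planted ground truth is coherent", {
  ses <- small_session(snr = 1, seed = 71)
  expect_equal(ses$truth$r_ceiling, sqrt(1 / 2))
  tb <- ses$truth$trial_bounds_true
  expect_true(all(tb[, 2] > tb[, 1]))
  expect_true(all(diff(as.vector(t(tb))) > 0))   # ordered, non-overlapping
  # detected bounds track the true pulse bounds within 3 samples
  tt <- session_trial_table(ses)
  expect_lt(max(abs(tt$onset_sample - tb[, 1])), 4)
  expect_lt(max(abs(tt$offset_sample - tb[, 2])), 4)
})

test_that("artifacts are confined to peripheral channels", {
  ses <- small_session(snr = 1, seed = 71)
  rec <- recording(matrix(rnorm(4000 * 25), 4000, 25),
                   500, small_montage()$label,
                   peripheral = small_montage()$peripheral)
  # zero amplitudes: bit-identical output
  same <- plant_artifacts(rec, blink_amplitude = 0, blink_rate = 0,
                          drift_amplitude = 0, seed = 3)
  expect_identical(same$samples, rec$samples)
  # artifacts on: peripheral variance strictly increases, rest untouched
  out <- plant_artifacts(rec, blink_amplitude = 4, blink_rate = 0.5,
                         drift_amplitude = 2, seed = 3)
  per <- rec$peripheral
  expect_identical(out$samples[, !per], rec$samples[, !per])
  v0 <- apply(rec$samples[, per], 2, var)
  v1 <- apply(out$samples[, per], 2, var)
  expect_true(all(v1 > v0))
})

test_that("kinematics-correlated peripheral artifacts become decodable", {
  m <- small_montage()
  mk <- function(rho, seed) {
    generate_session(small_tap(20),
                     coupling_spec(default_coupled_channels(m, 3),
                                   c(50, 100, 150), snr = 0),
                     seed = seed, montage = m,
                     artifact_kin_coupling = rho)
  }
  r_at <- function(rho) {
    rs <- vapply(1:2, function(s) {
      ses <- mk(rho, 100 + s)
      cv <- outer_cv(ses, "peripheral", seed = s, n_folds = 4,
                     inner_folds = 4, use_ga = FALSE)
      stats::median(cv$r)
    }, numeric(1))
    mean(rs)
  }
  expect_gt(r_at(3), r_at(0) + 0.15)
})
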