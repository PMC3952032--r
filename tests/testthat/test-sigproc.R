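# Signal conditioning: referencing, filtering, resampling, segmentation.

test_that("channel rejection leaves 47 of 65 channels and validates labels", {
  m <- default_montage()
  rec <- recording(matrix(rnorm(200 * 65), 200, 65), 500, m$label,
                   peripheral = m$peripheral)
  out <- reject_channels(rec, m$label[m$peripheral])
  expect_equal(ncol(out$samples), 47)
  expect_false(any(out$peripheral))

  same <- reject_channels(rec, character(0))
  expect_equal(same$samples, rec$samples, ignore_attr = TRUE)
  expect_error(reject_channels(rec, "NOPE"), "unknown channel")
  expect_error(reject_channels(rec, m$label), "leaves nothing")
})

test_that("common average reference zeroes the cross-channel mean", {
  x <- matrix(rnorm(300), 100, 3)
  rec <- recording(x, 100, c("a", "b", "c"))
  out <- common_average_reference(rec)
  expect_lt(max(abs(rowMeans(out$samples))), 1e-12)

  # closed form for two channels
  rec2 <- recording(cbind(x[, 1], x[, 2]), 100, c("a", "b"))
  out2 <- common_average_reference(rec2)
  expect_equal(out2$samples[, 1], (x[, 1] - x[, 2]) / 2,
               ignore_attr = TRUE)
  # constant offset on all channels is removed
  rec3 <- recording(x + 5, 100, c("a", "b", "c"))
  expect_equal(common_average_reference(rec3)$samples, out$samples)
  # re-referencing and single-channel input are errors
  expect_error(common_average_reference(out), "already applied")
  expect_error(common_average_reference(
    recording(x[, 1, drop = FALSE], 100, "a")), "at least 2")
})

test_that("zero-phase filters match closed-form magnitude responses", {
  hp <- filter_spec("butterworth", 8, 0.1, "high")
  lp <- filter_spec("butterworth", 1, 3, "low")
  # DC through the high-pass vanishes
  expect_lt(max(abs(zero_phase_filter(rep(7.3, 4000), hp, 100))), 1e-10)
  # 1 Hz sinusoid through the 3 Hz low-pass: amplitude 1/(1+(g1/g3)^2)
  t <- (0:19999) / 100
  y <- zero_phase_filter(sin(2 * pi * t), lp, 100)
  amp <- sqrt(2) * stats::sd(y)
  expect_gte(amp, 0.9)
  expect_lte(amp, 1.0)
  gr <- (tan(pi * 1 / 100) / tan(pi * 3 / 100))^2
  expect_equal(amp, 1 / (1 + gr), tolerance = 1e-3)
  # zero-phase symmetry: filtering commutes with time reversal
  x <- rnorm(2000)
  expect_equal(zero_phase_filter(rev(x), lp, 100),
               rev(zero_phase_filter(x, lp, 100)), tolerance = 1e-9)
  # linearity
  a <- rnorm(1500); b <- rnorm(1500)
  expect_equal(zero_phase_filter(2 * a - 3 * b, hp, 100),
               2 * zero_phase_filter(a, hp, 100) -
                 3 * zero_phase_filter(b, hp, 100), tolerance = 1e-9)
  expect_error(zero_phase_filter(rnorm(10), hp, 100), "too short")
})

test_that("antialiasing downsampler preserves passband and kills stopband", {
  t <- (0:49999) / 500
  mk <- function(f) recording(matrix(sin(2 * pi * f * t), ncol = 1),
                              500, "ch")
  lo <- antialias_downsample(mk(2))
  expect_equal(lo$rate, 100)
  expect_equal(nrow(lo$samples), 10000)
  expect_equal(sqrt(2) * stats::sd(lo$samples), 1, tolerance = 0.01)
  hi <- antialias_downsample(mk(45))
  expect_lt(sqrt(2) * stats::sd(hi$samples), 0.05)
  odd <- recording(matrix(rnorm(1001), ncol = 1), 250, "ch")
  expect_error(antialias_downsample(odd), "integer multiple")
})

test_that("PCHIP upsampling is shape-preserving and exact on ramps", {
  ts <- cumsum(runif(60, 1 / 70, 1 / 35))
  # linear ramp reproduced exactly
  up <- upsample_kinematics(ts, 3 * ts + 1, rate = 100)
  expect_equal(up$angle, 3 * up$time + 1, tolerance = 1e-10)
  # monotone data give monotone interpolant
  y <- cumsum(abs(rnorm(60)))
  up2 <- upsample_kinematics(ts, y, rate = 100)
  expect_true(all(diff(up2$angle) >= -1e-12))
  # interpolation passes through the knots
  tu <- (0:49) / 100
  up3 <- upsample_kinematics(tu, sin(tu * 4), rate = 100)
  expect_equal(up3$angle, sin(tu * 4), tolerance = 1e-12)
  expect_error(upsample_kinematics(c(0, 1, 1, 2), 1:4), "increasing")
})

test_that("differentiation matches analytic derivatives", {
  expect_equal(differentiate(rep(2.5, 50), 100), rep(0, 50))
  expect_equal(differentiate(0.3 * (0:99) / 100, 100), rep(0.3, 100))
  t <- (0:9999) / 100
  d <- differentiate(sin(2 * pi * 3 * t), 100)
  expect_equal(sqrt(2) * stats::sd(d), 2 * pi * 3, tolerance = 0.01)
  expect_error(differentiate(1, 100), "at least 2")
})

test_that("derivative and delta low-pass commute as linear operators", {
  lp <- filter_spec("butterworth", 1, 3, "low")
  x <- cumsum(rnorm(4000))
  a <- differentiate(zero_phase_filter(x, lp, 100), 100)
  b <- zero_phase_filter(differentiate(x, 100), lp, 100)
  core <- 100:3900
  expect_gt(stats::cor(a[core], b[core]), 0.999)
})

test_that("segmentation standardizes channels and baselines kinematics", {
  n <- 3000
  F <- matrix(rnorm(2 * n, mean = 3, sd = 2), n, 2)
  kin <- rnorm(n) + 10
  trials <- data.frame(onset_sample = c(500, 1500, 2500),
                       offset_sample = c(700, 1680, 2620))
  seg <- segment_and_standardize(F, kin, trials, rate = 100)
  expect_equal(colMeans(seg$X), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(seg$X, 2, stats::sd), c(1, 1), tolerance = 1e-12)
  # half-open windows: each trial contributes offset-onset+20 samples
  expect_equal(length(seg$kin),
               sum(trials$offset_sample - trials$onset_sample + 20))
  # kinematic baseline: mean over [-0.1, 0) s subtracted
  i1 <- seg$trial_id == 1
  base <- mean(kin[490:499])
  expect_equal(seg$kin[i1], kin[490:709] - base, ignore_attr = TRUE)
  # training statistics can be reused on held-out data
  seg2 <- segment_and_standardize(F + 1, kin, trials, rate = 100,
                                  stats = seg$stats)
  expect_equal(seg2$X,
               seg$X + matrix(1 / seg$stats$sd, nrow(seg$X), 2, byrow = TRUE),
               tolerance = 1e-10)
  # out-of-range trial is dropped with a warning
  bad <- rbind(trials, data.frame(onset_sample = 2995, offset_sample = 3050))
  expect_warning(seg3 <- segment_and_standardize(F, kin, bad, rate = 100),
                 "dropped")
  expect_equal(seg3$kept_trials, 1:3)
})
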