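# ERD/ERS maps, sign tests, lag correlation maps, grand averages.

test_that("period extraction cuts the prescribed 1 s windows", {
  n <- 4000
  x <- matrix(0, n, 2)
  trials <- data.frame(onset_sample = c(1000, 3000),
                       offset_sample = c(1200, 3180))
  # spikes at the expected window starts (relative -150, +50, offset)
  x[850, 1] <- 100; x[1050, 1] <- 100; x[1200, 1] <- 100
  p <- extract_periods(x, trials, rate = 100)
  expect_equal(dim(p$rest), c(2, 100, 2))
  expect_equal(p$kept, 1:2)
  # the spike lands at position 1 of each window (detrending preserves it)
  expect_equal(which.max(p$rest[1, , 1]), 1)
  expect_equal(which.max(p$movement[1, , 1]), 1)
  expect_equal(which.max(p$end[1, , 1]), 1)
  # overlapping windows drop the trial with a warning
  close_tr <- data.frame(onset_sample = c(1000, 1400),
                         offset_sample = c(1200, 1600))
  expect_warning(p2 <- extract_periods(x, close_tr, rate = 100), "dropped")
  expect_equal(p2$kept, 1L)
})

test_that("ERD/ERS recover planted amplitude changes", {
  rate <- 100
  mk_period <- function(freq, amp, ntr = 8) {
    arr <- array(0, c(ntr, 100, 1))
    for (i in seq_len(ntr))
      arr[i, , 1] <- amp * sin(2 * pi * freq * (0:99) / rate +
                                 stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(100, sd = 0.02)
    arr
  }
  set.seed(20)
  periods <- list(rest = mk_period(10, 1), movement = mk_period(10, 0.5),
                  end = mk_period(25, 1), rate = rate)
  # halved alpha amplitude: relative power change (0.25 - 1)/1 = -0.75
  ee <- erd_ers(periods)
  expect_equal(stats::median(ee$alpha_erd), -0.75, tolerance = 0.075)
  # beta: movement has no 25 Hz, end has amp 1 -> build a proper pair
  set.seed(21)
  periods2 <- list(rest = mk_period(10, 1), movement = mk_period(25, 1),
                   end = mk_period(25, 2), rate = rate)
  ee2 <- erd_ers(periods2)
  expect_equal(stats::median(ee2$beta_ers), 3, tolerance = 0.3)
  # gain invariance: scaling a channel leaves the ratios unchanged
  p3 <- lapply(periods2[1:3], function(a) a * 7.3)
  p3$rate <- rate
  ee3 <- erd_ers(p3)
  expect_equal(ee3$beta_ers, ee2$beta_ers, tolerance = 1e-10)
})

test_that("the sign test is exact", {
  expect_equal(sign_test(rep(1, 10)), 2 / 1024, tolerance = 1e-12)
  expect_equal(sign_test(c(rep(1, 5), rep(-1, 5))), 1)
  expect_equal(sign_test(numeric(0)), 1)
  expect_equal(sign_test(rep(0, 8)), 1)            # zeros are excluded
  expect_equal(sign_test(c(0, 0, 1, 1, 1)),
               stats::binom.test(3, 3)$p.value)
  # 80 of 100 positive vs the exact two-sided binomial enumeration
  v <- c(rep(1, 80), rep(-1, 20))
  enum <- 2 * sum(stats::dbinom(80:100, 100, 0.5))
  expect_equal(sign_test(v), enum, tolerance = 1e-12)
})

test_that("lag correlation maps localize a planted lag-0 copy", {
  set.seed(22)
  n <- 6000
  vel <- as.numeric(zero_phase_filter(rnorm(n),
                                      filter_spec("butterworth", 1, 3,
                                                  "low"), 100))
  F <- cbind(copy = vel, noise = rnorm(n))
  trials <- data.frame(onset_sample = seq(500, 5500, by = 500),
                       offset_sample = seq(700, 5700, by = 500))
  maps <- lag_correlation_maps(F, vel, trials, lags_ms = c(0, 100))
  at0 <- maps[maps$channel == "copy" & maps$lag_ms == 0, ]
  expect_equal(at0$median_r, 1, tolerance = 1e-10)
  expect_true(at0$significant)
  noise0 <- maps[maps$channel == "noise" & maps$lag_ms == 0, ]
  expect_lt(abs(noise0$median_r), 0.3)
  rarr <- attr(maps, "r")
  expect_equal(dim(rarr), c(nrow(trials), 2, 2))
})

test_that("grand averages reproduce a single repeated trial", {
  rate <- 100
  n <- 8000
  sig <- sin(2 * pi * 1.5 * (0:(n - 1)) / rate)
  onsets <- seq(500, 7000, by = 650)
  trials <- data.frame(onset_sample = onsets, offset_sample = onsets + 180)
  # one channel = deterministic function of time-from-onset
  F <- matrix(0, n, 1)
  for (on in onsets) {
    idx <- (on - 160):(on + 310)
    F[idx, 1] <- F[idx, 1] + cos(2 * pi * (idx - on) / 200)
  }
  kin <- F[, 1] * 2 + 1
  ga <- grand_average(F, kin, trials, rate)
  expect_equal(length(ga$time), 451)
  expect_equal(ga$time[1], -1.5)
  # identical trials: average equals the (z-scored, baseline-corrected)
  # single-trial trace; oracle computed directly
  rows <- (onsets[3] - 150):(onsets[3] + 300)
  tr <- F[rows, 1] - mean(F[(onsets[3] - 150):(onsets[3] - 51), 1])
  expect_gt(stats::cor(ga$eeg[, 1], tr), 0.999)
  # kinematics is an affine copy of the channel: identical z-scored trace
  expect_equal(ga$kin, ga$eeg[, 1], tolerance = 1e-8)
})
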