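# Movement bounds, trial statistics, multitaper spectra.

# raised-cosine tap train: n_taps pulses over `len` seconds
tap_trace <- function(rest, rom, len, n_taps = 3, rate = 100,
                      lead = 2, tail = 2) {
  t <- seq(0, lead + len + tail, by = 1 / rate)
  a <- rep(rest, length(t))
  d <- len / n_taps
  inb <- t >= lead & t < lead + len
  a[inb] <- rest + rom * 0.5 * (1 - cos(2 * pi * ((t[inb] - lead) %% d) / d))
  a
}

test_that("5% rule finds analytic speed crossings within one sample", {
  rate <- 100
  a <- tap_trace(0, 40, 1.5, rate = rate)
  b <- detect_bounds(a, c(1, length(a)), rate)
  # first crossing: speed = max * sin(2 pi u / d) > 0.05 max
  d <- 0.5
  u_star <- asin(0.05) * d / (2 * pi)
  expect_lt(abs(b$onset_sample - (2 * rate + u_star * rate)), 2)
  expect_lt(abs(b$offset_sample - ((2 + 1.5) * rate - u_star * rate)), 2)
  # symmetric pulse: bounds symmetric about the centre
  centre <- 2 * rate + 0.75 * rate
  # half-sample alignment of the first-difference speed allows a small
  # asymmetry on top of the per-bound +/-1 sample
  expect_lte(abs((centre - b$onset_sample) - (b$offset_sample - centre)), 3)
  # invariance to offset and positive scaling
  b2 <- detect_bounds(7 + 3 * a, c(1, length(a)), rate)
  expect_equal(b2$onset_sample, b$onset_sample)
  expect_equal(b2$offset_sample, b$offset_sample)
  expect_error(detect_bounds(rep(1, 500), c(1, 500), rate), "flat")
})

test_that("trial statistics reproduce closed-form values", {
  rate <- 100
  a <- tap_trace(-22.33, 39.64, 1.5, rate = rate)
  b <- detect_bounds(a, c(1, length(a)), rate)
  st <- trial_statistics(a, b$onset_sample, b$offset_sample, rate)
  expect_true(st$valid)
  expect_equal(st$rest_position, -22.33, tolerance = 1e-6)
  expect_equal(st$extension_angle, 17.31, tolerance = 0.05)
  expect_equal(st$rom, 39.64, tolerance = 0.05)
  # speed = taps / length; a 2.0 s trial gives 1.5 taps/s
  st2 <- trial_statistics(a, b$onset_sample,
                          b$onset_sample + 2 * rate, rate)
  expect_equal(st2$tapping_speed, 1.5)
})

test_that("across-trial summaries compute mean, sd and CoV", {
  tt <- data.frame(trial_length = c(1, 3), tapping_speed = c(2, 2),
                   rest_position = c(-1, 1), extension_angle = c(5, 5),
                   rom = c(6, 4))
  s <- summarize_trials(tt)
  tl <- s[s$statistic == "trial_length", ]
  expect_equal(tl$mean, 2)
  expect_equal(tl$sd, sqrt(2))
  expect_equal(tl$cov, sqrt(2) / 2)
  # identical trials: sd 0, CoV 0
  expect_equal(s[s$statistic == "tapping_speed", ]$sd, 0)
  expect_equal(s[s$statistic == "tapping_speed", ]$cov, 0)
  # zero mean: CoV undefined
  expect_true(is.na(s[s$statistic == "rest_position", ]$cov))
  # a subject-1-like trial length row: mean 1.43, sd 0.12 -> CoV 0.084
  tt2 <- data.frame(trial_length = stats::rnorm(400, 1.43, 0.12))
  s2 <- summarize_trials(tt2, stats = "trial_length")
  expect_equal(s2$cov, 0.12 / 1.43, tolerance = 0.15)
})

test_that("multitaper PSD locates peaks and conserves power", {
  rate <- 100
  t <- (0:2047) / rate
  p <- multitaper_psd(sin(2 * pi * 2 * t), rate)
  expect_equal(p$freq[which.max(p$psd)], 2, tolerance = 0.2)
  expect_true(all(p$psd >= 0))
  # Parseval: integrated density approximates the variance
  x <- rnorm(8192)
  p2 <- multitaper_psd(x, rate)
  df <- p2$freq[2] - p2$freq[1]
  expect_equal(sum(p2$psd) * df, stats::var(x), tolerance = 0.1)
  # all-zero series: all-zero spectrum
  expect_true(all(multitaper_psd(rep(0, 1000), rate)$psd == 0))
  # short series is zero-padded with a warning
  expect_warning(multitaper_psd(rnorm(100), rate), "zero-padding")
})

test_that("cumulative-power frequency matches analytic spectra", {
  # single spectral line: any fraction returns its frequency
  freq <- seq(0, 50, by = 0.04)
  psd <- numeric(length(freq))
  psd[freq == 1.56] <- 1
  expect_equal(freq_at_cumulative_power(freq, psd, 0.95), 1.56)
  expect_equal(freq_at_cumulative_power(freq, psd, 0.10), 1.56)
  # flat spectrum on [0, 50]: 95% at 47.5 Hz
  f2 <- seq(0, 50, by = 0.5)
  expect_equal(freq_at_cumulative_power(f2, rep(1, length(f2)), 0.95),
               47.5)
  expect_error(freq_at_cumulative_power(f2, rep(0, length(f2))),
               "zero total")
})

test_that("coarse scan locates separated trial windows", {
  rate <- 100
  a1 <- tap_trace(0, 40, 1.5, rate = rate, lead = 3, tail = 0)
  a <- c(a1, tap_trace(0, 40, 1.2, rate = rate, lead = 2, tail = 3))
  w <- locate_trial_windows(a, rate)
  expect_equal(nrow(w), 2)
  tt <- trial_table(a, w, rate)
  expect_equal(nrow(tt), 2)
  expect_true(all(tt$valid))
  expect_equal(tt$trial_length, c(1.5, 1.2), tolerance = 0.05)
})
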