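# Lag embedding, OLS fitting, prediction, correlation scoring.

test_that("lag embedding produces the documented column layout", {
  set.seed(2)
  n <- 600
  F <- matrix(rnorm(n * 47), n, 47)
  colnames(F) <- paste0("c", 1:47)
  d <- lag_design(1:47)
  rows <- 101:500
  X <- embed_lags(F, d, rows)
  expect_equal(ncol(X), 47 * 7)          # N = 47 channels, L = 7 lags
  expect_equal(nrow(X), length(rows))
  # channel-major, lag-minor: column (i-1)*7+k holds channel i at lag k
  expect_equal(X[, (4 - 1) * 7 + 3], F[rows - 10, 4])  # 100 ms = 10 smp
  expect_equal(colnames(X)[1:3], c("c1@0ms", "c1@50ms", "c1@100ms"))
  # single channel, single lag 0: identity embedding
  X1 <- embed_lags(F, lag_design(5, lags_ms = 0), rows)
  expect_equal(drop(X1), F[rows, 5], ignore_attr = TRUE)
  # insufficient context
  expect_error(embed_lags(F, d, 10:500), "context")
})

test_that("a 150 ms shift-coded channel peaks at its lag column", {
  set.seed(3)
  n <- 3000
  target <- as.numeric(zero_phase_filter(rnorm(n),
                                         filter_spec("butterworth", 1, 3,
                                                     "low"), 100))
  F <- matrix(rnorm(n * 4), n, 4)
  F[1:(n - 15), 3] <- target[16:n]      # channel 3 leads target by 150 ms
  rows <- 101:2900
  X <- embed_lags(F, lag_design(1:4), rows)
  cors <- abs(cor(X, target[rows]))
  best <- which.max(cors)
  expect_equal(best, (3 - 1) * 7 + 4)    # channel 3 at tau = 150 ms
  expect_gt(cors[best], 0.999)
})

test_that("OLS recovers exact linear combinations and rejects mismatches", {
  set.seed(4)
  X <- matrix(rnorm(500 * 20), 500, 20)
  b <- rnorm(20)
  w <- fit_decoder(X, drop(X %*% b) + 1.5)
  expect_lt(max(abs(w$b - b)) / max(abs(b)), 1e-8)
  expect_equal(w$intercept, 1.5, tolerance = 1e-8)
  # target orthogonal to predictors: zero weights, intercept = mean
  y0 <- stats::residuals(stats::lm.fit(cbind(1, X), rnorm(500)))
  w0 <- fit_decoder(X, y0 + 2)
  expect_lt(max(abs(w0$b)), 1e-8)
  expect_equal(w0$intercept, 2, tolerance = 1e-8)
  # rank-deficient design falls back to minimum norm with a warning
  Xr <- cbind(X, X[, 1])
  expect_warning(wr <- fit_decoder(Xr, drop(X %*% b)), "minimum-norm")
  expect_equal(drop(cbind(1, Xr) %*% c(wr$intercept, wr$b)),
               drop(X %*% b), tolerance = 1e-6)
  expect_error(fit_decoder(X[1:10, ], rnorm(10)), "rows")
})

test_that("prediction is the fitted linear map", {
  set.seed(5)
  X <- matrix(rnorm(300 * 5), 300, 5)
  y <- rnorm(300)
  w <- fit_decoder(X, y)
  fitted <- predict(w, X)
  # OLS consistency: residuals orthogonal to predictors
  expect_lt(max(abs(crossprod(X, y - fitted))), 1e-8)
  # homogeneity about the intercept
  expect_equal(predict(w, 2 * X) - w$intercept,
               2 * (predict(w, X) - w$intercept), tolerance = 1e-10)
  # zero weights: constant intercept
  w$b[] <- 0
  expect_equal(predict(w, X), rep(w$intercept, 300))
  expect_error(predict(w, X[, 1:3]), "dimension")
})

test_that("postprocessing standardizes then smooths", {
  set.seed(6)
  x <- rnorm(2000, mean = 4, sd = 9)
  p <- postprocess_prediction(x, 100)
  # z-scored before filtering: mean ~0; variance shrinks only by filtering
  expect_lt(abs(mean(p)), 0.01)
  expect_lte(stats::sd(p), 1.001)
  # input well inside the passband passes almost unchanged (z-scoring
  # undoes the uniform passband gain, so postprocessing is idempotent)
  smooth <- zero_phase_filter(rnorm(2000),
                              filter_spec("butterworth", 2, 0.3, "low"), 100)
  p1 <- postprocess_prediction(smooth, 100)
  p2 <- postprocess_prediction(p1, 100)
  expect_lt(sqrt(mean((p2 - p1)^2)) / stats::sd(p1), 0.05)
  expect_error(postprocess_prediction(rep(1, 100), 100), "zero-variance")
})

test_that("pearson_r matches closed forms and the null bound", {
  a <- rnorm(100)
  expect_equal(pearson_r(a, a), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(a, 2 * a + 3), 1)        # affine invariance
  expect_warning(expect_true(is.na(pearson_r(a, rep(1, 100)))), "constant")
  expect_error(pearson_r(a, rnorm(50)), "length")
  # independent white noise: |r| < 2.53/sqrt(n) in ~99% of draws
  set.seed(7)
  hits <- mean(replicate(200, abs(pearson_r(rnorm(1000), rnorm(1000))) < 0.08))
  expect_gte(hits, 0.95)
})

test_that("weights recovered from noisy planted models stay faithful", {
  # snr 10 in the regression sense: var(Xb)/var(noise) = 10
  set.seed(8)
  ok <- vapply(1:10, function(s) {
    X <- matrix(rnorm(2000 * 21), 2000, 21)
    b <- rnorm(21)
    sig <- drop(X %*% b)
    y <- sig + rnorm(2000, sd = stats::sd(sig) / sqrt(10))
    stats::cor(fit_decoder(X, y)$b, b) > 0.9
  }, logical(1))
  expect_true(all(ok))
})

test_that("decoder weights survive a JSON round-trip", {
  set.seed(9)
  X <- matrix(rnorm(200 * 4), 200, 4)
  colnames(X) <- paste0("E", 1:4, "@0ms")
  w <- fit_decoder(X, rnorm(200))
  f <- tempfile(fileext = ".json")
  write_decoder_weights(w, f)
  w2 <- read_decoder_weights(f)
  expect_equal(w2$b, w$b)
  expect_equal(w2$intercept, w$intercept)
})
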