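# Lag-embedded linear decoder: current joint angular velocity modeled as a
# weighted sum of each selected channel's EEG derivative at fixed past
# lags (0-300 ms in 50 ms steps by default), fitted by ordinary least
# squares (Gaussian GLM with identity link).

#' Lag-embedding design
#'
#' @param channels ordered channel indices (columns of the feature matrix)
#'   entering the design.
#' @param lags_ms past lags in ms; must be nonnegative multiples of the
#'   sample period.
#' @param rate feature sampling rate in Hz.
#' @return object of class `lag_design`.
#' @export
lag_design <- function(channels, lags_ms = seq(0, 300, by = 50),
                       rate = 100) {
  if (any(lags_ms < 0)) stop("lags must be nonnegative (past EEG only)")
  samp <- lags_ms * rate / 1000
  if (any(abs(samp - round(samp)) > 1e-9))
    stop("lags must be multiples of the sample period")
  structure(list(channels = as.integer(channels), lags_ms = lags_ms,
                 lag_samples = as.integer(round(samp)),
                 L = length(lags_ms), rate = rate),
            class = "lag_design")
}

#' Build the lagged predictor matrix
#'
#' Row `t` of the result holds the feature value of every design channel
#' at every lag, `S'_i(t - tau_k)`. Column order is channel-major,
#' lag-minor: column `(i-1) * L + k` is channel `i` at lag `k`. Lagged
#' context at segment starts is drawn from the continuous feature matrix
#' preceding the segment (not zero-padded).
#'
#' @param features continuous feature matrix (time x channels) from which
#'   segments are cut.
#' @param design a [lag_design()].
#' @param rows integer vector of (absolute) sample rows to embed, e.g. the
#'   concatenated movement-segment rows.
#' @return predictor matrix with `length(rows)` rows and
#'   `length(channels) * L` columns; column names `"<col>@<lag>ms"`.
#' @export
embed_lags <- function(features, design, rows) {
  stopifnot(inherits(design, "lag_design"))
  features <- as.matrix(features)
  L <- design$L
  ch <- design$channels
  if (any(ch > ncol(features))) stop("design channel outside feature matrix")
  maxlag <- max(design$lag_samples)
  if (min(rows) - maxlag < 1L)
    stop("requested lag exceeds available context before first segment")
  X <- matrix(0, length(rows), length(ch) * L)
  for (k in seq_len(L)) {
    cols <- (seq_along(ch) - 1L) * L + k
    X[, cols] <- features[rows - design$lag_samples[k], ch, drop = FALSE]
  }
  cn <- colnames(features)
  if (is.null(cn)) cn <- paste0("ch", seq_len(ncol(features)))
  colnames(X) <- as.vector(t(outer(cn[ch], design$lags_ms,
                                   function(a, b) paste0(a, "@", b, "ms"))))
  X
}

#' Fit the linear decoder by ordinary least squares
#'
#' Gaussian GLM with identity link: minimizes squared error between the
#' lagged EEG-derivative predictors and the observed joint angular
#' velocity. An intercept is always included. Rank-deficient designs fall
#' back to the minimum-norm solution (with a warning).
#'
#' @param X predictor matrix from [embed_lags()].
#' @param y target velocity series.
#' @param design optional [lag_design()] stored for serialization.
#' @return object of class `decoder_weights` with elements `b`
#'   (named coefficient vector) and `intercept`.
#' @export
fit_decoder <- function(X, y, design = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (nrow(X) < ncol(X) + 1L) stop("need at least as many rows as columns")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("predictors and target must be finite")
  X1 <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X1)
  if (qrX$rank < ncol(X1)) {
    warning("rank-deficient design; returning the minimum-norm solution")
    beta <- MASS::ginv(X1) %*% y
    beta <- drop(beta)
    names(beta) <- colnames(X1)
  } else {
    beta <- qr.coef(qrX, y)
  }
  structure(list(intercept = unname(beta[1]), b = beta[-1],
                 design = design),
            class = "decoder_weights")
}

#' @export
print.decoder_weights <- function(x, ...) {
  cat(sprintf("<decoder_weights> %d coefficients + intercept %.4g\n",
              length(x$b), x$intercept))
  invisible(x)
}

#' Predict joint angular velocity from lagged EEG features
#'
#' @param object a `decoder_weights` fit.
#' @param X predictor matrix with the same column order as at fit time.
#' @param ... unused.
#' @return predicted velocity series.
#' @export
predict.decoder_weights <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$b))
    stop("predictor dimension does not match the fitted weights")
  drop(X %*% object$b) + object$intercept
}

#' Standardize and smooth a predicted trajectory
#'
#' Z-scores the prediction (using its own mean and sd) and applies the
#' same 3 Hz zero-phase first-order Butterworth low-pass used in
#' preprocessing.
#'
#' @param prediction predicted velocity series.
#' @param rate sampling rate in Hz.
#' @return postprocessed series.
#' @export
postprocess_prediction <- function(prediction, rate = 100) {
  s <- stats::sd(prediction)
  if (!is.finite(s) || s == 0) stop("zero-variance prediction")
  z <- (prediction - mean(prediction)) / s
  zero_phase_filter(z, lp_delta_spec(), rate)
}

#' Pearson correlation between observed and predicted trajectories
#'
#' The decoding-accuracy statistic: the product-moment correlation of two
#' equal-length series. Returns `NA` (with a warning) when either series
#' is constant.
#'
#' @param a,b numeric series of equal length (>= 3).
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("correlation undefined for constant input")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Serialize decoder weights to JSON
#'
#' Weights are keyed by `"<channel>@<lag>ms"` so a fit can be re-applied
#' without positional bookkeeping.
#'
#' @param w a `decoder_weights` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decoder_weights <- function(w, path) {
  jsonlite::write_json(list(intercept = w$intercept,
                            b = as.list(w$b)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decoder_weights
#' @export
read_decoder_weights <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = j$intercept, b = unlist(j$b), design = NULL),
            class = "decoder_weights")
}
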