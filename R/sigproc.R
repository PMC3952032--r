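#' Filter specification
#'
#' Describes an IIR filter used in the conditioning chain. Filters are
#' always applied zero-phase (forward-backward), so the effective
#' magnitude response is the squared design response.
#'
#' @param family "butterworth" or "chebyshev2".
#' @param order filter order (of the single-pass design).
#' @param cutoff cutoff (Butterworth) or stopband-edge (Chebyshev II)
#'   frequency in Hz.
#' @param mode "low" or "high".
#' @param stop_atten stopband attenuation in dB (Chebyshev II only).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(family = c("butterworth", "chebyshev2"),
                        order, cutoff, mode = c("low", "high"),
                        stop_atten = 60) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (order < 1 || order != round(order)) stop("order must be integer >= 1")
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(family = family, order = as.integer(order),
                 cutoff = cutoff, mode = mode, stop_atten = stop_atten),
            class = "filter_spec")
}

# squared magnitude response |H(w)|^2 of the bilinear-transformed design,
# evaluated in closed form (w in radians/sample). High-order IIR designs
# expressed as transfer-function coefficients are numerically unusable for
# narrow bands (e.g. an 8th-order 0.1 Hz high-pass at 100 Hz), while the
# warped-frequency magnitude formulas are exact at any order.
squared_magnitude <- function(spec, w, rate) {
  gc <- tan(pi * spec$cutoff / rate)
  g <- tan(w / 2)
  n <- spec$order
  if (spec$family == "butterworth") {
    x <- if (spec$mode == "low") g / gc else gc / g
    return(1 / (1 + x^(2 * n)))
  }
  # Chebyshev II: equiripple stopband beyond the stopband edge `cutoff`
  eps2 <- 1 / (10^(spec$stop_atten / 10) - 1)
  x <- abs(if (spec$mode == "low") gc / g else g / gc)
  Tn <- ifelse(x <= 1, cos(n * acos(pmin(x, 1))),
               cosh(n * acosh(pmax(x, 1))))
  1 / (1 + 1 / (eps2 * Tn^2))
}

#' Zero-phase filtering
#'
#' Applies the designed IIR filter with zero net phase: the series is
#' odd-reflection padded at both edges and multiplied in the frequency
#' domain by the filter's squared magnitude response `|H(f)|^2`, which is
#' the exact transfer function of a forward-backward pass. The magnitude
#' response is evaluated in closed form from the design parameters, which
#' stays exact where high-order recursive filtering (or even the
#' transfer-function coefficients themselves) break down numerically,
#' e.g. the 8th-order 0.1 Hz high-pass at 100 Hz. The pad is at least
#' `3 * (order + 1)`
#' samples and is widened to about three periods of the cutoff frequency
#' for narrow filters, so edge transients die out in the pad. For
#' high-pass filters the series mean is removed first.
#'
#' @param x numeric vector (or matrix, filtered per column).
#' @param spec a [filter_spec()].
#' @param rate sampling rate in Hz.
#' @return filtered series, same length as the input.
#' @export
zero_phase_filter <- function(x, spec, rate) {
  stopifnot(inherits(spec, "filter_spec"))
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  if (n <= 3 * spec$order)
    stop("series too short for the requested filter order")
  if (spec$cutoff >= rate / 2)
    stop("cutoff must lie below the Nyquist frequency")
  if (spec$mode == "high") X <- sweep(X, 2, colMeans(X))
  np <- min(n - 1L,
            max(3L * (spec$order + 1L), ceiling(3 * rate / spec$cutoff)))
  nfft <- stats::nextn(n + 2L * np, c(2, 3, 5))
  # squared magnitude response on the FFT grid
  w <- 2 * pi * (0:(nfft - 1)) / nfft
  H2 <- squared_magnitude(spec, w, rate)
  out <- matrix(0, n, ncol(X))
  for (j0 in seq(1L, ncol(X), by = 16L)) {        # bound memory use
    jj <- j0:min(ncol(X), j0 + 15L)
    XX <- rbind(2 * X[rep(1L, np), jj, drop = FALSE] -
                  X[(np + 1L):2L, jj, drop = FALSE],
                X[, jj, drop = FALSE],
                2 * X[rep(n, np), jj, drop = FALSE] -
                  X[(n - 1L):(n - np), jj, drop = FALSE],
                matrix(0, nfft - n - 2L * np, length(jj)))
    Y <- stats::mvfft(XX) * H2
    y <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
    out[, jj] <- y[(np + 1L):(np + n), , drop = FALSE]
  }
  if (vec) drop(out) else {
    colnames(out) <- colnames(X)
    out
  }
}

# the two delta-band filters used throughout the pipeline
hp_spec <- function() filter_spec("butterworth", 8, 0.1, "high")
lp_delta_spec <- function() filter_spec("butterworth", 1, 3, "low")

#' Antialias and downsample a recording to 100 Hz
#'
#' Applies a zero-phase Chebyshev II low-pass (order 8, 60 dB stopband
#' attenuation, stopband edge 40 Hz) and keeps every `rate/100`-th sample.
#'
#' @param rec an `eeg_recording` whose rate is an integer multiple of
#'   `target_rate`.
#' @param target_rate output rate in Hz (default 100).
#' @return the downsampled recording.
#' @export
antialias_downsample <- function(rec, target_rate = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_stage_new(rec, "downsample")
  fac <- rec$rate / target_rate
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("rate must be an integer multiple of the target rate")
  fac <- as.integer(round(fac))
  spec <- filter_spec("chebyshev2", 8, 40, "low", stop_atten = 60)
  y <- zero_phase_filter(rec$samples, spec, rec$rate)
  idx <- seq(1L, by = fac, length.out = floor(nrow(y) / fac))
  out <- recording(y[idx, , drop = FALSE], target_rate, rec$labels,
                   rec$peripheral, rec$valid, rec$stages)
  add_stage(out, "downsample")
}

#' Shape-preserving upsampling of glove kinematics to a uniform grid
#'
#' Interpolates non-uniformly sampled joint angles with a piecewise cubic
#' Hermite interpolating polynomial (PCHIP), which passes through the
#' samples and never overshoots local extrema, then evaluates on a uniform
#' grid.
#'
#' @param timestamps sample times in seconds, strictly increasing.
#' @param angles joint angles in degrees.
#' @param rate output rate in Hz.
#' @param t_out optional explicit output grid (seconds); values outside the
#'   observed range are clamped to it.
#' @return list with `time` and `angle` on the uniform grid.
#' @export
upsample_kinematics <- function(timestamps, angles, rate = 100,
                                t_out = NULL) {
  if (length(timestamps) != length(angles))
    stop("timestamps and angles must have equal length")
  if (length(timestamps) < 2L) stop("need at least two samples")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (is.null(t_out))
    t_out <- seq(timestamps[1], timestamps[length(timestamps)], by = 1 / rate)
  tq <- pmin(pmax(t_out, timestamps[1]), timestamps[length(timestamps)])
  list(time = t_out, angle = pracma::pchip(timestamps, angles, tq))
}

#' First-difference derivative
#'
#' First difference scaled by the sampling rate. The output is aligned to
#' the input length by repeating the first value, so EEG and kinematics
#' keep identical lengths with at most half a sample of phase offset.
#'
#' @param x numeric vector (or matrix, per column).
#' @param rate sampling rate in Hz.
#' @return derivative series, same length as input.
#' @export
differentiate <- function(x, rate) {
  if (is.matrix(x)) {
    if (nrow(x) < 2L) stop("need at least 2 samples")
    d <- diff(x) * rate
    return(rbind(d[1, , drop = FALSE], d))
  }
  if (length(x) < 2L) stop("need at least 2 samples")
  d <- diff(x) * rate
  c(d[1], d)
}

#' Movement-period segmentation with per-channel standardization
#'
#' Extracts, for every trial, the movement period from `margin` seconds
#' before onset to `margin` seconds after offset, concatenates the
#' segments, baseline-corrects each kinematic segment by its mean over the
#' pre-onset window, and z-scores each EEG channel across the
#' concatenation. Standardization statistics may be supplied (e.g. from
#' training trials) so held-out data is scaled without leakage.
#'
#' @param features numeric matrix, time x channels, at `rate` Hz.
#' @param kin numeric kinematic series, same length.
#' @param trials data.frame with `onset_sample` and `offset_sample`
#'   (1-based indices at `rate`).
#' @param rate sampling rate in Hz.
#' @param margin segment margin in seconds (default 0.1).
#' @param stats optional list with `mean` and `sd` per channel to reuse.
#' @return list with `X` (concatenated standardized features), `kin`
#'   (concatenated baseline-corrected kinematics), `trial_id`, `rows`
#'   (source row index of every concatenated sample), `segments`
#'   (per-trial start/end rows in the source series) and `stats`.
#'   Windows are half-open, so each trial contributes
#'   `offset - onset + 2 * margin * rate` samples.
#' @export
segment_and_standardize <- function(features, kin, trials, rate = 100,
                                    margin = 0.1, stats = NULL) {
  features <- as.matrix(features)
  if (length(kin) != nrow(features))
    stop("features and kin must have the same length")
  m <- as.integer(round(margin * rate))
  keep <- logical(nrow(trials))
  seg <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    s <- as.integer(trials$onset_sample[i]) - m
    e <- as.integer(trials$offset_sample[i]) + m - 1L
    if (s < 1L + m || e > nrow(features)) {
      warning(sprintf("trial %d dropped: segment margin out of range", i))
      next
    }
    keep[i] <- TRUE
    seg[[i]] <- c(s, e)
  }
  seg <- seg[keep]
  if (!length(seg)) stop("no trial survived segmentation")
  rows <- unlist(lapply(seg, function(se) se[1]:se[2]))
  trial_id <- rep(seq_along(seg),
                  vapply(seg, function(se) se[2] - se[1] + 1L, integer(1)))
  X <- features[rows, , drop = FALSE]
  # kinematic baseline: mean over [-margin, 0) s relative to onset
  kcat <- kin[rows]
  for (i in seq_along(seg)) {
    on <- seg[[i]][1] + m               # onset sample
    base <- mean(kin[(on - m):(on - 1L)])
    kcat[trial_id == i] <- kcat[trial_id == i] - base
  }
  if (is.null(stats)) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    stats <- list(mean = mu, sd = sdv)
  }
  sdv <- stats$sd
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2, stats$mean), 2, sdv, "/")
  list(X = X, kin = kcat, trial_id = trial_id, rows = rows,
       segments = do.call(rbind, seg), stats = stats,
       kept_trials = which(keep))
}
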