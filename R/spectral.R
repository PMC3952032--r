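# Movement-locked band-power changes (alpha ERD, beta ERS), per-lag
# delta-band correlation maps, and grand averages.

#' Extract rest / movement / end periods around each trial
#'
#' Per trial and channel, cuts three 1 s windows: rest (-1.5 to -0.5 s
#' relative to movement onset), movement (0.5 to 1.5 s after onset) and
#' end (0 to 1 s after movement offset). Windows are linearly detrended on
#' extraction. Trials whose windows run outside the recording or overlap
#' a neighbouring trial's movement period are dropped with a warning.
#'
#' @param samples numeric matrix (time x channels) at `rate` Hz, e.g. the
#'   rejected + common-average-referenced recording (broadband, not
#'   delta-filtered).
#' @param trials a `trial_table` (onset/offset samples at `rate`).
#' @param rate sampling rate in Hz.
#' @return list of arrays `rest`, `movement`, `end`, each
#'   trials x samples x channels, plus `kept` (retained trial indices).
#' @export
extract_periods <- function(samples, trials, rate = 100) {
  samples <- as.matrix(samples)
  w <- as.integer(round(rate))            # 1 s windows
  n <- nrow(samples)
  nch <- ncol(samples)
  spans <- lapply(seq_len(nrow(trials)), function(i) {
    on <- trials$onset_sample[i]
    off <- trials$offset_sample[i]
    list(rest = c(on - 1.5 * rate, on - 0.5 * rate - 1),
         movement = c(on + 0.5 * rate, on + 1.5 * rate - 1),
         end = c(off, off + rate - 1))
  })
  keep <- vapply(seq_along(spans), function(i) {
    s <- spans[[i]]
    lo <- s$rest[1]
    hi <- max(s$movement[2], s$end[2])
    if (lo < 1 || hi > n) return(FALSE)
    # rest window must not touch the previous trial's movement/rebound
    if (i > 1 && lo <= trials$offset_sample[i - 1] + rate) return(FALSE)
    TRUE
  }, logical(1))
  if (!all(keep))
    warning(sprintf("%d trial(s) dropped: period windows out of range",
                    sum(!keep)))
  kept <- which(keep)
  if (!length(kept)) stop("no trial has complete period windows")
  detrend_win <- function(M) {
    t0 <- seq_len(nrow(M))
    stats::residuals(stats::lm.fit(cbind(1, t0), M))
  }
  grab <- function(which_p) {
    arr <- array(0, c(length(kept), w, nch))
    for (j in seq_along(kept)) {
      sp <- spans[[kept[j]]][[which_p]]
      arr[j, , ] <- detrend_win(samples[sp[1]:sp[2], , drop = FALSE])
    }
    arr
  }
  list(rest = grab("rest"), movement = grab("movement"), end = grab("end"),
       kept = kept, rate = rate)
}

# mean multitaper band power for every (trial, channel) window in an array
band_power_array <- function(arr, rate, band, nw = 4, nfft = 512) {
  d <- dim(arr)                 # trials x samples x channels
  M <- matrix(aperm(arr, c(2, 1, 3)), nrow = d[2])   # samples x (tr*ch)
  psd <- mtm_psd_columns(M, rate, nw = nw, nfft = nfft)
  freq <- seq(0, rate / 2, length.out = nfft %/% 2 + 1)
  sel <- freq >= band[1] & freq <= band[2]
  matrix(colMeans(psd[sel, , drop = FALSE]), d[1], d[3])
}

#' Alpha ERD and beta ERS per trial and channel
#'
#' Event-related desynchronization/synchronization as relative band-power
#' changes: `alpha_erd = (P_movement - P_rest) / P_rest` over 8-13 Hz
#' (negative values = desynchronization during movement) and
#' `beta_ers = (P_end - P_movement) / P_movement` over 20-30 Hz (positive
#' values = post-movement rebound). Band power is the mean multitaper
#' density over the band's frequency bins (time-bandwidth product 4,
#' transform length 512). Being power ratios, both are invariant to a
#' per-channel gain.
#'
#' @param periods output of [extract_periods()].
#' @param alpha_band,beta_band frequency bands in Hz.
#' @param nw,nfft multitaper parameters.
#' @return list with matrices `alpha_erd` and `beta_ers`
#'   (trials x channels); entries with zero reference power are `NA`.
#' @export
erd_ers <- function(periods, alpha_band = c(8, 13), beta_band = c(20, 30),
                    nw = 4, nfft = 512) {
  rate <- periods$rate
  pr <- band_power_array(periods$rest, rate, alpha_band, nw, nfft)
  pm_a <- band_power_array(periods$movement, rate, alpha_band, nw, nfft)
  pm_b <- band_power_array(periods$movement, rate, beta_band, nw, nfft)
  pe <- band_power_array(periods$end, rate, beta_band, nw, nfft)
  alpha_erd <- (pm_a - pr) / pr
  beta_ers <- (pe - pm_b) / pm_b
  alpha_erd[pr == 0] <- NA
  beta_ers[pm_b == 0] <- NA
  list(alpha_erd = alpha_erd, beta_ers = beta_ers)
}

#' Exact two-sided sign test
#'
#' Binomial test on the signs of the values (zeros excluded): is the
#' median different from zero? Chosen over the t-test because band-power
#' ratios are strongly skewed across trials.
#'
#' @param values numeric vector.
#' @return two-sided p-value (1 when all values are zero).
#' @export
sign_test <- function(values) {
  v <- values[!is.na(values) & values != 0]
  if (!length(v)) return(1)
  stats::binom.test(sum(v > 0), length(v), p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Per-channel, per-lag correlation maps between EEG features and velocity
#'
#' For every trial, channel and lag, the Pearson correlation between the
#' lag-shifted preprocessed EEG derivative and the movement-period
#' kinematic velocity; summarized per (channel, lag) by the median across
#' trials and a sign test against a zero-median distribution.
#'
#' @param features preprocessed EEG derivative matrix (time x channels),
#'   identical to the decoder's input.
#' @param velocity preprocessed kinematic velocity (same length).
#' @param trials a `trial_table`.
#' @param lags_ms lag grid in ms.
#' @param rate sampling rate in Hz.
#' @param margin segment margin in seconds.
#' @param alpha significance level for the per-channel flags.
#' @return data.frame of class `scalp_stat_map` with columns `channel`,
#'   `lag_ms`, `median_r`, `p`, `significant`; the per-trial correlation
#'   array (trials x channels x lags) is attached as attribute `"r"`.
#' @export
lag_correlation_maps <- function(features, velocity, trials,
                                 lags_ms = seq(0, 300, by = 50),
                                 rate = 100, margin = 0.1, alpha = 0.05) {
  features <- as.matrix(features)
  m <- as.integer(round(margin * rate))
  lag_samp <- as.integer(round(lags_ms * rate / 1000))
  keep <- trials$onset_sample - m - max(lag_samp) >= 1 &
    trials$offset_sample + m <= nrow(features)
  if (!all(keep))
    warning(sprintf("%d trial(s) dropped: segment shorter than max lag",
                    sum(!keep)))
  tt <- trials[keep, ]
  nch <- ncol(features)
  rarr <- array(NA_real_, c(nrow(tt), nch, length(lags_ms)))
  for (i in seq_len(nrow(tt))) {
    seg <- (tt$onset_sample[i] - m):(tt$offset_sample[i] + m)
    y <- velocity[seg]
    if (stats::sd(y) == 0) next
    for (k in seq_along(lag_samp)) {
      Xk <- features[seg - lag_samp[k], , drop = FALSE]
      sds <- apply(Xk, 2, stats::sd)
      r <- suppressWarnings(as.vector(stats::cor(Xk, y)))
      r[sds == 0] <- NA
      rarr[i, , k] <- r
    }
  }
  lab <- colnames(features)
  if (is.null(lab)) lab <- paste0("ch", seq_len(nch))
  out <- do.call(rbind, lapply(seq_along(lags_ms), function(k) {
    data.frame(channel = lab, lag_ms = lags_ms[k],
               median_r = apply(rarr[, , k, drop = FALSE], 2, stats::median,
                                na.rm = TRUE),
               p = apply(rarr[, , k, drop = FALSE], 2,
                         function(v) sign_test(v)),
               stringsAsFactors = FALSE)
  }))
  out$significant <- out$p < alpha
  class(out) <- c("scalp_stat_map", "data.frame")
  attr(out, "r") <- rarr
  out
}

#' Movement-locked grand averages of EEG and kinematics
#'
#' Segments every channel (and the kinematic trace) from -1.5 to 3 s
#' around movement onset, baseline-corrects each trial by its mean over
#' -1.5 to -0.5 s, averages across trials, and z-scores the averaged
#' traces. Pass delta-band signals plus angle for a position comparison,
#' or derivative features plus velocity for a velocity comparison.
#'
#' @param signals matrix (time x channels).
#' @param kin kinematic series (same length).
#' @param trials a `trial_table`.
#' @param rate sampling rate in Hz.
#' @param window segment window relative to onset (s).
#' @param baseline baseline window relative to onset (s).
#' @return list with `time` (s, relative to onset), `eeg`
#'   (samples x channels), `kin`, and `n_trials` used.
#' @export
grand_average <- function(signals, kin, trials, rate = 100,
                          window = c(-1.5, 3), baseline = c(-1.5, -0.5)) {
  signals <- as.matrix(signals)
  w0 <- as.integer(round(window[1] * rate))
  w1 <- as.integer(round(window[2] * rate))
  b0 <- as.integer(round(baseline[1] * rate))
  b1 <- as.integer(round(baseline[2] * rate))
  keep <- trials$onset_sample + w0 >= 1 &
    trials$onset_sample + w1 <= nrow(signals)
  tt <- trials[keep, ]
  if (nrow(tt) < 10)
    warning("fewer than 10 valid trials in the grand average")
  if (!nrow(tt)) stop("no trial fits the averaging window")
  nsamp <- w1 - w0 + 1L
  acc_e <- matrix(0, nsamp, ncol(signals))
  acc_k <- numeric(nsamp)
  for (i in seq_len(nrow(tt))) {
    on <- tt$onset_sample[i]
    rows <- (on + w0):(on + w1)
    brows <- (on + b0):(on + b1)
    acc_e <- acc_e + sweep(signals[rows, , drop = FALSE], 2,
                           colMeans(signals[brows, , drop = FALSE]))
    acc_k <- acc_k + (kin[rows] - mean(kin[brows]))
  }
  acc_e <- acc_e / nrow(tt)
  acc_k <- acc_k / nrow(tt)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (s == 0) x - mean(x) else (x - mean(x)) / s
  }
  list(time = (w0:w1) / rate, eeg = apply(acc_e, 2, zscore),
       kin = zscore(acc_k), n_trials = nrow(tt))
}
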