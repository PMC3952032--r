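# Synthetic EEG + kinematics sessions with planted, recoverable structure.
#
# A session emulates a self-paced finger-tapping experiment: ~100 trials of
# three raised-cosine taps, glove angles sampled non-uniformly at 35-70 Hz
# with 0.93 degree quantization, and 65-channel EEG at 500 Hz consisting of
# 1/f background, a planted delta-band lagged copy of the kinematic
# velocity on a few central channels, alpha suppression during movement,
# beta rebound after movement offset, and drift/ocular artifacts confined
# to the 18 peripheral rim channels.

#' Tapping-task parameters
#'
#' Defaults follow the pooled behavioral statistics of a self-paced
#' three-tap task: rest around -18.6 deg, extension around +18.6 deg
#' (range of motion ~37 deg; both aligned to the 0.93 deg glove grid so
#' the resting trace quantizes without bias), trial length 1.84 +/-
#' 0.48 s (truncated at 0.5 s), and self-paced inter-trial rests
#' averaging 4 s.
#'
#' @param rest_angle resting joint angle (degrees).
#' @param extension_angle peak extension angle (degrees), `>= rest_angle`.
#' @param taps_per_trial taps per trial (default 3).
#' @param trial_length_mean,trial_length_sd trial duration distribution (s).
#' @param inter_trial_rest_mean mean inter-trial rest (s).
#' @param n_trials number of trials.
#' @return object of class `tap_params`.
#' @export
tap_params <- function(rest_angle = -18.6, extension_angle = 18.6,
                       taps_per_trial = 3, trial_length_mean = 1.84,
                       trial_length_sd = 0.48, inter_trial_rest_mean = 4,
                       n_trials = 100) {
  if (extension_angle < rest_angle)
    stop("extension_angle must be >= rest_angle")
  if (taps_per_trial < 1) stop("taps_per_trial must be >= 1")
  if (trial_length_mean <= 0) stop("trial_length_mean must be positive")
  if (trial_length_sd < 0) stop("trial_length_sd must be nonnegative")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (inter_trial_rest_mean <= 0)
    stop("inter_trial_rest_mean must be positive")
  structure(list(rest_angle = rest_angle, extension_angle = extension_angle,
                 taps_per_trial = as.integer(taps_per_trial),
                 trial_length_mean = trial_length_mean,
                 trial_length_sd = trial_length_sd,
                 inter_trial_rest_mean = inter_trial_rest_mean,
                 n_trials = as.integer(n_trials)),
            class = "tap_params")
}

# draw trial lengths and inter-trial gaps from the current RNG stream;
# gaps keep a 2.5 s floor so rest-window analyses always have room
draw_tap_schedule <- function(params) {
  draw_len <- function() {
    for (i in 1:1000) {
      l <- stats::rnorm(1, params$trial_length_mean, params$trial_length_sd)
      if (l >= 0.5) return(l)
    }
    stop("could not draw a positive trial length; check tap parameters")
  }
  lens <- vapply(seq_len(params$n_trials), function(i) draw_len(), numeric(1))
  floor_gap <- 2.5
  mg <- params$inter_trial_rest_mean
  draw_gap <- function(n) {
    if (mg > floor_gap) floor_gap + stats::rexp(n, 1 / (mg - floor_gap))
    else rep(mg, n)
  }
  gaps <- draw_gap(params$n_trials)        # gap after each trial
  lead_in <- max(4, draw_gap(1))
  starts <- lead_in + cumsum(c(0, (lens + gaps)[-params$n_trials]))
  list(lead_in = lead_in, lengths = lens, gaps = gaps, starts = starts,
       duration = lead_in + sum(lens + gaps) + 1)
}

# render the raised-cosine tap train at a given rate
render_tap_trajectory <- function(schedule, params, rate) {
  n <- as.integer(round(schedule$duration * rate))
  t <- (seq_len(n) - 1) / rate
  angle <- rep(params$rest_angle, n)
  rom <- params$extension_angle - params$rest_angle
  for (i in seq_along(schedule$starts)) {
    s <- schedule$starts[i]
    len <- schedule$lengths[i]
    d <- len / params$taps_per_trial
    in_tr <- t >= s & t < s + len
    u <- (t[in_tr] - s) %% d
    angle[in_tr] <- params$rest_angle + rom * 0.5 * (1 - cos(2 * pi * u / d))
  }
  bounds <- cbind(start = as.integer(round(schedule$starts * rate)) + 1L,
                  end = as.integer(round((schedule$starts +
                                            schedule$lengths) * rate)))
  list(angle = angle, rate = rate, trial_bounds = bounds)
}

#' Generate a synthetic finger-tapping angle trajectory
#'
#' Trials are trains of `taps_per_trial` raised-cosine flexion-extension
#' pulses; between trials the trace rests at `rest_angle`. Raised cosines
#' are smooth and band-limited, keeping 95% of the trajectory's spectral
#' power below 3 Hz at physiological tapping speeds.
#'
#' @param params a [tap_params()] object.
#' @param rate output sampling rate in Hz (default 100).
#' @param seed RNG seed (required; runs must be reproducible).
#' @return list with `angle` (degrees), `rate`, `trial_bounds` (matrix of
#'   true pulse-train start/end samples) and `schedule`.
#' @export
generate_tap_trajectory <- function(params, rate = 100, seed) {
  if (missing(seed)) stop("seed is required for reproducibility")
  stopifnot(inherits(params, "tap_params"))
  set.seed(seed)
  schedule <- draw_tap_schedule(params)
  out <- render_tap_trajectory(schedule, params, rate)
  out$schedule <- schedule
  out$params <- params
  out
}

#' Planted EEG-to-kinematics coupling specification
#'
#' Each coupled channel carries a copy of the delta-band joint-angle
#' trajectory leading the kinematics by one fixed lag; after the
#' pipeline's derivative transform the channel's feature is then the
#' lagged kinematic velocity, so the decoding model class (current
#' velocity as a weighted sum of past EEG derivatives) holds exactly. `snr` is the ratio of the coupled-component variance to the
#' background variance, measured in the decoder's feature domain over
#' movement segments and summed over channels, so the attainable decoding
#' correlation is `sqrt(snr / (1 + snr))`.
#'
#' @param channels labels of coupled (non-peripheral) channels.
#' @param lags_ms per-channel lead of the EEG copy, in ms (on the decoder
#'   lag grid).
#' @param weights relative per-channel coupling weights.
#' @param snr planted signal-to-background ratio (>= 0).
#' @return object of class `coupling_spec`.
#' @export
coupling_spec <- function(channels, lags_ms, weights = rep(1, length(channels)),
                          snr = 1) {
  if (length(lags_ms) != length(channels) ||
      length(weights) != length(channels))
    stop("channels, lags_ms and weights must have equal length")
  if (any(lags_ms < 0)) stop("lags must be nonnegative (EEG leads kinematics)")
  if (snr < 0) stop("snr must be nonnegative")
  structure(list(channels = as.character(channels), lags_ms = lags_ms,
                 weights = weights, snr = snr),
            class = "coupling_spec")
}

#' @rdname coupling_spec
#' @param montage montage data.frame.
#' @export
default_coupling <- function(montage = default_montage(), snr = 1) {
  ch <- default_coupled_channels(montage, 3)
  coupling_spec(ch, lags_ms = c(50, 100, 150), weights = c(1, 1, 1),
                snr = snr)
}

# colored noise with a 1/f amplitude spectrum above f_floor, unit
# variance; synthesized at a fast composite FFT length and truncated
one_over_f_noise <- function(n, rate, f_floor = 0.1) {
  nf <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(nf)
  X <- stats::fft(w)
  k <- 0:(nf - 1)
  f <- pmin(k, nf - k) * rate / nf
  shape <- 1 / sqrt(pmax(f, f_floor))
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE))[seq_len(n)] / nf
  x / stats::sd(x)
}

# spatial mixing matrix: row-normalized Gaussian kernel on montage coords
spatial_mixing <- function(montage, sigma) {
  if (sigma <= 0) return(diag(nrow(montage)))
  d2 <- outer(montage$x, montage$x, "-")^2 + outer(montage$y, montage$y, "-")^2
  K <- exp(-d2 / (2 * sigma^2))
  K / rowSums(K)
}

# deterministic per-channel transform from raw 500 Hz samples to the
# decoder's feature domain (100 Hz delta-band derivative); CAR excluded
feature_transform_500 <- function(x500, rate = 500, target = 100) {
  fac <- as.integer(round(rate / target))
  y <- zero_phase_filter(x500, filter_spec("chebyshev2", 8, 40, "low"), rate)
  y <- y[seq(1L, by = fac, length.out = floor(length(y) / fac))]
  y <- zero_phase_filter(y, hp_spec(), target)
  y <- zero_phase_filter(y, lp_delta_spec(), target)
  differentiate(y, target)
}

# rows of the movement-segment mask at 100 Hz
movement_mask_100 <- function(bounds100, n100, margin_samp = 10L) {
  rows <- unlist(lapply(seq_len(nrow(bounds100)), function(i) {
    max(1L, bounds100[i, 1] - margin_samp):min(n100, bounds100[i, 2] +
                                                 margin_samp)
  }))
  unique(rows)
}

shift_left <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  c(x[(k + 1):n], rep(0, k))
}

#' Generate a full synthetic EEG + kinematics session
#'
#' Produces a 500 Hz multichannel EEG recording, a non-uniformly sampled
#' quantized glove trace, and the ground truth needed to validate the
#' decoding pipeline (planted coupling, attainable correlation ceiling,
#' true trial bounds, modulation periods).
#'
#' The EEG is the sum of (i) spatially smoothed 1/f background, (ii) on
#' the coupled channels, the 3 Hz-low-passed joint-angle trajectory
#' shifted into the future by each channel's lag and scaled so the
#' planted feature-domain SNR equals `coupling$snr`, (iii) alpha-band (default
#' 10 Hz) oscillations on central channels whose amplitude is multiplied
#' by `alpha_movement_factor` during movement, (iv) beta-band (default
#' 25 Hz) oscillations whose amplitude is multiplied by
#' `beta_rebound_factor` in the 1 s after movement offset, and (v) drift
#' and blink-like transients confined to the peripheral rim channels.
#'
#' @param tap a [tap_params()] object.
#' @param coupling a [coupling_spec()] object (snr 0 plants nothing).
#' @param seed RNG seed (required).
#' @param montage montage data.frame (labels, coordinates, peripheral).
#' @param eeg_rate EEG sampling rate in Hz (default 500).
#' @param alpha_freq,alpha_amp,alpha_movement_factor alpha oscillation
#'   frequency (Hz), resting amplitude (units of background sd) and
#'   amplitude factor during movement (default 0.5: halved).
#' @param beta_freq,beta_amp,beta_rebound_factor,beta_rebound_s beta
#'   oscillation parameters; amplitude is multiplied by the rebound factor
#'   for `beta_rebound_s` seconds after movement offset.
#' @param modulated_channels labels carrying the alpha/beta modulation.
#' @param spatial_sigma Gaussian width of the background spatial mixing
#'   kernel (montage units; 0 disables mixing).
#' @param artifact_blink_amp,artifact_blink_rate,artifact_drift_amp,artifact_kin_coupling
#'   parameters forwarded to [plant_artifacts()].
#' @param glove_quantum glove angular resolution in degrees.
#' @return object of class `tap_session`: list with `eeg`
#'   (an `eeg_recording` at `eeg_rate`), `glove` (list of `time`,
#'   `angle`), `truth` (ground truth list) and `montage`.
#' @export
generate_session <- function(tap = tap_params(),
                             coupling = default_coupling(montage),
                             seed,
                             montage = default_montage(),
                             eeg_rate = 500,
                             alpha_freq = 10, alpha_amp = 2,
                             alpha_movement_factor = 0.5,
                             beta_freq = 25, beta_amp = 1.5,
                             beta_rebound_factor = 2, beta_rebound_s = 1,
                             modulated_channels =
                               default_modulated_channels(montage),
                             spatial_sigma = 0.12,
                             artifact_blink_amp = 4,
                             artifact_blink_rate = 0.1,
                             artifact_drift_amp = 2,
                             artifact_kin_coupling = 0,
                             glove_quantum = 0.93) {
  if (missing(seed)) stop("seed is required for reproducibility")
  stopifnot(inherits(tap, "tap_params"), inherits(coupling, "coupling_spec"))
  periph_labels <- montage$label[montage$peripheral]
  if (any(coupling$channels %in% periph_labels))
    stop("coupled channels must be non-peripheral")
  if (!all(coupling$channels %in% montage$label))
    stop("unknown coupled channel label")
  set.seed(seed)

  schedule <- draw_tap_schedule(tap)
  tr500 <- render_tap_trajectory(schedule, tap, eeg_rate)
  tr100 <- render_tap_trajectory(schedule, tap, 100)
  n500 <- length(tr500$angle)
  n100 <- length(tr100$angle)
  nch <- nrow(montage)

  # --- background: spatially smoothed 1/f processes -----------------------
  B <- matrix(0, n500, nch)
  for (j in seq_len(nch)) B[, j] <- one_over_f_noise(n500, eeg_rate)
  M <- spatial_mixing(montage, spatial_sigma)
  B <- B %*% t(M)
  B <- sweep(B, 2, apply(B, 2, stats::sd), "/")

  # --- alpha / beta oscillations with movement-locked envelopes -----------
  t500 <- (seq_len(n500) - 1) / eeg_rate
  mod_idx <- match(modulated_channels, montage$label)
  if (anyNA(mod_idx)) stop("unknown modulated channel label")
  alpha_env <- rep(1, n500)
  beta_env <- rep(1, n500)
  for (i in seq_len(nrow(tr500$trial_bounds))) {
    s <- tr500$trial_bounds[i, 1]
    e <- tr500$trial_bounds[i, 2]
    alpha_env[s:e] <- alpha_movement_factor
    re <- min(n500, e + as.integer(round(beta_rebound_s * eeg_rate)))
    beta_env[(e + 1):re] <- beta_rebound_factor
  }
  # 100 ms ramps so the envelopes are not step discontinuities
  k <- as.integer(round(0.1 * eeg_rate))
  smooth_env <- function(env) {
    s <- stats::filter(env, rep(1 / k, k), sides = 2)
    s[is.na(s)] <- env[is.na(s)]
    as.numeric(s)
  }
  alpha_env <- smooth_env(alpha_env)
  beta_env <- smooth_env(beta_env)
  for (j in mod_idx) {
    B[, j] <- B[, j] +
      alpha_amp * alpha_env * sin(2 * pi * alpha_freq * t500 +
                                    stats::runif(1, 0, 2 * pi)) +
      beta_amp * beta_env * sin(2 * pi * beta_freq * t500 +
                                  stats::runif(1, 0, 2 * pi))
  }

  # --- planted coupling, calibrated in the feature domain -----------------
  # the raw injected component is position-shaped (delta-band angle):
  # after the pipeline's derivative the EEG feature is then velocity-shaped,
  # i.e. exactly the decoder's target up to the planted lag
  p500 <- zero_phase_filter(tr500$angle - tap$rest_angle,
                            lp_delta_spec(), eeg_rate)
  truth_weights <- rep(0, length(coupling$channels))
  if (coupling$snr > 0 && length(coupling$channels) > 0 &&
      max(abs(p500)) > 0) {
    cp_idx <- match(coupling$channels, montage$label)
    lag_samp <- as.integer(round(coupling$lags_ms * eeg_rate / 1000))
    mask <- movement_mask_100(tr100$trial_bounds, n100)
    ratio <- numeric(length(cp_idx))
    sigs <- vector("list", length(cp_idx))
    for (m in seq_along(cp_idx)) {
      sigs[[m]] <- shift_left(p500, lag_samp[m])
      q <- stats::var(feature_transform_500(sigs[[m]], eeg_rate)[mask])
      b <- stats::var(feature_transform_500(B[, cp_idx[m]], eeg_rate)[mask])
      ratio[m] <- coupling$weights[m]^2 * q / b
    }
    alpha_scale <- sqrt(coupling$snr / sum(ratio))
    truth_weights <- alpha_scale * coupling$weights
    for (m in seq_along(cp_idx))
      B[, cp_idx[m]] <- B[, cp_idx[m]] + truth_weights[m] * sigs[[m]]
  }

  eeg <- recording(B, eeg_rate, montage$label,
                   peripheral = montage$peripheral)

  # --- peripheral-only artifacts ------------------------------------------
  # movement-locked artifact waveform: the normalized tap pulse train
  # (facial/ocular activity time-locked to the taps)
  kin_art <- if (max(abs(p500)) > 0) p500 / max(abs(p500)) else p500

  eeg <- plant_artifacts(eeg, blink_amplitude = artifact_blink_amp,
                         blink_rate = artifact_blink_rate,
                         drift_amplitude = artifact_drift_amp,
                         kin_coupling = artifact_kin_coupling,
                         kin_signal = kin_art,
                         front_y = montage$y)

  # --- glove sampling: non-uniform 35-70 Hz, quantized --------------------
  dur <- (n500 - 1) / eeg_rate
  dt <- stats::runif(ceiling(dur * 70) + 10, 1 / 70, 1 / 35)
  ts <- c(0, cumsum(dt))
  ts <- ts[ts < dur]
  ts <- c(ts, dur)
  ga <- stats::approx((seq_len(n500) - 1) / eeg_rate, tr500$angle,
                      xout = ts)$y
  ga <- round(ga / glove_quantum) * glove_quantum

  truth <- structure(list(
    coupling = list(channels = coupling$channels,
                    lags_ms = coupling$lags_ms,
                    weights = truth_weights, snr = coupling$snr),
    r_ceiling = sqrt(coupling$snr / (1 + coupling$snr)),
    trial_bounds_true = tr100$trial_bounds,
    trial_bounds_true_raw = tr500$trial_bounds,
    modulated_channels = modulated_channels,
    alpha = list(freq = alpha_freq, amp = alpha_amp,
                 movement_factor = alpha_movement_factor),
    beta = list(freq = beta_freq, amp = beta_amp,
                rebound_factor = beta_rebound_factor,
                rebound_s = beta_rebound_s),
    schedule = schedule, seed = seed), class = "session_truth")

  structure(list(eeg = eeg, glove = list(time = ts, angle = ga),
                 truth = truth, montage = montage),
            class = "tap_session")
}

#' @export
print.tap_session <- function(x, ...) {
  cat(sprintf("<tap_session> %d trials, %d EEG channels @ %g Hz, %.0f s\n",
              nrow(x$truth$trial_bounds_true), ncol(x$eeg$samples),
              x$eeg$rate, nrow(x$eeg$samples) / x$eeg$rate))
  cat(sprintf("  planted snr %.3g on {%s}; r ceiling %.3f\n",
              x$truth$coupling$snr,
              paste(x$truth$coupling$channels, collapse = ", "),
              x$truth$r_ceiling))
  invisible(x)
}

#' Add drift and ocular-type artifacts to peripheral channels
#'
#' Adds slow drift and brief blink-like transients to the peripheral rim
#' channels only; non-peripheral channels are returned bit-identical.
#' Optionally a fraction of a movement-locked signal can be mixed in
#' (`kin_coupling`) to emulate task-correlated facial/ocular activity.
#'
#' @param rec an `eeg_recording`.
#' @param blink_amplitude transient amplitude (background-sd units).
#' @param blink_rate transients per second.
#' @param drift_amplitude sd of the slow drift component.
#' @param kin_coupling amplitude of the movement-locked component.
#' @param kin_signal movement-locked signal (length of the recording);
#'   required when `kin_coupling > 0`.
#' @param front_y optional per-channel y coordinate; frontal channels
#'   (y > 0.5) get full blink amplitude, others 30%.
#' @param seed optional seed; by default draws from the current RNG stream.
#' @return the recording with artifacts planted.
#' @export
plant_artifacts <- function(rec, blink_amplitude = 4, blink_rate = 0.1,
                            drift_amplitude = 2, kin_coupling = 0,
                            kin_signal = NULL, front_y = NULL,
                            seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(seed)) set.seed(seed)
  per <- which(rec$peripheral)
  if (!length(per)) return(rec)
  n <- n_samples(rec)
  rate <- rec$rate
  if (kin_coupling > 0 && is.null(kin_signal))
    stop("kin_signal required when kin_coupling > 0")
  t0 <- (seq_len(n) - 1) / rate
  for (j in per) {
    x <- numeric(n)
    if (drift_amplitude > 0) {
      d <- zero_phase_filter(stats::rnorm(n),
                             filter_spec("butterworth", 2, 0.3, "low"), rate)
      x <- x + drift_amplitude * d / stats::sd(d)
    }
    if (blink_amplitude > 0 && blink_rate > 0) {
      nb <- stats::rpois(1, blink_rate * n / rate)
      if (nb > 0) {
        ctr <- stats::runif(nb, 0, n / rate)
        amp <- blink_amplitude *
          (if (!is.null(front_y) && front_y[j] <= 0.5) 0.3 else 1)
        for (b in seq_len(nb))
          x <- x + amp * exp(-(t0 - ctr[b])^2 / (2 * 0.08^2))
      }
    }
    if (kin_coupling > 0)
      x <- x + kin_coupling * kin_signal
    rec$samples[, j] <- rec$samples[, j] + x
  }
  rec
}
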