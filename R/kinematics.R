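# Trial boundary detection and per-trial kinematic statistics.

#' Detect movement onset and offset by the 5% peak-speed rule
#'
#' Within a trial window, movement onset is the first sample whose angular
#' speed (absolute first derivative of the angle) exceeds 5% of the
#' maximum speed in the window; offset is the last such sample. The
#' threshold is relative, so the bounds are invariant to offsets and
#' positive rescalings of the angle trace.
#'
#' @param angle joint-angle series in degrees.
#' @param window integer vector `c(start, end)` of 1-based sample indices
#'   bracketing one trial.
#' @param rate sampling rate in Hz.
#' @param threshold speed fraction (default 0.05).
#' @return list with `onset_sample`, `offset_sample` (absolute indices)
#'   and `max_speed` (deg/s).
#' @export
detect_bounds <- function(angle, window, rate = 100, threshold = 0.05) {
  s <- max(1L, as.integer(window[1]))
  e <- min(length(angle), as.integer(window[2]))
  if (e - s < 3L) stop("trial window too short")
  seg <- angle[s:e]
  speed <- abs(differentiate(seg, rate))
  mx <- max(speed)
  if (mx <= 0) stop("no movement in window (flat trace)")
  above <- which(speed > threshold * mx)
  list(onset_sample = s + above[1] - 1L,
       offset_sample = s + above[length(above)] - 1L,
       max_speed = mx)
}

# local maxima with a prominence floor (fraction of the trace's range)
find_peaks <- function(x, min_prom_frac = 0.1) {
  n <- length(x)
  if (n < 3L) return(integer())
  d <- diff(x)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(idx)) return(integer())
  rng <- diff(range(x))
  if (rng <= 0) return(integer())
  keep <- vapply(idx, function(i) {
    left <- min(x[1:i])
    right <- min(x[i:n])
    (x[i] - max(left, right)) > min_prom_frac * rng
  }, logical(1))
  idx[keep]
}

#' Kinematic statistics of one trial
#'
#' Computes the Table-style per-trial measures: trial length (s), tapping
#' speed (`n_taps / length`, taps/s), resting position (mean angle over
#' the 1 s windows before onset and after offset), extension angle (mean
#' of the `n_taps` largest local maxima inside the trial) and range of
#' motion (extension minus rest). Local maxima require a prominence above
#' 10% of the trace range to suppress quantization jitter.
#'
#' @param angle joint-angle series (degrees).
#' @param onset_sample,offset_sample movement bounds (1-based indices).
#' @param rate sampling rate in Hz.
#' @param n_taps taps per trial (default 3).
#' @return one-row data.frame of trial statistics (`valid` is FALSE when
#'   fewer than `n_taps` local maxima were found).
#' @export
trial_statistics <- function(angle, onset_sample, offset_sample,
                             rate = 100, n_taps = 3) {
  w <- as.integer(round(rate))            # 1 s rest windows
  if (onset_sample - w < 1L || offset_sample + w > length(angle))
    stop("1 s rest margins not available around the trial")
  rest <- mean(c(angle[(onset_sample - w):(onset_sample - 1L)],
                 angle[(offset_sample + 1L):(offset_sample + w)]))
  seg <- angle[onset_sample:offset_sample]
  pk <- find_peaks(seg, 0.1)
  valid <- length(pk) >= n_taps
  ext <- if (length(pk)) {
    mean(sort(seg[pk], decreasing = TRUE)[seq_len(min(n_taps, length(pk)))])
  } else NA_real_
  len <- (offset_sample - onset_sample) / rate
  data.frame(onset_sample = onset_sample, offset_sample = offset_sample,
             trial_length = len, tapping_speed = n_taps / len,
             rest_position = rest, extension_angle = ext,
             rom = ext - rest, n_peaks = length(pk), valid = valid)
}

#' Locate candidate trial windows in an unannotated angle trace
#'
#' Coarse energy scan: angular speed is smoothed with a 0.5 s moving
#' average; contiguous regions above 5% of the global maximum smoothed
#' speed, separated by more than `min_gap` seconds, become candidate
#' windows (expanded by `pad` seconds on both sides).
#'
#' @param angle joint-angle series (degrees).
#' @param rate sampling rate in Hz.
#' @param min_gap minimum silent gap between trials (s).
#' @param pad window expansion (s).
#' @return matrix with columns `start`, `end` (sample indices).
#' @export
locate_trial_windows <- function(angle, rate = 100, min_gap = 1, pad = 0.5) {
  speed <- abs(differentiate(angle, rate))
  k <- as.integer(round(0.5 * rate))
  sm <- stats::filter(speed, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  on <- sm > 0.05 * max(sm)
  r <- rle(as.vector(on))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  act <- which(r$values)
  if (!length(act)) stop("no movement found")
  win <- cbind(starts[act], ends[act])
  # merge windows separated by less than min_gap
  merged <- win[1, , drop = FALSE]
  if (nrow(win) > 1) for (i in 2:nrow(win)) {
    if (win[i, 1] - merged[nrow(merged), 2] < min_gap * rate) {
      merged[nrow(merged), 2] <- win[i, 2]
    } else merged <- rbind(merged, win[i, ])
  }
  p <- as.integer(round(pad * rate))
  merged[, 1] <- pmax(1L, merged[, 1] - p)
  merged[, 2] <- pmin(length(angle), merged[, 2] + p)
  colnames(merged) <- c("start", "end")
  merged
}

#' Build a trial table from an angle trace
#'
#' Applies [detect_bounds()] and [trial_statistics()] to each trial
#' window. Windows may come from session ground truth or from
#' [locate_trial_windows()].
#'
#' @param angle joint-angle series (degrees).
#' @param windows matrix with one row per trial (`start`, `end` samples).
#' @param rate sampling rate in Hz.
#' @param n_taps taps per trial.
#' @return data.frame of class `trial_table`, one row per trial.
#' @export
trial_table <- function(angle, windows, rate = 100, n_taps = 3) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    b <- detect_bounds(angle, windows[i, ], rate)
    trial_statistics(angle, b$onset_sample, b$offset_sample, rate, n_taps)
  })
  out <- do.call(rbind, rows)
  out$trial <- seq_len(nrow(out))
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Across-trial summary of kinematic statistics
#'
#' Mean, standard deviation and coefficient of variation (sd / |mean|) of
#' each per-trial measure. The CoV is reported missing when the mean is
#' zero.
#'
#' @param tt a `trial_table` (or data.frame of trial statistics).
#' @param stats columns to summarize.
#' @return data.frame with one row per statistic.
#' @export
summarize_trials <- function(tt,
                             stats = c("trial_length", "tapping_speed",
                                       "rest_position", "extension_angle",
                                       "rom")) {
  if (nrow(tt) < 2L) stop("need at least 2 trials to summarize")
  rows <- lapply(stats, function(s) {
    v <- tt[[s]]
    m <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    data.frame(statistic = s, mean = m, sd = sdv,
               cov = if (m == 0) NA_real_ else sdv / abs(m))
  })
  do.call(rbind, rows)
}
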