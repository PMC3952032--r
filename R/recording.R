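#' Multichannel uniformly sampled recording
#'
#' Container for a multichannel EEG (or other sensor) time series. Samples
#' are stored time-in-rows, channels-in-columns. Each channel carries a
#' validity flag and a peripheral flag (sensors along frontal/temporal rim
#' that are excluded from decoding but used in artifact-control scenarios).
#'
#' @param samples numeric matrix, time x channels.
#' @param rate sampling rate in Hz.
#' @param labels character vector of channel names, one per column.
#' @param peripheral logical vector, TRUE for rim channels.
#' @param valid logical vector, FALSE for channels flagged bad.
#' @param stages character vector of processing-stage tags already applied.
#'
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(samples, rate, labels,
                      peripheral = rep(FALSE, ncol(samples)),
                      valid = rep(TRUE, ncol(samples)),
                      stages = character()) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  nch <- ncol(samples)
  if (length(labels) != nch) stop("labels length must equal channel count")
  if (length(peripheral) != nch || length(valid) != nch)
    stop("channel masks must match channel count")
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  colnames(samples) <- labels
  structure(
    list(samples = samples, rate = rate, labels = as.character(labels),
         peripheral = as.logical(peripheral), valid = as.logical(valid),
         stages = stages),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$rate,
              nrow(x$samples) / x$rate))
  cat(sprintf("  peripheral: %d, flagged invalid: %d\n",
              sum(x$peripheral), sum(!x$valid)))
  if (length(x$stages))
    cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

n_channels <- function(rec) ncol(rec$samples)
n_samples <- function(rec) nrow(rec$samples)

# each conditioning stage may be applied once; re-application is a
# pipeline-order bug, not a no-op
assert_stage_new <- function(rec, tag) {
  if (tag %in% rec$stages)
    stop(sprintf("stage '%s' already applied to this recording", tag))
}

add_stage <- function(rec, tag) {
  rec$stages <- c(rec$stages, tag)
  rec
}

#' Drop channels from a recording
#'
#' Removes the named channels, e.g. the 18 peripheral rim sensors that are
#' rejected before decoding. With the default 65-sensor montage and no
#' manual rejections this leaves 47 usable channels.
#'
#' @param rec an `eeg_recording`.
#' @param reject character vector of channel labels (or integer indices).
#' @return the recording without the rejected channels.
#' @export
reject_channels <- function(rec, reject) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.numeric(reject)) {
    if (any(reject < 1 | reject > n_channels(rec)))
      stop("channel index out of range")
    idx <- as.integer(reject)
  } else {
    idx <- match(reject, rec$labels)
    if (anyNA(idx))
      stop("unknown channel label(s): ",
           paste(reject[is.na(idx)], collapse = ", "))
  }
  keep <- setdiff(seq_len(n_channels(rec)), idx)
  if (length(keep) == 0L) stop("rejecting all channels leaves nothing")
  out <- recording(rec$samples[, keep, drop = FALSE], rec$rate,
                   rec$labels[keep], rec$peripheral[keep], rec$valid[keep],
                   rec$stages)
  add_stage(out, paste0("reject:", length(idx)))
}

#' Keep only the named channels (complement of [reject_channels()])
#' @inheritParams reject_channels
#' @param keep labels or indices of channels to retain.
#' @return the recording restricted to `keep`, in montage order.
#' @export
keep_channels <- function(rec, keep) {
  if (is.numeric(keep)) {
    drop_idx <- setdiff(seq_len(n_channels(rec)), as.integer(keep))
  } else {
    idx <- match(keep, rec$labels)
    if (anyNA(idx)) stop("unknown channel label(s)")
    drop_idx <- setdiff(seq_len(n_channels(rec)), idx)
  }
  if (length(drop_idx) == 0L) return(rec)
  reject_channels(rec, drop_idx)
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across valid channels
#' from every channel. After referencing the per-sample mean of valid
#' channels is zero.
#'
#' @param rec an `eeg_recording` with at least two valid channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_stage_new(rec, "car")
  use <- which(rec$valid)
  if (length(use) < 2L)
    stop("common average reference needs at least 2 valid channels")
  avg <- rowMeans(rec$samples[, use, drop = FALSE])
  rec$samples <- rec$samples - avg
  add_stage(rec, "car")
}
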