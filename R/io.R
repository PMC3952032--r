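# Plain-text formats: EEG matrices, glove tables, trial tables, ground
# truth, run configuration, and the summary report.

#' Write / read an EEG recording as a delimited matrix
#'
#' Tab-separated values, one column per channel (header = labels), with
#' the sampling rate and channel masks in `#`-prefixed header lines.
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @param digits signif digits for the samples.
#' @return `path` / the recording.
#' @export
write_eeg_table <- function(rec, path, digits = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz: %g", rec$rate),
               paste0("# peripheral: ",
                      paste(as.integer(rec$peripheral), collapse = ",")),
               paste0("# valid: ",
                      paste(as.integer(rec$valid), collapse = ","))), con)
  utils::write.table(signif(rec$samples, digits), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eeg_table
#' @export
read_eeg_table <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  rate <- get("rate_hz")
  if (is.null(rate)) stop("EEG table is missing the '# rate_hz:' header")
  rate <- as.numeric(rate)
  if (!is.finite(rate)) stop("unparseable sampling rate")
  tab <- utils::read.delim(path, comment.char = "#",
                           check.names = FALSE)
  if (!nrow(tab)) stop("EEG table contains no samples")
  parse_mask <- function(key, default) {
    v <- get(key)
    if (is.null(v)) return(default)
    as.logical(as.integer(strsplit(v, ",")[[1]]))
  }
  nch <- ncol(tab)
  recording(as.matrix(tab), rate, names(tab),
            peripheral = parse_mask("peripheral", rep(FALSE, nch)),
            valid = parse_mask("valid", rep(TRUE, nch)))
}

#' Write / read a glove kinematics table
#'
#' Two-column tab-separated table (`timestamp_s`, `angle_deg`) with
#' strictly increasing timestamps; quantized angles survive the
#' round-trip on their grid.
#'
#' @param time timestamps in seconds.
#' @param angle joint angles in degrees.
#' @param path file path.
#' @return `path` / list with `time` and `angle`.
#' @export
write_glove <- function(time, angle, path) {
  if (length(time) != length(angle)) stop("time/angle length mismatch")
  utils::write.table(data.frame(timestamp_s = time, angle_deg = angle),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_glove
#' @export
read_glove <- function(path) {
  tab <- tryCatch(utils::read.delim(path), error = function(e)
    stop("unreadable glove table: ", conditionMessage(e)))
  if (!nrow(tab)) stop("glove table is empty")
  if (!all(c("timestamp_s", "angle_deg") %in% names(tab)))
    stop("glove table must have columns timestamp_s, angle_deg")
  if (any(diff(tab$timestamp_s) <= 0))
    stop("glove timestamps must be strictly increasing")
  list(time = tab$timestamp_s, angle = tab$angle_deg)
}

#' Write / read a trial table
#' @param tt a `trial_table`.
#' @param path file path.
#' @return `path` / the trial table.
#' @export
write_trial_table <- function(tt, path) {
  utils::write.table(as.data.frame(tt), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.delim(path)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Run configuration with validated defaults
#'
#' All stage parameters of the pipeline in one list. Unknown keys are
#' rejected so silently misspelled options cannot pass through. Defaults
#' are the pipeline's standard analysis settings.
#'
#' @param ... overrides of the default entries.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    scenario = "unmodified",
    seed = 1L,
    eeg_rate = 500, work_rate = 100,
    highpass_hz = 0.1, highpass_order = 8,
    lowpass_hz = 3, lowpass_order = 1,
    antialias_hz = 40, antialias_order = 8, antialias_atten_db = 60,
    lags_ms = seq(0, 300, by = 50),
    n_outer_folds = 10, n_inner_folds = 8,
    segment_margin_s = 0.1,
    ga = unclass(ga_config()),
    onset_threshold = 0.05,
    alpha_band = c(8, 13), beta_band = c(20, 30),
    mtm_nw = 4, mtm_nfft = 512,
    eeg_path = NULL, glove_path = NULL, montage_path = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if ("ga" %in% names(over)) {
    unknown_ga <- setdiff(names(over$ga), names(defaults$ga))
    if (length(unknown_ga))
      stop("unknown GA key(s): ", paste(unknown_ga, collapse = ", "))
    defaults$ga[names(over$ga)] <- over$ga
    over$ga <- NULL
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j)
}

#' Summary report of a decoding run
#'
#' Deterministic summary: per-fold r table, the r quartile summary
#' (min / Q1 / median / Q3 / max), and the channel-selection histogram
#' with binomial significance flags.
#'
#' @param results a `cv_result` from [outer_cv()] (or a list of them).
#' @return object of class `decode_report`.
#' @export
decode_report <- function(results) {
  if (inherits(results, "cv_result")) results <- list(results)
  if (!length(results) || !sum(vapply(results, nrow, integer(1)))) {
    warning("empty results; returning an empty report")
    return(structure(list(folds = NULL, quartiles = NULL,
                          selection = NULL), class = "decode_report"))
  }
  folds <- do.call(rbind, lapply(results, as.data.frame))
  r <- folds$r[!is.na(folds$r)]
  q <- stats::quantile(r, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  quart <- data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                      max = q[5])
  masks <- do.call(rbind, lapply(results, attr, "masks"))
  sel <- if (!is.null(masks))
    selection_histogram(masks, attr(results[[1]], "labels")) else NULL
  structure(list(folds = folds, quartiles = quart, selection = sel),
            class = "decode_report")
}

#' @export
print.decode_report <- function(x, ...) {
  if (is.null(x$folds)) {
    cat("<decode_report> (empty)\n")
    return(invisible(x))
  }
  cat("<decode_report>\n")
  cat(sprintf("  %d folds; decoding accuracy r: min %.2f / Q1 %.2f / median %.2f / Q3 %.2f / max %.2f\n",
              nrow(x$folds), x$quartiles$min, x$quartiles$q1,
              x$quartiles$median, x$quartiles$q3, x$quartiles$max))
  if (!is.null(x$selection)) {
    ns <- sum(x$selection$selected)
    cat(sprintf("  channels above the binomial selection threshold (count >= %d): %d\n",
                attr(x$selection, "threshold"), ns))
  }
  invisible(x)
}

#' Write session ground truth to JSON
#' @param truth a `session_truth`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(coupling = truth$coupling, r_ceiling = truth$r_ceiling,
              trial_bounds_true = truth$trial_bounds_true,
              modulated_channels = truth$modulated_channels,
              alpha = truth$alpha, beta = truth$beta, seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
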