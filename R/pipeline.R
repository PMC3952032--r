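# Outer 10-fold cross-validation with GA channel selection, decoding
# scenarios, and cross-scenario statistics.
#
# Per outer fold the full lagged design (all channels x all lags, plus
# intercept) is embedded once and summarized by per-trial Gram matrices;
# a channel mask's inner-CV fitness then reduces to masked solves of the
# summed normal equations, which makes the GA affordable.

#' Scenario-specific preprocessed EEG features
#'
#' Applies the conditioning chain (antialias + downsample to 100 Hz,
#' channel rejection, common average reference, 0.1 Hz high-pass, 3 Hz
#' low-pass, derivative) for one decoding scenario:
#' \describe{
#'   \item{unmodified}{non-peripheral channels, full chain (the standard
#'     decoding input);}
#'   \item{peripheral}{only the 18 peripheral rim channels, without
#'     common average referencing (so ocular artifacts do not spread);}
#'   \item{rest}{identical features to `unmodified`; the rest-period
#'     window substitution happens at segmentation time in [outer_cv()].}
#' }
#'
#' @param session a `tap_session` (or an `eeg_recording` at 500 Hz).
#' @param scenario one of "unmodified", "peripheral", "rest".
#' @param manual_reject additional channel labels to drop.
#' @return list with `F` (derivative features, time x channels), `delta`
#'   (pre-derivative delta-band signals), `labels`, `rate`, `scenario`.
#' @export
scenario_features <- function(session,
                              scenario = c("unmodified", "peripheral",
                                           "rest"),
                              manual_reject = NULL) {
  scenario <- match.arg(scenario)
  rec <- if (inherits(session, "tap_session")) session$eeg else session
  stopifnot(inherits(rec, "eeg_recording"))
  down <- antialias_downsample(rec, 100)
  if (scenario == "peripheral") {
    rec2 <- keep_channels(down, which(down$peripheral))
  } else {
    drop <- unique(c(down$labels[down$peripheral], manual_reject))
    rec2 <- reject_channels(down, drop)
    rec2 <- common_average_reference(rec2)
  }
  delta <- zero_phase_filter(rec2$samples, hp_spec(), 100)
  delta <- zero_phase_filter(delta, lp_delta_spec(), 100)
  F <- differentiate(delta, 100)
  colnames(F) <- colnames(delta) <- rec2$labels
  list(F = F, delta = delta, labels = rec2$labels, rate = 100,
       scenario = scenario)
}

#' Preprocess the glove kinematics of a session
#'
#' PCHIP-upsamples the non-uniform glove samples onto the 100 Hz EEG
#' grid, low-passes at 3 Hz (smoothing the quantization steps) and
#' differentiates.
#'
#' @param session a `tap_session`.
#' @return list with `time`, `angle_raw` (upsampled angle before
#'   smoothing; used for trial statistics), `position` (delta-band angle,
#'   degrees) and `velocity` (deg/s), at 100 Hz aligned to the EEG.
#' @export
preprocess_kinematics <- function(session) {
  stopifnot(inherits(session, "tap_session"))
  n100 <- floor(n_samples(session$eeg) / (session$eeg$rate / 100))
  grid <- (seq_len(n100) - 1) / 100
  up <- upsample_kinematics(session$glove$time, session$glove$angle,
                            rate = 100, t_out = grid)
  pos <- zero_phase_filter(up$angle, lp_delta_spec(), 100)
  list(time = grid, angle_raw = up$angle, position = pos,
       velocity = differentiate(pos, 100))
}

#' Trial table of a synthetic session
#'
#' Applies the 5% peak-speed rule within windows around the ground-truth
#' trial bounds.
#'
#' @param session a `tap_session`.
#' @param kin optional precomputed [preprocess_kinematics()] output.
#' @param pad window padding around the true bounds (s).
#' @return a `trial_table`.
#' @export
session_trial_table <- function(session, kin = NULL, pad = 0.5) {
  if (is.null(kin)) kin <- preprocess_kinematics(session)
  tb <- session$truth$trial_bounds_true
  p <- as.integer(round(pad * 100))
  windows <- cbind(pmax(1L, tb[, 1] - p),
                   pmin(length(kin$angle_raw), tb[, 2] + p))
  trial_table(kin$angle_raw, windows, rate = 100, n_taps = 3)
}

# contiguous near-equal split of n items into k groups
split_contiguous <- function(n, k) {
  split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
}

# solve symmetric normal equations; jitter then pseudo-inverse fallback
solve_sym <- function(A, b) {
  out <- tryCatch(drop(chol2inv(chol(A)) %*% b), error = function(e) NULL)
  if (!is.null(out)) return(out)
  out <- tryCatch({
    drop(chol2inv(chol(A + diag(1e-8 * mean(diag(A)), nrow(A)))) %*% b)
  }, error = function(e) NULL)
  if (!is.null(out)) return(out)
  drop(MASS::ginv(A) %*% b)
}

# segment row indices for one trial under a scenario (half-open windows)
trial_rows_for <- function(onset, offset, margin, scenario) {
  mv <- (onset - margin):(offset + margin - 1L)
  if (scenario == "rest") {
    len <- length(mv)
    feat <- (onset - margin - len):(onset - margin - 1L)
  } else feat <- mv
  list(feat = feat, kin = mv)
}

#' Outer cross-validated decoding with GA channel selection
#'
#' Runs the full decoding analysis on one session: per outer fold, the GA
#' (fitness: median Pearson r over `inner_folds` inner cross-validation
#' folds of the training trials) selects a channel subset; the decoder is
#' then fitted by OLS on all training trials and evaluated as the
#' correlation between the postprocessed predicted and observed
#' velocities over the concatenated test trials. No test-fold data enters
#' channel-standardization statistics, GA fitness, or the final fit.
#'
#' In the "rest" scenario the EEG features of every trial are taken from
#' the rest window of identical length ending 0.1 s before movement
#' onset, while the target remains the movement-period velocity.
#'
#' @param session a `tap_session`.
#' @param scenario decoding scenario (see [scenario_features()]).
#' @param seed seed for fold shuffling and the GA streams (required).
#' @param ga_cfg a [ga_config()]; reduce `max_generations` for quick runs.
#' @param lags_ms decoder lag grid (ms).
#' @param n_folds outer folds (default 10).
#' @param inner_folds inner folds for the GA fitness (default 8).
#' @param shuffle randomize trial-to-fold assignment (default FALSE:
#'   contiguous blocks in session order).
#' @param trials optional `trial_table` (detected from the session when
#'   NULL).
#' @param manual_reject extra channels to drop.
#' @param use_ga set FALSE to skip channel selection and decode with
#'   `fixed_mask`.
#' @param fixed_mask logical channel mask (or labels) used when
#'   `use_ga = FALSE`; NULL means all channels.
#' @return data.frame of class `cv_result` with one row per fold:
#'   `fold`, `scenario`, `r` (outer test correlation), `inner_r` (best GA
#'   fitness), `n_selected`, `generations`. Selected masks are attached
#'   as attribute `"masks"` (folds x channels), labels as `"labels"`.
#' @export
outer_cv <- function(session, scenario = "unmodified", seed,
                     ga_cfg = ga_config(), lags_ms = seq(0, 300, by = 50),
                     n_folds = 10, inner_folds = 8, shuffle = FALSE,
                     trials = NULL, manual_reject = NULL,
                     use_ga = TRUE, fixed_mask = NULL) {
  if (missing(seed)) stop("seed is required for reproducibility")
  set.seed(seed)
  feats <- scenario_features(session, scenario, manual_reject)
  kin <- preprocess_kinematics(session)
  if (is.null(trials)) trials <- session_trial_table(session, kin)
  n_tr <- nrow(trials)
  if (n_tr < 20) stop("cross-validation needs at least 20 trials")
  margin <- 10L                      # 0.1 s at 100 Hz
  maxlag <- max(lags_ms) / 1000 * 100
  nch <- ncol(feats$F)
  L <- length(lags_ms)

  # per-trial segment rows; drop trials without room for margins/context
  rows <- vector("list", n_tr)
  ok <- logical(n_tr)
  for (i in seq_len(n_tr)) {
    r <- trial_rows_for(trials$onset_sample[i], trials$offset_sample[i],
                        margin, scenario)
    if (min(r$feat) - maxlag >= 1 && max(r$feat) <= nrow(feats$F) &&
        max(r$kin) <= nrow(feats$F)) {
      rows[[i]] <- r
      ok[i] <- TRUE
    }
  }
  if (!all(ok))
    warning(sprintf("%d trial(s) dropped: insufficient context", sum(!ok)))
  rows <- rows[ok]
  n_tr <- length(rows)
  fold_of <- if (shuffle) {
    sample(rep(seq_len(n_folds), length.out = n_tr))
  } else as.integer(cut(seq_len(n_tr), n_folds, labels = FALSE))

  feat_rows <- unlist(lapply(rows, `[[`, "feat"))
  kin_rows <- unlist(lapply(rows, `[[`, "kin"))
  seg_len <- vapply(rows, function(r) length(r$feat), integer(1))
  trial_id <- rep(seq_len(n_tr), seg_len)
  # per-trial kinematic baseline: mean velocity over [-0.1, 0) s
  y_all <- kin$velocity[kin_rows]
  for (i in seq_len(n_tr)) {
    on <- rows[[i]]$kin[1] + margin
    y_all[trial_id == i] <- y_all[trial_id == i] -
      mean(kin$velocity[(on - margin):(on - 1L)])
  }

  design <- lag_design(seq_len(nch), lags_ms, rate = 100)
  if (!is.null(fixed_mask) && !is.logical(fixed_mask))
    fixed_mask <- feats$labels %in% fixed_mask

  res <- vector("list", n_folds)
  masks <- matrix(FALSE, n_folds, nch)
  for (f in seq_len(n_folds)) {
    test_tr <- which(fold_of == f)
    train_tr <- setdiff(seq_len(n_tr), test_tr)
    train_rows_cat <- which(trial_id %in% train_tr)
    # channel standardization from training segments only
    Ftr <- feats$F[feat_rows[train_rows_cat], , drop = FALSE]
    mu <- colMeans(Ftr)
    sdv <- apply(Ftr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Fs <- sweep(sweep(feats$F, 2, mu), 2, sdv, "/")
    X <- cbind(1, embed_lags(Fs, design, feat_rows))
    # per-trial Gram summaries of the full design
    G <- vector("list", n_tr)
    g <- vector("list", n_tr)
    for (i in seq_len(n_tr)) {
      ri <- which(trial_id == i)
      G[[i]] <- crossprod(X[ri, , drop = FALSE])
      g[[i]] <- crossprod(X[ri, , drop = FALSE], y_all[ri])
    }
    inner <- split_contiguous(length(train_tr), inner_folds)
    inner_data <- lapply(inner, function(ix) {
      itest <- train_tr[ix]
      itrain <- setdiff(train_tr, itest)
      list(A = Reduce(`+`, G[itrain]), b = Reduce(`+`, g[itrain]),
           test_rows = which(trial_id %in% itest))
    })
    mask_cols <- function(mask) c(1L, 1L + which(rep(mask, each = L)))
    fitness <- function(mask) {
      idx <- mask_cols(mask)
      rs <- vapply(inner_data, function(d) {
        beta <- solve_sym(d$A[idx, idx], d$b[idx])
        pred <- drop(X[d$test_rows, idx, drop = FALSE] %*% beta)
        post <- tryCatch(postprocess_prediction(pred, 100),
                         error = function(e) NULL)
        if (is.null(post)) return(-1)
        r <- suppressWarnings(pearson_r(post, y_all[d$test_rows]))
        if (is.na(r)) -1 else r
      }, numeric(1))
      stats::median(rs)
    }
    if (use_ga) {
      ga <- run_ga(fitness, nch, ga_cfg)
      mask <- ga$best_mask
      inner_r <- ga$best_fitness
      gens <- ga$generations
    } else {
      mask <- if (is.null(fixed_mask)) rep(TRUE, nch) else fixed_mask
      inner_r <- fitness(mask)
      gens <- 0L
    }
    masks[f, ] <- mask
    idx <- mask_cols(mask)
    A <- Reduce(`+`, G[train_tr])
    b <- Reduce(`+`, g[train_tr])
    beta <- solve_sym(A[idx, idx], b[idx])
    test_rows <- which(trial_id %in% test_tr)
    pred <- drop(X[test_rows, idx, drop = FALSE] %*% beta)
    r <- tryCatch({
      post <- postprocess_prediction(pred, 100)
      suppressWarnings(pearson_r(post, y_all[test_rows]))
    }, error = function(e) NA_real_)
    res[[f]] <- data.frame(fold = f, scenario = scenario, r = r,
                           inner_r = inner_r, n_selected = sum(mask),
                           generations = gens)
  }
  out <- do.call(rbind, res)
  class(out) <- c("cv_result", "data.frame")
  attr(out, "masks") <- masks
  attr(out, "labels") <- feats$labels
  attr(out, "fold_of") <- fold_of
  out
}

#' GA channel selection on one training set
#'
#' Runs a single genetic-algorithm channel search on a set of training
#' trials (by default all trials of the session), with the same
#' inner-cross-validation fitness as [outer_cv()]. Useful for channel
#' recovery experiments across independently generated sessions, where
#' each run sees genuinely independent background noise.
#'
#' @inheritParams outer_cv
#' @return the [run_ga()] result, with the channel labels attached as
#'   attribute `"labels"`.
#' @export
select_channels_ga <- function(session, scenario = "unmodified", seed,
                               ga_cfg = ga_config(),
                               lags_ms = seq(0, 300, by = 50),
                               inner_folds = 8, trials = NULL,
                               manual_reject = NULL) {
  if (missing(seed)) stop("seed is required for reproducibility")
  set.seed(seed)
  feats <- scenario_features(session, scenario, manual_reject)
  kin <- preprocess_kinematics(session)
  if (is.null(trials)) trials <- session_trial_table(session, kin)
  margin <- 10L
  maxlag <- max(lags_ms) / 1000 * 100
  nch <- ncol(feats$F)
  L <- length(lags_ms)
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    r <- trial_rows_for(trials$onset_sample[i], trials$offset_sample[i],
                        margin, scenario)
    if (min(r$feat) - maxlag >= 1 && max(r$feat) <= nrow(feats$F))
      rows[[length(rows) + 1L]] <- r
  }
  n_tr <- length(rows)
  feat_rows <- unlist(lapply(rows, `[[`, "feat"))
  kin_rows <- unlist(lapply(rows, `[[`, "kin"))
  trial_id <- rep(seq_len(n_tr),
                  vapply(rows, function(r) length(r$feat), integer(1)))
  y <- kin$velocity[kin_rows]
  for (i in seq_len(n_tr)) {
    on <- rows[[i]]$kin[1] + margin
    y[trial_id == i] <- y[trial_id == i] -
      mean(kin$velocity[(on - margin):(on - 1L)])
  }
  mu <- colMeans(feats$F[feat_rows, , drop = FALSE])
  sdv <- apply(feats$F[feat_rows, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Fs <- sweep(sweep(feats$F, 2, mu), 2, sdv, "/")
  X <- cbind(1, embed_lags(Fs, lag_design(seq_len(nch), lags_ms), feat_rows))
  G <- lapply(seq_len(n_tr), function(i) {
    ri <- which(trial_id == i)
    list(A = crossprod(X[ri, , drop = FALSE]),
         b = crossprod(X[ri, , drop = FALSE], y[ri]))
  })
  inner <- split_contiguous(n_tr, inner_folds)
  inner_data <- lapply(inner, function(ix) {
    itrain <- setdiff(seq_len(n_tr), ix)
    list(A = Reduce(`+`, lapply(G[itrain], `[[`, "A")),
         b = Reduce(`+`, lapply(G[itrain], `[[`, "b")),
         test_rows = which(trial_id %in% ix))
  })
  fitness <- function(mask) {
    idx <- c(1L, 1L + which(rep(mask, each = L)))
    rs <- vapply(inner_data, function(d) {
      beta <- solve_sym(d$A[idx, idx], d$b[idx])
      pred <- drop(X[d$test_rows, idx, drop = FALSE] %*% beta)
      post <- tryCatch(postprocess_prediction(pred, 100),
                       error = function(e) NULL)
      if (is.null(post)) return(-1)
      r <- suppressWarnings(pearson_r(post, y[d$test_rows]))
      if (is.na(r)) -1 else r
    }, numeric(1))
    stats::median(rs)
  }
  ga <- run_ga(fitness, nch, ga_cfg)
  attr(ga, "labels") <- feats$labels
  ga
}

#' Cross-validated decoding with the planted (true) design
#'
#' Decodes a synthetic session using exactly the ground-truth design:
#' each planted channel at its single planted lag, ordinary least squares
#' on the training trials of each fold, no channel selection, and no
#' extra smoothing of the prediction. Because the true design has one
#' predictor per independent coupled channel, the expected test
#' correlation of the raw prediction is the planted ceiling
#' `sqrt(snr / (1 + snr))`. Richer decoders can exceed that number: the
#' full lag grid whitens the temporally correlated background, and the
#' standard postprocessing low-pass removes out-of-band prediction noise.
#'
#' @param session a `tap_session` with planted coupling.
#' @param seed RNG seed (fold bookkeeping only; the fit is deterministic).
#' @param n_folds outer folds (default 10).
#' @return data.frame with per-fold `r` and the session `r_ceiling`.
#' @export
decode_true_design <- function(session, seed = 1, n_folds = 10) {
  set.seed(seed)
  tc <- session$truth$coupling
  if (!length(tc$channels) || tc$snr <= 0)
    stop("session has no planted coupling")
  feats <- scenario_features(session, "unmodified")
  kin <- preprocess_kinematics(session)
  trials <- session_trial_table(session, kin)
  margin <- 10L
  lag_samp <- as.integer(round(tc$lags_ms / 10))
  ok <- trials$onset_sample - margin - max(lag_samp) >= 1 &
    trials$offset_sample + margin <= nrow(feats$F)
  trials <- trials[ok, ]
  n_tr <- nrow(trials)
  rows <- lapply(seq_len(n_tr), function(i)
    (trials$onset_sample[i] - margin):(trials$offset_sample[i] + margin - 1L))
  feat_rows <- unlist(rows)
  trial_id <- rep(seq_len(n_tr), lengths(rows))
  y <- kin$velocity[feat_rows]
  for (i in seq_len(n_tr)) {
    on <- rows[[i]][1] + margin
    y[trial_id == i] <- y[trial_id == i] -
      mean(kin$velocity[(on - margin):(on - 1L)])
  }
  ch_idx <- match(tc$channels, feats$labels)
  if (anyNA(ch_idx)) stop("planted channel missing from usable features")
  X <- vapply(seq_along(ch_idx), function(m)
    feats$F[feat_rows - lag_samp[m], ch_idx[m]], numeric(length(feat_rows)))
  fold_of <- as.integer(cut(seq_len(n_tr), n_folds, labels = FALSE))
  r <- vapply(seq_len(n_folds), function(f) {
    te <- which(trial_id %in% which(fold_of == f))
    tr <- setdiff(seq_along(feat_rows), te)
    w <- fit_decoder(X[tr, , drop = FALSE], y[tr])
    pred <- predict(w, X[te, , drop = FALSE])
    suppressWarnings(pearson_r(pred, y[te]))
  }, numeric(1))
  data.frame(fold = seq_len(n_folds), r = r,
             r_ceiling = session$truth$r_ceiling)
}

#' Compare decoding accuracies across scenarios
#'
#' Kruskal-Wallis omnibus test over the per-fold r-values of two or more
#' scenarios, followed by pairwise rank-sum tests with Holm correction.
#'
#' @param r_by_scenario named list of numeric r-value vectors (>= 3 values
#'   each).
#' @param alpha significance level for the pairwise flags.
#' @return list with `p_value` (omnibus), `pairwise` (matrix of adjusted
#'   p-values), `significant` (logical matrix) and `method`.
#' @export
compare_scenarios <- function(r_by_scenario, alpha = 0.05) {
  if (length(r_by_scenario) < 2L) stop("need at least 2 scenarios")
  if (any(vapply(r_by_scenario, length, integer(1)) < 3L))
    stop("need at least 3 values per scenario")
  vals <- unlist(r_by_scenario, use.names = FALSE)
  grp <- factor(rep(names(r_by_scenario),
                    vapply(r_by_scenario, length, integer(1))))
  if (length(unique(vals)) == 1L) {
    k <- length(r_by_scenario)
    pw <- matrix(1, k - 1, k - 1)
    return(list(p_value = 1, pairwise = pw, significant = pw < alpha,
                method = "degenerate (all values tied)"))
  }
  kw <- stats::kruskal.test(vals, grp)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(vals, grp, p.adjust.method = "holm",
                                exact = FALSE))$p.value
  list(p_value = kw$p.value, pairwise = pw,
       significant = !is.na(pw) & pw < alpha,
       method = "Kruskal-Wallis omnibus + pairwise rank-sum (Holm)")
}
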