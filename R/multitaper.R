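# Thomson multitaper spectral estimation.
#
# Discrete prolate spheroidal sequences are computed from the classical
# symmetric tridiagonal eigenproblem, which is numerically stable for the
# window lengths used here (<= 512). Tapers are cached per (n, nw, k).

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' @param n window length.
#' @param nw time-bandwidth product.
#' @param k number of tapers (default `2 * nw - 1`).
#' @return n x k matrix of unit-energy tapers, ordered by concentration.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t0 <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- dg
  A[cbind(1:(n - 1), 2:n)] <- od
  A[cbind(2:n, 1:(n - 1))] <- od
  ev <- eigen(A, symmetric = TRUE)
  H <- ev$vectors[, seq_len(k), drop = FALSE]
  # fix sign: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    s <- sum(H[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) H[, j] <- -H[, j]
    } else if (sum((n - t0) * H[, j]) < 0) {
      H[, j] <- -H[, j]
    }
  }
  H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  .dpss_cache[[key]] <- H
  H
}

# multitaper eigenspectra for columns of a matrix, n <= nfft (zero-padded)
mtm_psd_columns <- function(M, rate, nw = 4, nfft = 512, k = 2 * nw - 1) {
  n <- nrow(M)
  if (n > nfft) stop("window longer than nfft")
  H <- dpss_tapers(n, nw, k)
  nf <- nfft %/% 2 + 1
  acc <- matrix(0, nf, ncol(M))
  for (j in seq_len(k)) {
    T <- M * H[, j]
    if (n < nfft) T <- rbind(T, matrix(0, nfft - n, ncol(M)))
    F <- stats::mvfft(T)[seq_len(nf), , drop = FALSE]
    acc <- acc + Mod(F)^2
  }
  acc <- acc / k / rate
  # one-sided density: double everything except DC (and Nyquist if present)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nf] <- 1
  acc * dbl
}

#' Thomson multitaper power spectral density
#'
#' Multitaper PSD with time-bandwidth product `nw` (using `2 nw - 1`
#' tapers) and transform length `nfft`. The series is linearly detrended
#' first. Series longer than `nfft` are split into non-overlapping blocks
#' of `nfft` samples and the eigenspectra are averaged across blocks;
#' shorter series are zero-padded (with a warning). Densities are
#' one-sided, so the spectrum integrates to approximately the series
#' variance.
#'
#' @param x numeric series.
#' @param rate sampling rate in Hz.
#' @param nw time-bandwidth product (default 4).
#' @param nfft transform window length (default 512).
#' @param detrend linearly detrend before tapering (default TRUE).
#' @param quiet suppress the zero-padding warning.
#' @return list with `freq` (Hz) and `psd` (power density, unit^2/Hz).
#' @export
multitaper_psd <- function(x, rate, nw = 4, nfft = 512, detrend = TRUE,
                           quiet = FALSE) {
  n <- length(x)
  if (n < 8L) stop("series too short for spectral estimation")
  if (detrend) {
    t0 <- seq_len(n)
    x <- stats::residuals(stats::lm.fit(cbind(1, t0), x))
  }
  if (n < nfft) {
    if (!quiet)
      warning("series shorter than nfft; zero-padding the taper window")
    M <- matrix(x, ncol = 1)
    psd <- mtm_psd_columns(M, rate, nw, nfft)[, 1]
  } else {
    nb <- n %/% nfft
    M <- matrix(x[seq_len(nb * nfft)], nrow = nfft)
    psd <- rowMeans(mtm_psd_columns(M, rate, nw, nfft))
  }
  freq <- seq(0, rate / 2, length.out = nfft %/% 2 + 1)
  list(freq = freq, psd = psd)
}

#' Frequency capturing a fraction of cumulative spectral power
#'
#' @param freq frequency grid (Hz).
#' @param psd nonnegative power densities on that grid.
#' @param fraction cumulative-power fraction (default 0.95).
#' @return the smallest grid frequency at which the cumulative power
#'   reaches `fraction` of the total.
#' @export
freq_at_cumulative_power <- function(freq, psd, fraction = 0.95) {
  if (length(freq) != length(psd)) stop("freq and psd lengths differ")
  if (any(psd < 0)) stop("psd must be nonnegative")
  tot <- sum(psd)
  if (tot <= 0) stop("zero total power")
  cum <- cumsum(psd)
  freq[which(cum >= fraction * tot)[1]]
}
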