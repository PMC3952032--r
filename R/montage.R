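#' Default 65-sensor scalp montage
#'
#' A synthetic approximation of a 64-channel geodesic sensor net plus the
#' vertex electrode, laid out as concentric rings on the unit disc
#' (top-down view, nose up: x is left(-)/right(+), y is back(-)/front(+)).
#' The 18 outermost sensors along the frontal/temporal rim are flagged
#' peripheral; they are rejected before decoding, leaving 47 usable
#' channels. The geometry is a plausible stand-in, not a vendor layout.
#'
#' @return data.frame with columns `label`, `x`, `y`, `peripheral`.
#' @export
default_montage <- function() {
  ring <- function(n, r, phase = 0) {
    th <- phase + 2 * pi * (seq_len(n) - 1) / n
    # start at the front midline and go clockwise
    data.frame(x = r * sin(th), y = r * cos(th))
  }
  pts <- rbind(
    data.frame(x = 0, y = 0),          # vertex
    ring(6, 0.22),
    ring(12, 0.42, phase = pi / 12),
    ring(16, 0.62),
    ring(12, 0.80, phase = pi / 12),
    ring(18, 1.00)                     # rim: peripheral
  )
  n <- nrow(pts)                       # 65
  lab <- c("Cz", paste0("E", seq_len(n - 1)))
  data.frame(label = lab, x = round(pts$x, 4), y = round(pts$y, 4),
             peripheral = c(rep(FALSE, n - 18), rep(TRUE, 18)),
             stringsAsFactors = FALSE)
}

#' Read / write a montage sidecar table
#'
#' Tab-separated table with columns `label`, `x`, `y`, `peripheral`.
#' @param path file path.
#' @return `read_montage`: the montage data.frame.
#' @export
read_montage <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "peripheral")
  if (!all(need %in% names(m)))
    stop("montage file must have columns: ", paste(need, collapse = ", "))
  m$peripheral <- as.logical(m$peripheral)
  m
}

#' @rdname read_montage
#' @param montage montage data.frame.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Default planted-coupling channels
#'
#' Picks `n` well-separated non-peripheral sensors over the left central
#' scalp (contralateral to a right-hand task), used as the default site of
#' the planted kinematic coupling in synthetic sessions. Channels are
#' chosen greedily to keep pairwise distance large so that the spatially
#' smoothed background noise stays effectively independent between them.
#'
#' @param montage montage data.frame.
#' @param n number of channels.
#' @return character vector of channel labels.
#' @export
default_coupled_channels <- function(montage = default_montage(), n = 3) {
  cand <- montage[!montage$peripheral & montage$x < -0.15 &
                    abs(montage$y) < 0.55, ]
  if (nrow(cand) < n) stop("montage too small for ", n, " coupled channels")
  # greedy max-min-distance selection, seeded at the most central candidate
  d0 <- sqrt((cand$x + 0.45)^2 + cand$y^2)
  sel <- which.min(d0)
  while (length(sel) < n) {
    dmin <- vapply(seq_len(nrow(cand)), function(i) {
      min(sqrt((cand$x[i] - cand$x[sel])^2 + (cand$y[i] - cand$y[sel])^2))
    }, numeric(1))
    dmin[sel] <- -Inf
    sel <- c(sel, which.max(dmin))
  }
  cand$label[sel]
}

#' Default alpha/beta-modulated channels
#'
#' Bilateral central sensors carrying the planted alpha suppression during
#' movement and beta rebound after movement offset.
#'
#' @param montage montage data.frame.
#' @param n_per_side channels per hemisphere.
#' @return character vector of channel labels.
#' @export
default_modulated_channels <- function(montage = default_montage(),
                                       n_per_side = 6) {
  usable <- montage[!montage$peripheral, ]
  pick_side <- function(sgn) {
    d <- sqrt((usable$x - sgn * 0.45)^2 + usable$y^2)
    usable$label[order(d)[seq_len(n_per_side)]]
  }
  c(pick_side(-1), pick_side(1))
}
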