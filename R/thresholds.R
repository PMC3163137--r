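# Classical automatic histogram thresholding: Kapur maximum-entropy (vessel
# walls on the excess-red image) and Tsai moment-preserving (tissue on the
# decimated blue channel).

#' Build a grey-level histogram over the occupied range
#'
#' One bin per integer level between the minimum and maximum observed value.
#' The offset maps bin 1 to its grey value, so signed images (the excess-red
#' transform spans -510..510) are handled without clamping.
#'
#' @param values Integer-valued numeric matrix or vector.
#' @return An object of class `grey_histogram` with fields `counts` and
#'   `level_offset`.
#' @export
grey_histogram <- function(values) {
  v <- as.integer(values)
  if (anyNA(v)) stop("histogram input must not contain NA", call. = FALSE)
  if (length(v) == 0L) stop("histogram input is empty", call. = FALSE)
  off <- min(v)
  counts <- tabulate(v - off + 1L, nbins = max(v) - off + 1L)
  structure(list(counts = counts, level_offset = off),
            class = "grey_histogram")
}

#' @export
print.grey_histogram <- function(x, ...) {
  cat(sprintf("<grey_histogram> levels %d..%d, %d occupied, n = %.0f\n",
              x$level_offset, x$level_offset + length(x$counts) - 1L,
              sum(x$counts > 0), sum(x$counts)))
  invisible(x)
}

hist_levels <- function(hist) {
  hist$level_offset + seq_along(hist$counts) - 1L
}

check_histogram <- function(hist) {
  if (!inherits(hist, "grey_histogram"))
    stop("expected a grey_histogram", call. = FALSE)
  if (sum(hist$counts > 0) < 2L)
    stop("degenerate histogram: fewer than 2 occupied grey levels",
         call. = FALSE)
}

#' Kapur-Sahoo-Wong maximum-entropy threshold
#'
#' Selects the threshold t maximizing the sum of the Shannon entropies of the
#' two classes of the normalized histogram: background (levels <= t) and
#' foreground (levels > t). Candidates leaving either class empty are
#' skipped; ties are broken towards the lowest t, so results are exactly
#' reproducible.
#'
#' @param hist A [grey_histogram].
#' @return Integer threshold on the histogram's grey scale; foreground is
#'   `level > t`.
#' @export
threshold_entropy <- function(hist) {
  check_histogram(hist)
  p <- hist$counts / sum(hist$counts)
  Pb <- cumsum(p)
  Pf <- 1 - Pb
  plogp <- ifelse(p > 0, p * log(p), 0)
  Sb <- cumsum(plogp)
  Sf <- sum(plogp) - Sb
  valid <- Pb > 0 & Pf > 0
  crit <- rep(-Inf, length(p))
  crit[valid] <- (-Sb[valid] / Pb[valid] + log(Pb[valid])) +
                 (-Sf[valid] / Pf[valid] + log(Pf[valid]))
  # lowest t among near-ties, so exact mirror symmetries resolve stably
  hist_levels(hist)[which(crit >= max(crit) - 1e-10)[1]]
}

#' Tsai moment-preserving threshold
#'
#' Finds the two-level image that preserves the first three grey-level
#' moments of the input histogram. The closed form yields representative
#' levels z0 < z1 and a background fraction p0; the threshold is the
#' smallest level whose cumulative histogram fraction reaches p0.
#' Background is `level <= t`.
#'
#' @param hist A [grey_histogram].
#' @return Integer threshold on the histogram's grey scale.
#' @export
threshold_moment <- function(hist) {
  check_histogram(hist)
  p <- hist$counts / sum(hist$counts)
  z <- as.numeric(hist_levels(hist))
  m1 <- sum(p * z); m2 <- sum(p * z^2); m3 <- sum(p * z^3)
  cd <- m2 - m1^2
  if (cd <= 0)
    stop("degenerate histogram: zero variance moment system", call. = FALSE)
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (disc <= 0)
    stop("degenerate histogram: moment system has no real two-level solution",
         call. = FALSE)
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("degenerate histogram: background fraction outside (0, 1)",
         call. = FALSE)
  cumfrac <- cumsum(p)
  idx <- which(cumfrac >= p0 - 1e-12)[1]
  hist_levels(hist)[idx]
}
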