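#' Canonical hemodynamic response function
#'
#' Double-gamma HRF: a positive gamma lobe peaking at `peak_s`, minus an
#' undershoot lobe peaking at `undershoot_s` scaled by `undershoot_ratio`.
#' The kernel starts at 0, is scaled to unit peak, and is truncated at
#' `duration_s` (32 s), by which point its magnitude is far below 1e-3 of
#' peak.
#'
#' @param resolution_ms Sampling resolution in ms; must divide 1000.
#' @param peak_s,undershoot_s Peak times of the two gamma lobes in seconds.
#' @param undershoot_ratio Amplitude ratio of undershoot to peak lobe.
#' @param duration_s Kernel support in seconds.
#' @return Numeric kernel vector with attribute `resolution_ms`.
#' @examples
#' h <- canonical_hrf(10)
#' (which.max(h) - 1) * 10 / 1000  # peaks near 5 s
#' @export
canonical_hrf <- function(resolution_ms = 1, peak_s = 5, undershoot_s = 15,
                          undershoot_ratio = 1 / 6, duration_s = 32) {
  if (resolution_ms < 1 || 1000 %% resolution_ms != 0)
    stop("resolution_ms must be a positive divisor of 1000", call. = FALSE)
  t_s <- seq(0, duration_s, by = resolution_ms / 1000)
  # gamma with scale 1: mode at shape - 1, so shape = peak + 1
  h <- stats::dgamma(t_s, shape = peak_s + 1, scale = 1) -
    undershoot_ratio * stats::dgamma(t_s, shape = undershoot_s + 1, scale = 1)
  h <- h / max(h)
  structure(h, resolution_ms = resolution_ms)
}

# Hemodynamic kernel rearranged for exact TR-point convolution.
# Column k holds the kernel samples at lags (k-1)*spb - (r-1) for
# r = 1..spb, so that (t(N) %*% Hm) summed along its diagonals equals the
# dense convolution evaluated at TR onsets (see tr_band_add).
hrf_tr_matrix <- function(hrf, spb) {
  Lh <- length(hrf)
  K <- (Lh - 2L) %/% spb + 2L
  Hm <- matrix(0, spb, K)
  for (k in seq_len(K)) {
    idx <- (k - 1L) * spb - (seq_len(spb) - 1L) + 1L
    ok <- idx >= 1L & idx <= Lh
    Hm[ok, k] <- hrf[idx[ok]]
  }
  Hm
}

# accumulate the banded product into the TR-resolution output:
# y[b0 + b + k] += M[b, k]
tr_band_add <- function(y, M, b0) {
  nb <- nrow(M)
  n <- length(y)
  for (k in seq_len(ncol(M))) {
    j0 <- b0 + k
    if (j0 > n) break
    j1 <- min(j0 + nb - 1L, n)
    y[j0:j1] <- y[j0:j1] + M[seq_len(j1 - j0 + 1L), k]
  }
  y
}

#' Convolve a neural response with the HRF and sample at TR resolution
#'
#' Computes the dense working-resolution convolution of a neural response
#' with the hemodynamic kernel and samples it at the onset of every TR. The
#' result is exactly the dense convolution evaluated at the TR sample points
#' (the HRF is a strong temporal low-pass filter, so sampling loses
#' essentially nothing).
#'
#' @param neural Numeric vector or (time x category) matrix at working
#'   resolution.
#' @param hrf Hemodynamic kernel from [canonical_hrf()] at the same
#'   resolution; defaults to the canonical double-gamma.
#' @param tr_s Repetition time in seconds (default 1).
#' @param resolution_ms Working resolution of `neural` in ms.
#' @return Predictor of length `duration / tr_s` (or a matrix of them).
#' @export
predict_bold <- function(neural, hrf = NULL, tr_s = 1, resolution_ms = 1) {
  if (is.null(hrf)) hrf <- canonical_hrf(resolution_ms)
  if (!is.null(attr(hrf, "resolution_ms")) &&
      attr(hrf, "resolution_ms") != resolution_ms)
    stop("hrf resolution does not match 'resolution_ms'", call. = FALSE)
  x <- if (is.matrix(neural)) neural else matrix(neural, ncol = 1)
  spb <- as.integer(round(tr_s * 1000 / resolution_ms))
  if (nrow(x) %% spb != 0)
    stop("run duration is not an integer multiple of the TR", call. = FALSE)
  nb <- nrow(x) %/% spb
  Hm <- hrf_tr_matrix(as.numeric(hrf), spb)
  out <- matrix(0, nb, ncol(x), dimnames = list(NULL, colnames(x)))
  for (j in seq_len(ncol(x))) {
    M <- crossprod(matrix(x[, j], spb, nb), Hm)
    out[, j] <- tr_band_add(numeric(nb), M, 0L)
  }
  if (is.matrix(neural)) out else drop(out)
}
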