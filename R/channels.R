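#' Neural impulse response functions for the two temporal channels
#'
#' Builds the millisecond-scale impulse response functions (IRFs) as cascades
#' of leaky integrators, i.e. gamma densities
#' \eqn{h_i(t) = (t/\tau_i)^{n_i - 1} e^{-t/\tau_i} / (\tau_i (n_i-1)!)}.
#' The sustained channel uses the monophasic first filter (`n1` stages, time
#' constant `tau_ms`), normalized to unit area so the response to a long
#' stimulus plateaus at 1. The transient channel is the biphasic difference
#' between the first filter and a second, slower filter (`n2` stages, time
#' constant `kappa * tau_ms`), rescaled so its positive lobe has unit area;
#' its net area is zero, so it responds only at stimulus onsets and offsets.
#'
#' Only `tau_ms` is treated as free during model optimization; `kappa`, `n1`
#' and `n2` are fixed constants of the filter cascade (1.33, 9 and 10).
#'
#' @param tau_ms IRF time constant in ms (optimization bounds 4-20).
#' @param kappa Ratio of the second filter's time constant to `tau_ms`.
#' @param n1,n2 Number of cascade stages of the two filters (`n2 > n1`).
#' @param resolution_ms Sampling resolution; must resolve the sustained peak
#'   with at least 5 samples.
#' @return An `irf_pair` list: `sustained` and `transient` kernel vectors
#'   sampled at bin midpoints, `resolution_ms`, `onset_norm` (peak of the
#'   transient step response, used to normalize transient drive so an
#'   isolated onset peaks at 1) and `normalization` metadata.
#' @examples
#' irf <- make_irfs(4.93)
#' which.max(irf$sustained)  # peak near (n1 - 1) * tau = 39.4 ms
#' @export
make_irfs <- function(tau_ms = 4.93, kappa = 1.33, n1 = 9, n2 = 10,
                      resolution_ms = 1) {
  stopifnot(tau_ms > 0, kappa > 1, n2 > n1, n1 >= 1)
  peak_ms <- (n1 - 1) * tau_ms
  if (peak_ms / resolution_ms < 5)
    stop("resolution_ms = ", resolution_ms, " is too coarse to resolve an IRF ",
         "peaking at ", round(peak_ms, 1), " ms (need >= 5 samples before peak)",
         call. = FALSE)
  # support: keep all but < 1e-6 of the slower filter's mass
  support_ms <- ceiling(stats::qgamma(1 - 1e-7, shape = n2, scale = kappa * tau_ms))
  L <- ceiling(support_ms / resolution_ms)
  t_mid <- (seq_len(L) - 0.5) * resolution_ms
  g1 <- stats::dgamma(t_mid, shape = n1, scale = tau_ms)
  g2 <- stats::dgamma(t_mid, shape = n2, scale = kappa * tau_ms)
  g1 <- g1 / sum(g1)
  g2 <- g2 / sum(g2)
  ht <- g1 - g2
  ht <- ht / sum(ht[ht > 0])
  structure(
    list(sustained = g1, transient = ht, resolution_ms = resolution_ms,
         tau_ms = tau_ms, kappa = kappa, n1 = n1, n2 = n2,
         onset_norm = max(cumsum(ht)),
         normalization = paste("sustained: unit area; transient: unit",
                               "positive-lobe area, drive scaled so an",
                               "isolated onset peaks at 1")),
    class = "irf_pair")
}

#' @export
print.irf_pair <- function(x, ...) {
  cat(sprintf(paste0("Channel IRFs: tau = %.3g ms, kappa = %.3g, n1 = %d, n2 = %d ",
                     "(%d samples at %g ms)\n"),
              x$tau_ms, x$kappa, x$n1, x$n2, length(x$sustained), x$resolution_ms))
  invisible(x)
}

# causal convolution of a piecewise-constant signal with a short kernel,
# truncated to the signal length; exact, via scatter of the signal's jumps
# followed by a cumulative sum (conv(x, k) = cumsum(conv(diff x, k)))
conv_steps <- function(x, kernel) {
  n <- length(x)
  d <- diff(c(0, x))
  pos <- which(d != 0)
  out <- numeric(n + length(kernel))
  for (p in pos)
    out[p:(p + length(kernel) - 1)] <- out[p:(p + length(kernel) - 1)] + d[p] * kernel
  cumsum(out)[seq_len(n)]
}

#' Convolve a stimulus step function with a channel IRF
#'
#' Causal, zero-padded linear convolution of each category's binary stimulus
#' vector with a kernel, truncated to run length. The signal before run start
#' is taken to be zero (runs open with a long blank baseline, so this is
#' benign).
#'
#' @param step A [render_step_function()] matrix (or a numeric vector for a
#'   single channel).
#' @param kernel Kernel vector at the same resolution (e.g. one element of
#'   [make_irfs()]).
#' @return Drive with the same shape as `step`.
#' @export
convolve_channel <- function(step, kernel) {
  if (is.matrix(step)) {
    out <- apply(step, 2, conv_steps, kernel = kernel)
    dimnames(out) <- dimnames(step)
    out
  } else {
    conv_steps(as.numeric(step), kernel)
  }
}

#' Exponential fMRI-adaptation of the sustained drive
#'
#' Multiplies the convolved sustained drive by an exponential decay
#' \eqn{e^{-t/\alpha}} where t is the time elapsed since the most recent
#' stimulus onset; the clock resets at every onset, keeps running through
#' inter-stimulus gaps, and extends to the end of the run after the final
#' stimulus. Before the first onset the multiplier is 1. At `t = alpha_s`
#' seconds after an onset the response has declined to 1/e (~37%) of its
#' unadapted value.
#'
#' @param drive Numeric vector (one category's sustained drive).
#' @param onsets_ms Sorted stimulus onset times in ms on the same clock.
#' @param alpha_s Adaptation time constant in seconds (bounds 10-40).
#' @param resolution_ms Sampling resolution of `drive`.
#' @return The adapted drive.
#' @export
apply_adaptation <- function(drive, onsets_ms, alpha_s, resolution_ms = 1) {
  stopifnot(alpha_s > 0, !is.unsorted(onsets_ms))
  if (length(onsets_ms) == 0) return(drive)
  t_ms <- (seq_along(drive) - 1) * resolution_ms
  drive * adaptation_multiplier(t_ms, onsets_ms, alpha_s)
}

# exp(-(t - last onset)/alpha), 1 before the first onset
adaptation_multiplier <- function(t_ms, onsets_ms, alpha_s) {
  idx <- findInterval(t_ms, onsets_ms)
  m <- numeric(length(t_ms)) + 1
  has <- idx > 0
  m[has] <- exp(-(t_ms[has] - onsets_ms[idx[has]]) / (alpha_s * 1000))
  m
}

#' Compressive temporal summation (CTS) of the sustained drive
#'
#' Static power-law compression `drive ^ epsilon`. Applies only to the
#' (non-negative) sustained channel.
#'
#' @param drive Non-negative drive vector.
#' @param epsilon Compression exponent in (0, 1]; bounds 0.01-1.
#' @return Compressed drive.
#' @export
apply_cts <- function(drive, epsilon) {
  stopifnot(epsilon > 0, epsilon <= 1)
  if (any(drive < -1e-12))
    stop("CTS applies to the non-negative sustained drive only", call. = FALSE)
  pmax(drive, 0)^epsilon
}

#' Asymmetric sigmoid compression of the transient drive
#'
#' Pointwise cumulative-Weibull sigmoids that compress the positive (onset)
#' and negative (offset) lobes of the biphasic transient drive separately:
#' \deqn{\sigma(x) = 1 - e^{-(x/\lambda)^{k_{on}}} \ (x \ge 0), \quad
#'       \sigma(x) = 1 - e^{-(-x/\lambda)^{k_{off}}} \ (x < 0).}
#' Both lobes map to non-negative responses in `[0, 1)`. Smaller shape values
#' `k` produce more compressive nonlinearities that elongate the transient
#' responses.
#'
#' @param x Signed transient drive (normalized so an isolated onset peaks
#'   at 1).
#' @param lam Sigmoid scale, shared between lobes (bounds 0.01-0.5).
#' @param k_on,k_off Shape of the onset / offset compression (bounds 0.1-6).
#' @return Compressed response, same shape as `x`.
#' @export
sigmoid_rectifier <- function(x, lam, k_on, k_off) {
  stopifnot(lam > 0, k_on > 0, k_off > 0)
  if (k_on == k_off) return(1 - exp(-(abs(x) / lam)^k_on))
  k <- k_off + (x >= 0) * (k_on - k_off)
  1 - exp(-(abs(x) / lam)^k)
}

#' Quadratic rectification of the transient drive
#'
#' The simpler alternative transient nonlinearity: pointwise squaring, which
#' maps both lobes of the biphasic drive to non-negative responses.
#'
#' @param x Signed transient drive.
#' @return `x^2`.
#' @export
quadratic_rectifier <- function(x) x^2
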