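#' Onset/offset balance of the transient channel
#'
#' Indexes the relative contribution of stimulus-offset responses as
#' `k_on / (k_on + k_off)`. Because smaller sigmoid shape values elongate
#' transient responses, a balance of 0.5 (`k_on = k_off`) means onset and
#' offset contribute equally, values above 0.5 mean offset-dominant
#' responses, and values below 0.5 mean onset-dominant responses.
#'
#' @param k_on,k_off Sigmoid shape parameters of the onset and offset
#'   compression (both > 0).
#' @return Balance in (0, 1).
#' @examples
#' balance_metric(3, 3)    # 0.5: equal contributions
#' balance_metric(6, 0.1)  # ~0.98: offset-dominant
#' @export
balance_metric <- function(k_on, k_off) {
  if (any(k_on <= 0) || any(k_off <= 0))
    stop("sigmoid shape parameters must be positive", call. = FALSE)
  k_on / (k_on + k_off)
}

#' Sustained/transient channel contribution ratio
#'
#' `|beta_S / beta_T|`: how much of a region's response is carried by the
#' sustained relative to the transient channel.
#'
#' @param beta_S,beta_T Channel weights (same category).
#' @return Non-negative ratio; `NA` where `beta_T` is 0 (undefined, reported
#'   as missing rather than infinite).
#' @export
channel_ratio <- function(beta_S, beta_T) {
  out <- abs(beta_S / beta_T)
  out[beta_T == 0] <- NA_real_
  out
}

#' Contrast effect size of channel weights
#'
#' Category selectivity within one channel: the weight of the preferred
#' category minus the mean weight of the nonpreferred categories.
#'
#' @param betas Channel x category weight matrix (as in `coef(fit)`), or a
#'   named vector of one channel's weights.
#' @param preferred Name of the preferred category.
#' @param channel Channel row to use when `betas` is a matrix.
#' @return Signed effect size (negative when the preferred category's weight
#'   is below the others' mean).
#' @examples
#' contrast_effect_size(c(face = 2, body = 1, word = 0), "face")  # 1.5
#' @export
contrast_effect_size <- function(betas, preferred, channel = NULL) {
  b <- if (is.matrix(betas)) {
    if (is.null(channel)) stop("'channel' is required for a weight matrix",
                               call. = FALSE)
    betas[channel, ]
  } else betas
  if (!preferred %in% names(b))
    stop("preferred category '", preferred, "' not among the weights",
         call. = FALSE)
  unname(b[preferred] - mean(b[setdiff(names(b), preferred)]))
}

#' Peak response amplitude per trial
#'
#' Model-free condition summary: the maximum of an ROI time series within
#' each trial window, extended by a hemodynamic lag to capture the delayed
#' BOLD peak.
#'
#' @param series Numeric ROI time series at TR resolution.
#' @param windows Two-column matrix of trial `[start, end]` times in seconds
#'   (run clock), one row per trial.
#' @param lag_s Hemodynamic lag added to each window's end (default 6 s).
#' @param tr_s Repetition time in seconds.
#' @return Numeric vector of peak amplitudes, one per window.
#' @export
peak_trial_amplitude <- function(series, windows, lag_s = 6, tr_s = 1) {
  windows <- matrix(windows, ncol = 2)
  apply(windows, 1, function(w) {
    i0 <- floor(w[1] / tr_s) + 1
    i1 <- ceiling((w[2] + lag_s) / tr_s)
    if (i0 < 1 || i0 > length(series))
      stop("trial window outside the series", call. = FALSE)
    max(series[i0:min(i1, length(series))])
  })
}

#' Noise ceiling from inter-trial variability
#'
#' Upper bound on the cross-validated variance a model can explain, from the
#' reliability of the data themselves: trials of each condition are split in
#' half at random, condition-mean time courses are formed per half and
#' concatenated across conditions, and the two halves are correlated. The
#' mean split-half correlation over random splits is Spearman-Brown
#' corrected to the full data and squared to give the ceiling.
#'
#' @param trials A list (one element per condition) of trial x time
#'   matrices of repeated responses, or a single such matrix.
#' @param n_splits Number of random half-splits averaged.
#' @param seed Optional integer seed for the splits.
#' @return Estimated ceiling on x-R^2 (clipped below at 0 only by chance
#'   level, not explicitly). Errors when any condition has fewer than 2
#'   trials.
#' @export
noise_ceiling <- function(trials, n_splits = 100, seed = NULL) {
  if (is.matrix(trials)) trials <- list(trials)
  if (any(vapply(trials, nrow, integer(1)) < 2))
    stop("noise ceiling is undefined with fewer than 2 trials per condition",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- vapply(seq_len(n_splits), function(s) {
    h1 <- numeric(0); h2 <- numeric(0)
    for (m in trials) {
      idx <- sample.int(nrow(m))
      a <- idx[seq_len(nrow(m) %/% 2)]
      b <- setdiff(idx, a)
      h1 <- c(h1, colMeans(m[a, , drop = FALSE]))
      h2 <- c(h2, colMeans(m[b, , drop = FALSE]))
    }
    stats::cor(h1, h2)
  }, numeric(1))
  r <- mean(r, na.rm = TRUE)
  # negative reliability means no repeatable signal: the ceiling is 0, not
  # the square of a negative Spearman-Brown value
  sb <- max(0, 2 * r / (1 + r))
  sb^2
}
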