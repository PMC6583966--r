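#' Ground-truth parameter sets for synthetic ROI data
#'
#' Defines the generating model for [generate_dataset()]. Two illustrative
#' presets mirror the qualitative response regimes the model family was
#' built to separate (the parameter values are illustrative defaults, not
#' fitted values):
#' \describe{
#'   \item{`ventral-like`}{both channels contribute, strong adaptation and
#'     offset-dominant transients (`k_on > k_off`, balance ~0.77), category
#'     selectivity in both channels.}
#'   \item{`lateral-like`}{transient-dominated: sustained weights 0,
#'     balanced onset/offset sigmoids (balance 0.5).}
#' }
#'
#' @param preset `"ventral-like"`, `"lateral-like"` or `"custom"`.
#' @param variant Generating model variant.
#' @param tau,alpha,epsilon,lam,k_on,k_off Nonlinear parameters (within the
#'   fitting bounds so recovery is well-posed).
#' @param beta_S,beta_T Named channel weights per category (in normalized
#'   predictor units).
#' @param noise_sd Additive noise SD in signal units; alternatively give
#'   `snr` to [generate_dataset()].
#' @param noise_model `"white"` or `"ar1"`.
#' @param rho AR(1) coefficient (used when `noise_model = "ar1"`).
#' @return A `tc_truth` list of generating values.
#' @examples
#' ground_truth("lateral-like")$beta_S
#' @export
ground_truth <- function(preset = c("ventral-like", "lateral-like", "custom"),
                         variant = "A+S", tau = 4.93, alpha = 15,
                         epsilon = 0.1, lam = 0.1, k_on = 3.35, k_off = 1,
                         beta_S = c(face = 0.9, body = 0.35, word = 0.3),
                         beta_T = c(face = 1.1, body = 0.5, word = 0.45),
                         noise_sd = 0, noise_model = c("white", "ar1"),
                         rho = 0.3) {
  preset <- match.arg(preset)
  if (preset == "lateral-like") {
    beta_S <- c(face = 0, body = 0, word = 0)
    k_on <- 3
    k_off <- 3
    lam <- 0.1
    alpha <- 20
  }
  b <- tc_bounds()
  pars <- c(tau = tau, alpha = alpha, epsilon = epsilon, lam = lam,
            k_on = k_on, k_off = k_off)
  out_of_bounds <- pars < b$lower | pars > b$upper
  if (any(out_of_bounds))
    warning("ground-truth parameter(s) outside the fitting bounds: ",
            paste(names(pars)[out_of_bounds], collapse = ", "),
            "; recovery may be ill-posed")
  structure(list(preset = preset, variant = variant_name(variant),
                 params = pars, beta_S = beta_S, beta_T = beta_T,
                 noise_sd = noise_sd,
                 noise_model = match.arg(noise_model), rho = rho),
            class = "tc_truth")
}

#' @export
print.tc_truth <- function(x, ...) {
  cat(sprintf("Ground truth (%s, %s variant): noise %s sd %.3g\n",
              x$preset, x$variant, x$noise_model, x$noise_sd))
  print(round(x$params, 3))
  invisible(x)
}

#' Generate a synthetic multi-run ROI dataset
#'
#' Forward-simulates region-of-interest BOLD time series from a generating
#' model: for each run, the truth's variant is evaluated on the run design
#' (channel predictors, max-height normalized across the whole dataset),
#' weighted by the truth's channel weights, and additive seeded noise is
#' applied. The default designs are the canonical acquisition: `n_runs`
#' 270-s full-permutation runs of each of the three experiments, 12-s
#' baselines, TR = 1 s.
#'
#' @param truth A [ground_truth()] object.
#' @param designs Optional list of `run_design`; default: `n_runs` runs of
#'   each experiment.
#' @param n_runs Runs per experiment for the default designs (4 emulates the
#'   original acquisition).
#' @param snr If given, overrides `truth$noise_sd` with
#'   `max(abs(signal)) / snr` (peak signal over noise SD).
#' @param seed Integer seed; the same seed reproduces the dataset bit for
#'   bit.
#' @param randomize_order Shuffle trial order within each run (seeded);
#'   default `FALSE` keeps the deterministic canonical order.
#' @param resolution_ms,tr_s Working resolution and repetition time.
#' @param hrf Optional hemodynamic kernel override.
#' @return A `tc_dataset`: list with `designs`, `series` (one numeric
#'   vector per run), `clean` (noise-free forward predictions), `truth`
#'   (sidecar with all generating values), `noise_sd` (the SD actually
#'   used) and `seed`.
#' @examples
#' dat <- generate_dataset(ground_truth("lateral-like"), n_runs = 1, seed = 1)
#' length(dat$series[[1]])  # 270 samples per run
#' @export
generate_dataset <- function(truth, designs = NULL, n_runs = 4, snr = NULL,
                             seed = 1, randomize_order = FALSE,
                             resolution_ms = 1, tr_s = 1, hrf = NULL) {
  stopifnot(inherits(truth, "tc_truth"))
  set.seed(seed)
  if (is.null(designs)) {
    designs <- list()
    for (e in 1:3) for (r in seq_len(n_runs))
      designs[[length(designs) + 1]] <-
        experiment_run(e, seed = if (randomize_order) seed + 100 * e + r else NULL)
  }
  X <- build_design_matrix(designs, truth$variant, truth$params,
                           resolution_ms = resolution_ms, tr_s = tr_s,
                           hrf = hrf)
  info <- variant_info(truth$variant)
  cats <- attr(X, "categories")
  beta <- numeric(0)
  for (ch in variant_channels(info)) {
    w <- switch(ch, sustained = truth$beta_S, transient = truth$beta_T,
                glm = truth$beta_S)
    beta <- c(beta, stats::setNames(w[cats], paste(ch, cats, sep = ".")))
  }
  pcols <- grep("^intercept\\.", colnames(X), invert = TRUE)
  signal <- drop(X[, pcols, drop = FALSE] %*% beta[colnames(X)[pcols]])
  noise_sd <- if (!is.null(snr)) max(abs(signal)) / snr else truth$noise_sd
  rid <- attr(X, "run_index")
  noise <- if (truth$noise_model == "ar1") {
    as.numeric(stats::filter(stats::rnorm(length(signal)), truth$rho,
                             method = "recursive")) *
      noise_sd * sqrt(1 - truth$rho^2)
  } else {
    stats::rnorm(length(signal), 0, noise_sd)
  }
  y <- signal + noise
  structure(list(designs = designs, series = split(y, rid),
                 clean = split(signal, rid), truth = truth,
                 noise_sd = noise_sd, seed = seed,
                 resolution_ms = resolution_ms, tr_s = tr_s),
            class = "tc_dataset")
}

#' @export
print.tc_dataset <- function(x, ...) {
  cat(sprintf("Synthetic ROI dataset: %d run(s), %d samples each, noise sd %.3g (seed %d)\n",
              length(x$series), length(x$series[[1]]), x$noise_sd, x$seed))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Generates datasets over a grid of ground truths, signal-to-noise ratios
#' and seeds, refits the generating variant to each, and reports bias and
#' error of every recovered parameter and channel weight.
#'
#' @param truths Named list of [ground_truth()] objects.
#' @param snrs Numeric vector of peak-signal / noise-SD ratios.
#' @param seeds Integer vector of dataset seeds.
#' @param n_runs Runs per experiment per dataset.
#' @param optimize Re-optimize nonlinear parameters for each dataset (the
#'   full recovery problem); if `FALSE` only channel weights are refit at
#'   the generating parameters.
#' @param control Optimizer settings, see [tcm_control()].
#' @return A data.frame with one row per (truth, snr, seed, quantity):
#'   columns `truth`, `snr`, `seed`, `quantity`, `true`, `recovered`,
#'   `error`.
#' @export
recovery_experiment <- function(truths, snrs = 5, seeds = 1:3, n_runs = 2,
                                optimize = TRUE, control = tcm_control()) {
  if (inherits(truths, "tc_truth")) truths <- list(truth = truths)
  rows <- list()
  for (tn in names(truths)) {
    truth <- truths[[tn]]
    info <- variant_info(truth$variant)
    for (snr in snrs) for (seed in seeds) {
      dat <- generate_dataset(truth, n_runs = n_runs, snr = snr, seed = seed)
      fit <- tcm(dat, variant = truth$variant, optimize = optimize,
                 control = control)
      tv <- c(truth$params[info$free],
              if (info$has_sus) stats::setNames(truth$beta_S,
                                                paste0("beta_S.", names(truth$beta_S))),
              if (info$has_trans) stats::setNames(truth$beta_T,
                                                  paste0("beta_T.", names(truth$beta_T))))
      rv <- c(fit$params[info$free],
              if (info$has_sus) stats::setNames(fit$betas["sustained", ],
                                                paste0("beta_S.", colnames(fit$betas))),
              if (info$has_trans) stats::setNames(fit$betas["transient", ],
                                                  paste0("beta_T.", colnames(fit$betas))))
      rows[[length(rows) + 1]] <- data.frame(
        truth = tn, snr = snr, seed = seed, quantity = names(tv),
        true = unname(tv), recovered = unname(rv[names(tv)]),
        error = unname(rv[names(tv)] - tv), row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
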