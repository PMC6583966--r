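#' Ordinary least squares channel weights
#'
#' Solves `y = X b + e` by OLS via the QR decomposition. The design must be
#' full column rank; otherwise the offending (aliased) columns are named in
#' the error.
#'
#' @param X Design matrix (e.g. from [build_design_matrix()]).
#' @param y Response vector (concatenated ROI time series), same length as
#'   `nrow(X)`.
#' @return List with `coefficients` (named), `fitted`, `residuals` and `rss`.
#' @examples
#' X <- cbind(a = c(1, 0, 1, 1), b = c(0, 1, 1, 0))
#' fit_betas(X, X %*% c(2, -1))$coefficients
#' @export
fit_betas <- function(X, y) {
  if (nrow(X) != length(y))
    stop("nrow(X) must equal length(y)", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  list(coefficients = beta, fitted = fitted, residuals = res,
       rss = sum(res^2))
}

#' Optimizer settings for model fitting
#'
#' @param iter_max Optimizer iteration budget (Levenberg-Marquardt steps or
#'   `nlminb` iterations).
#' @param rel_tol Relative convergence tolerance of the objective.
#' @param multistart Number of additional seeded random starting points
#'   (0 = single start at the canonical initial values, as in the original
#'   fitting procedure).
#' @param engine `"lm"` (bounded Levenberg-Marquardt on the residual vector,
#'   [minpack.lm::nls.lm()]; the default, exploiting the least-squares
#'   structure) or `"nlminb"` (bounded quasi-Newton on the residual sum of
#'   squares).
#' @param resolution_ms Working resolution of the forward model in ms.
#' @param tr_s Repetition time in seconds.
#' @param init,lower,upper Optional named overrides of the canonical initial
#'   values and box constraints ([tc_bounds()]).
#' @return A list of settings for [tcm()], [optimize_params()] and
#'   [cross_validate()].
#' @export
tcm_control <- function(iter_max = 100, rel_tol = 1e-8, multistart = 0,
                        engine = c("lm", "nlminb"), resolution_ms = 1,
                        tr_s = 1, init = NULL, lower = NULL, upper = NULL) {
  b <- tc_bounds()
  for (nm in names(init)) b$init[nm] <- init[nm]
  for (nm in names(lower)) b$lower[nm] <- lower[nm]
  for (nm in names(upper)) b$upper[nm] <- upper[nm]
  list(iter_max = iter_max, rel_tol = rel_tol, multistart = multistart,
       engine = match.arg(engine), resolution_ms = resolution_ms, tr_s = tr_s,
       bounds = b)
}

# experiment id per run (needed for per-experiment scoring)
run_experiments <- function(designs) {
  vapply(designs, function(d) d$experiment, integer(1))
}

as_run_list <- function(designs) {
  if (inherits(designs, "run_design")) list(designs) else designs
}

# residuals of the nested OLS fit at given nonlinear parameters
resid_at <- function(parvec, free, comp, info, hrf, y, base = tc_bounds()$init) {
  params <- base
  params[free] <- parvec
  X <- try(finish_design(comp, info, params, hrf), silent = TRUE)
  if (inherits(X, "try-error")) return(rep(1e6, length(y)))
  r <- fit_betas(X, y)$residuals
  if (any(!is.finite(r))) rep(1e6, length(y)) else r
}

# residual sum of squares of the nested OLS fit at given nonlinear parameters
rss_at <- function(parvec, free, comp, info, hrf, y, base = tc_bounds()$init) {
  sum(resid_at(parvec, free, comp, info, hrf, y, base)^2)
}

#' Optimize a variant's nonlinear parameters
#'
#' Minimizes the residual sum of squares of the nested OLS fit over the
#' variant's free parameters (a subset of `tau`, `alpha`, `epsilon`, `lam`,
#' `k_on`, `k_off`) under box constraints, starting from the canonical
#' initial values. The default engine is bounded Levenberg-Marquardt on the
#' residual vector ([minpack.lm::nls.lm()]); a bounded quasi-Newton on the
#' summed objective ([stats::nlminb()]) is available via
#' `tcm_control(engine = "nlminb")`. Deterministic; optional seeded
#' multi-start.
#'
#' @param designs Run designs of the training data (list of `run_design`).
#' @param series List of ROI time series (one numeric vector per run, TR
#'   resolution).
#' @param variant Model variant name.
#' @param control See [tcm_control()].
#' @param seed Integer seed for the optional multi-start draws.
#' @param hrf Optional hemodynamic kernel override.
#' @param categories Stimulus categories.
#' @return List with `par` (named optimized parameters; empty for `GLM`),
#'   `objective`, `init_objective`, `convergence` (0 = converged),
#'   `iterations`, `evaluations` and `message`. The final objective never
#'   exceeds the initial one (best-so-far is returned on non-convergence).
#' @export
optimize_params <- function(designs, series, variant, control = tcm_control(),
                            seed = NULL, hrf = NULL,
                            categories = c("face", "body", "word")) {
  designs <- as_run_list(designs)
  info <- variant_info(variant)
  free <- info$free
  if (is.null(hrf)) hrf <- canonical_hrf(control$resolution_ms)
  comp <- compile_runs(designs, control$resolution_ms, control$tr_s, categories,
                       tail_ms = irf_tail_ms(control$bounds$upper[["tau"]]))
  y <- unlist(series, use.names = FALSE)
  if (length(free) == 0)
    return(list(par = numeric(0), objective = rss_at(numeric(0), free, comp,
                                                     info, hrf, y),
                init_objective = NA_real_, convergence = 0L, iterations = 0L,
                evaluations = 0L, message = "no free parameters"))
  b <- control$bounds
  starts <- list(b$init[free])
  if (control$multistart > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(control$multistart)) {
      u <- stats::runif(length(free))
      starts[[i + 1]] <- b$lower[free] + u * (b$upper[free] - b$lower[free])
    }
  }
  init_obj <- rss_at(starts[[1]], free, comp, info, hrf, y, base = b$init)
  best <- NULL
  for (s in starts) {
    if (control$engine == "lm") {
      o <- suppressWarnings(minpack.lm::nls.lm(
        s, lower = b$lower[free], upper = b$upper[free], fn = resid_at,
        control = minpack.lm::nls.lm.control(maxiter = control$iter_max,
                                             ftol = control$rel_tol,
                                             ptol = control$rel_tol),
        free = free, comp = comp, info = info, hrf = hrf, y = y, base = b$init))
      opt <- list(par = o$par, objective = o$deviance,
                  convergence = if (o$info %in% 1:4) 0L else 1L,
                  iterations = o$niter, evaluations = o$niter,
                  message = o$message)
    } else {
      o <- stats::nlminb(s, rss_at, lower = b$lower[free], upper = b$upper[free],
                         control = list(iter.max = control$iter_max,
                                        eval.max = 10 * control$iter_max,
                                        rel.tol = control$rel_tol),
                         free = free, comp = comp, info = info, hrf = hrf,
                         y = y, base = b$init)
      opt <- list(par = o$par, objective = o$objective,
                  convergence = o$convergence, iterations = o$iterations,
                  evaluations = sum(o$evaluations), message = o$message)
    }
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (best$objective > init_obj) {   # optimizer contract: never worse than init
    best$par <- starts[[1]]
    best$objective <- init_obj
    best$convergence <- 1L
    best$message <- "optimizer failed to improve on the initial point"
  }
  par <- stats::setNames(pmin(pmax(best$par, b$lower[free]), b$upper[free]), free)
  list(par = par, objective = best$objective, init_objective = init_obj,
       convergence = best$convergence,
       iterations = best$iterations, evaluations = best$evaluations,
       message = best$message)
}

#' Fit a two-temporal-channel encoding model
#'
#' The central fitting function: given run designs and the matching ROI time
#' series, optionally optimizes the variant's nonlinear parameters
#' (IRF/adaptation/sigmoid constants) by bounded nonlinear least squares and
#' estimates channel weights (one `beta` per channel and stimulus category)
#' plus per-run intercepts by OLS.
#'
#' @param designs A `run_design`, a list of them, or a `tc_dataset` from
#'   [generate_dataset()] (in which case `series` is taken from it).
#' @param series List of ROI time series (percent signal change or arbitrary
#'   units), one numeric vector per run at TR resolution.
#' @param variant Model variant (see [tc_variants()]); default the full
#'   `A+S` model.
#' @param params Named starting / fixed parameter values (override the
#'   canonical initial values).
#' @param optimize If `FALSE`, the forward model is evaluated at `params`
#'   (or the canonical initial values) and only the `beta` weights are fit.
#' @param control Optimizer and resolution settings, see [tcm_control()].
#' @param seed Seed for the optional multi-start.
#' @param hrf Optional hemodynamic kernel override.
#' @param categories Stimulus categories.
#' @return An object of class `tcm` with components `variant`, `params`
#'   (optimized or fixed), `betas` (channel x category matrix),
#'   `intercepts`, `coefficients`, `fitted`, `residuals`, `rss`,
#'   `r_squared` (in-sample, intercept-corrected), `normalization`, `opt`
#'   (optimizer trace) and the data. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' truth <- ground_truth("ventral-like", noise_sd = 0.2)
#' dat <- generate_dataset(truth, n_runs = 1, seed = 1)
#' fit <- tcm(dat, variant = "A+S", optimize = FALSE)
#' coef(fit)
#' }
#' @export
tcm <- function(designs, series = NULL, variant = "A+S", params = NULL,
                optimize = TRUE, control = tcm_control(), seed = NULL,
                hrf = NULL, categories = c("face", "body", "word")) {
  cl <- match.call()
  if (inherits(designs, "tc_dataset")) {
    if (is.character(series)) variant <- series   # tcm(dat, "A+S")
    else if (!is.null(series))
      stop("'series' is taken from the dataset; pass other arguments by name",
           call. = FALSE)
    series <- designs$series
    designs <- designs$designs
  }
  designs <- as_run_list(designs)
  if (length(designs) != length(series))
    stop("need one series per run design", call. = FALSE)
  info <- variant_info(variant)
  if (is.null(hrf)) hrf <- canonical_hrf(control$resolution_ms)
  if (!is.null(params)) control$bounds$init[names(params)] <- params
  opt <- if (optimize && length(info$free) > 0) {
    ctl <- control
    ctl$bounds <- control$bounds
    optimize_params(designs, series, info$name, control = ctl, seed = seed,
                    hrf = hrf, categories = categories)
  } else {
    list(par = control$bounds$init[info$free], objective = NA_real_,
         convergence = 0L, iterations = 0L, evaluations = 0L,
         message = "parameters fixed")
  }
  full <- control$bounds$init
  full[names(opt$par)] <- opt$par
  X <- build_design_matrix(designs, info$name, full,
                           resolution_ms = control$resolution_ms,
                           tr_s = control$tr_s, hrf = hrf,
                           categories = categories)
  y <- unlist(series, use.names = FALSE)
  ols <- fit_betas(X, y)
  channels <- variant_channels(info)
  betas <- matrix(NA_real_, length(channels), length(categories),
                  dimnames = list(channels, categories))
  for (ch in channels)
    betas[ch, ] <- ols$coefficients[paste(ch, categories, sep = ".")]
  ints <- ols$coefficients[grep("^intercept\\.", names(ols$coefficients))]
  yc <- y - drop(X[, names(ints), drop = FALSE] %*% ints)
  r2 <- 1 - ols$rss / sum((yc - mean(yc))^2)
  structure(
    list(variant = info$name,
         params = full[if (info$glm) character() else union("tau", info$free)],
         free = info$free, betas = betas, intercepts = ints,
         coefficients = ols$coefficients, fitted = ols$fitted,
         residuals = ols$residuals, rss = ols$rss, r_squared = r2,
         normalization = attr(X, "normalization"),
         run_index = attr(X, "run_index"), opt = opt, designs = designs,
         series = series, categories = categories, control = control,
         hrf = hrf, call = cl),
    class = "tcm")
}

# cross-validated R^2: per-run intercepts are removed from data and
# prediction before scoring, and SS_tot is taken about the left-out mean
xr2_score <- function(y, yhat, run_id) {
  for (r in unique(run_id)) {
    i <- run_id == r
    y[i] <- y[i] - mean(y[i])
    yhat[i] <- yhat[i] - mean(yhat[i])
  }
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

# default split-half folds: first half vs second half of runs per experiment
default_folds <- function(experiments, seed = NULL) {
  fold <- integer(length(experiments))
  for (e in unique(experiments)) {
    idx <- which(experiments == e)
    if (length(idx) < 2)
      stop("cross-validation needs at least 2 runs per experiment", call. = FALSE)
    if (!is.null(seed)) idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(1:2, length.out = length(idx))
  }
  fold
}

#' Split-half cross-validation of a model variant
#'
#' Splits the runs of every experiment in half, optimizes the variant's
#' parameters and channel weights on each half, predicts the complementary
#' half, and scores cross-validated variance explained (x-R^2) per
#' experiment and overall (the mean across experiments). Results are
#' averaged over both fold directions, so swapping the folds leaves the
#' result unchanged. x-R^2 can be negative when a poor model's residual
#' variance exceeds the measured variance.
#'
#' @inheritParams tcm
#' @param folds Optional integer vector (1 or 2 per run) assigning runs to
#'   halves; default: first half vs second half of each experiment's runs.
#' @param seed If given (and `folds` is `NULL`), runs are assigned to halves
#'   reproducibly at random.
#' @return Object of class `tcm_cv`: `x_r2` (named vector, one per
#'   experiment plus `"overall"`), `params` and `betas` (averaged across
#'   both splits), `folds`, `fits` (the two training fits) and `variant`.
#' @export
cross_validate <- function(designs, series = NULL, variant = "A+S",
                           folds = NULL, seed = NULL, params = NULL,
                           optimize = TRUE, control = tcm_control(),
                           hrf = NULL, categories = c("face", "body", "word")) {
  if (inherits(designs, "tc_dataset")) {
    if (is.character(series)) variant <- series   # cross_validate(dat, "A+S")
    else if (!is.null(series))
      stop("'series' is taken from the dataset; pass other arguments by name",
           call. = FALSE)
    series <- designs$series
    designs <- designs$designs
  }
  designs <- as_run_list(designs)
  exps <- run_experiments(designs)
  if (is.null(folds)) {
    if (!is.null(seed)) set.seed(seed)
    folds <- default_folds(exps, seed = seed)
  }
  if (!all(folds %in% 1:2)) stop("folds must assign runs to halves 1 and 2",
                                 call. = FALSE)
  if (is.null(hrf)) hrf <- canonical_hrf(control$resolution_ms)
  halves <- lapply(1:2, function(f) which(folds == f))
  fits <- vector("list", 2)
  scores <- vector("list", 2)
  for (d in 1:2) {
    train <- halves[[d]]
    test <- halves[[3 - d]]
    fit <- tcm(designs[train], series[train], variant = variant,
               params = params, optimize = optimize, control = control,
               hrf = hrf, categories = categories)
    Xt <- build_design_matrix(designs[test], variant, fit$params,
                              resolution_ms = control$resolution_ms,
                              tr_s = control$tr_s, hrf = hrf,
                              categories = categories)
    pcols <- grep("^intercept\\.", colnames(Xt), invert = TRUE)
    bet <- fit$coefficients[colnames(Xt)[pcols]]
    yhat <- drop(Xt[, pcols, drop = FALSE] %*% bet)
    y <- unlist(series[test], use.names = FALSE)
    rid <- attr(Xt, "run_index")
    per_exp <- vapply(sort(unique(exps)), function(e) {
      i <- rid %in% which(exps[test] == e)
      if (!any(i)) return(NA_real_)
      xr2_score(y[i], yhat[i], rid[i])
    }, numeric(1))
    names(per_exp) <- paste0("exp", sort(unique(exps)))
    scores[[d]] <- c(per_exp, overall = mean(per_exp, na.rm = TRUE))
    fits[[d]] <- fit
  }
  x_r2 <- (scores[[1]] + scores[[2]]) / 2
  pars <- (fits[[1]]$params + fits[[2]]$params) / 2
  betas <- (fits[[1]]$betas + fits[[2]]$betas) / 2
  structure(list(variant = variant_name(variant), x_r2 = x_r2, params = pars,
                 betas = betas, folds = folds, per_split = scores,
                 fits = fits),
            class = "tcm_cv")
}

#' @export
print.tcm_cv <- function(x, digits = 3, ...) {
  cat("Split-half cross-validation of the", x$variant, "model\n")
  cat("x-R^2:\n")
  print(round(x$x_r2, digits))
  cat("parameters (averaged across splits):\n")
  print(round(x$params, digits))
  invisible(x)
}

#' Compare model variants by cross-validated R^2
#'
#' Runs [cross_validate()] for each requested variant with an identical fold
#' assignment and tabulates x-R^2 per experiment plus the overall mean.
#'
#' @inheritParams cross_validate
#' @param variants Character vector of variant names.
#' @return A data.frame with one row per variant (class `tcm_comparison`);
#'   attribute `cv` holds the individual `tcm_cv` objects.
#' @export
compare_models <- function(designs, series = NULL,
                           variants = c("GLM", "CTS", "L+Q", "A+S"),
                           folds = NULL, seed = NULL,
                           control = tcm_control(), hrf = NULL,
                           categories = c("face", "body", "word")) {
  if (inherits(designs, "tc_dataset")) {
    if (is.character(series)) variants <- series  # compare_models(dat, c(...))
    else if (!is.null(series))
      stop("'series' is taken from the dataset; pass other arguments by name",
           call. = FALSE)
    series <- designs$series
    designs <- designs$designs
  }
  designs <- as_run_list(designs)
  exps <- run_experiments(designs)
  if (is.null(folds)) {
    if (!is.null(seed)) set.seed(seed)
    folds <- default_folds(exps, seed = seed)
  }
  cvs <- lapply(variants, function(v)
    cross_validate(designs, series, variant = v, folds = folds,
                   control = control, hrf = hrf, categories = categories))
  tab <- do.call(rbind, lapply(cvs, function(cv) as.data.frame(t(cv$x_r2))))
  tab <- cbind(variant = vapply(cvs, `[[`, character(1), "variant"), tab)
  rownames(tab) <- NULL
  structure(tab, cv = stats::setNames(cvs, tab$variant),
            class = c("tcm_comparison", "data.frame"))
}

#' @export
print.tcm_comparison <- function(x, digits = 3, ...) {
  cat("Cross-validated R^2 by model variant\n")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits)
  print(y)
  invisible(x)
}
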