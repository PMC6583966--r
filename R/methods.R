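#' @export
print.tcm <- function(x, digits = 3, ...) {
  cat(sprintf("Two-temporal-channel encoding model (%s variant)\n", x$variant))
  cat(sprintf("  %d run(s), %d time points, R^2 = %.3f\n",
              length(x$designs), length(x$fitted), x$r_squared))
  if (length(x$params)) {
    cat("  parameters:\n")
    print(round(x$params, digits))
  }
  cat("  channel weights (beta):\n")
  print(round(x$betas, digits))
  invisible(x)
}

#' @export
summary.tcm <- function(object, ...) {
  structure(list(fit = object), class = "summary.tcm")
}

#' @export
print.summary.tcm <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  residual SD: %.4g\n", stats::sd(f$residuals)))
  cat(sprintf("  optimizer: %s (%d iterations, %d evaluations)\n",
              if (f$opt$convergence == 0) "converged" else
                paste0("not converged (", f$opt$message, ")"),
              f$opt$iterations, f$opt$evaluations))
  if (!is.null(f$normalization)) {
    cat("  predictor normalization (max height before scaling):\n")
    print(signif(f$normalization, digits))
  }
  invisible(x)
}

#' Extract channel weights or model parameters
#'
#' @param object A fitted [tcm()] model.
#' @param what `"betas"` (channel x category weights, default),
#'   `"params"` (optimized nonlinear parameters) or `"all"` (every OLS
#'   coefficient including per-run intercepts).
#' @param ... Unused.
#' @return Named numeric vector or matrix.
#' @export
coef.tcm <- function(object, what = c("betas", "params", "all"), ...) {
  switch(match.arg(what),
         betas = object$betas,
         params = object$params,
         all = object$coefficients)
}

#' @export
fitted.tcm <- function(object, ...) object$fitted

#' @export
residuals.tcm <- function(object, ...) object$residuals

#' Predict BOLD responses from a fitted model
#'
#' Applies the fitted parameters and channel weights to new (or the
#' training) run designs. Channel predictor blocks are scaled by the
#' normalization constants recorded at fit time, so the weights keep their
#' meaning; intercepts are only added for the training data.
#'
#' @param object A fitted `tcm` model.
#' @param newdesigns Optional `run_design` (list); default: training fitted
#'   values.
#' @param ... Unused.
#' @return List of predicted time series, one per run (or the fitted values
#'   when `newdesigns` is missing).
#' @export
predict.tcm <- function(object, newdesigns = NULL, ...) {
  if (is.null(newdesigns)) return(object$fitted)
  newdesigns <- as_run_list(newdesigns)
  X <- build_design_matrix(newdesigns, object$variant, object$params,
                           resolution_ms = object$control$resolution_ms,
                           tr_s = object$control$tr_s, hrf = object$hrf,
                           categories = object$categories)
  pcols <- grep("^intercept\\.", colnames(X), invert = TRUE)
  # undo the new matrix's own scaling, re-apply the training scaling
  ch <- sub("\\..*$", "", colnames(X)[pcols])
  scale <- attr(X, "normalization")[ch] / object$normalization[ch]
  Xp <- sweep(X[, pcols, drop = FALSE], 2, scale, `*`)
  yhat <- drop(Xp %*% object$coefficients[colnames(X)[pcols]])
  split(yhat, attr(X, "run_index"))
}

#' Simulate responses from a fitted model
#'
#' Draws new noisy realizations of the fitted model's prediction: fitted
#' values plus white Gaussian noise with the residual standard deviation.
#'
#' @param object A fitted `tcm` model.
#' @param nsim Number of simulated datasets.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns, one simulated concatenated
#'   series per column.
#' @export
simulate.tcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd <- stats::sd(object$residuals)
  out <- replicate(nsim, object$fitted + stats::rnorm(length(object$fitted), 0, sd))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Plot measured and predicted time series of a fitted model
#'
#' One panel per run: the measured ROI series and the model fit.
#'
#' @param x A fitted `tcm` model.
#' @param runs Which runs to show (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tcm <- function(x, runs = 1, ...) {
  old <- graphics::par(mfrow = c(length(runs), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (r in runs) {
    i <- x$run_index == r
    t_s <- seq_len(sum(i)) - 1
    graphics::plot(t_s, x$series[[r]], type = "l", col = "grey40",
                   xlab = "time (s)", ylab = "BOLD (input units)",
                   main = sprintf("run %d (%s model)", r, x$variant), ...)
    graphics::lines(t_s, x$fitted[i], col = "firebrick", lwd = 2)
    graphics::legend("topright", c("measured", "predicted"), bty = "n",
                     col = c("grey40", "firebrick"), lwd = c(1, 2))
  }
  invisible(x)
}
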