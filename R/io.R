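# Plain-text serialization: JSON for structured objects (run designs, fit
# results, dataset sidecars), TSV for time series and matrices.

#' Write / read a run design as JSON
#'
#' @param run A `run_design`.
#' @param path Output file.
#' @return `read_run_design()` returns the reconstructed `run_design`.
#' @export
write_run_design <- function(run, path) {
  stopifnot(inherits(run, "run_design"))
  obj <- list(
    baseline_s = run$baseline_s,
    total_duration_s = run$total_duration_s,
    trials = lapply(run$trials, function(tr)
      list(experiment = tr$experiment, duration_s = tr$duration_s,
           category = tr$category, onset_ms = tr$onset_ms,
           events = apply(tr$events, 1, as.list))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_design
#' @export
read_run_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  trials <- lapply(obj$trials, function(tr)
    build_trial(tr$experiment, tr$duration_s, tr$category, freeform = TRUE))
  build_run(trials, baseline_s = obj$baseline_s)
}

#' Export a step function or neural response as TSV
#'
#' Columns: `time_ms` then one column per category/channel.
#'
#' @param x A `step_function` (or any time x channel matrix with a
#'   `resolution_ms` attribute).
#' @param path Output file.
#' @param resolution_ms Resolution override when `x` carries no attribute.
#' @export
write_timeseries_tsv <- function(x, path, resolution_ms = NULL) {
  res <- resolution_ms %||% attr(x, "resolution_ms") %||% 1
  df <- data.frame(time_ms = (seq_len(nrow(x)) - 1) * res)
  df <- cbind(df, as.data.frame(unclass(x)[seq_len(nrow(x)), , drop = FALSE]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a design matrix as TSV
#'
#' Header names each column `channel.category` or `intercept.runN`.
#'
#' @param X A `tc_design` matrix.
#' @param path Output file.
#' @export
write_design_tsv <- function(X, path) {
  utils::write.table(as.data.frame(unclass(X)[seq_len(nrow(X)), ]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model or cross-validation result as JSON
#'
#' @param fit A `tcm` or `tcm_cv` object.
#' @param path Output file.
#' @export
write_fit_json <- function(fit, path) {
  obj <- if (inherits(fit, "tcm_cv")) {
    list(variant = fit$variant, x_r2 = as.list(fit$x_r2),
         params = as.list(fit$params),
         betas = apply(fit$betas, 1, as.list, simplify = FALSE),
         folds = fit$folds)
  } else {
    list(variant = fit$variant, params = as.list(fit$params),
         betas = apply(fit$betas, 1, as.list, simplify = FALSE),
         intercepts = as.list(fit$intercepts), r_squared = fit$r_squared,
         normalization = as.list(fit$normalization),
         optimizer = fit$opt[c("objective", "convergence", "iterations",
                               "evaluations", "message")])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' One TSV per run (`t_s`, `signal`) plus a JSON sidecar with the complete
#' ground truth and seed, so recovery can be scored later.
#'
#' @param dataset A `tc_dataset`.
#' @param dir Output directory (created if needed).
#' @return The sidecar path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(dataset$series)) {
    df <- data.frame(t_s = (seq_along(dataset$series[[r]]) - 1) * dataset$tr_s,
                     signal = dataset$series[[r]])
    utils::write.table(df, file.path(dir, sprintf("run%02d.tsv", r)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- dataset$truth
  sidecar <- list(preset = truth$preset, variant = truth$variant,
                  params = as.list(truth$params),
                  beta_S = as.list(truth$beta_S),
                  beta_T = as.list(truth$beta_T),
                  noise_sd = dataset$noise_sd,
                  noise_model = truth$noise_model, seed = dataset$seed,
                  n_runs = length(dataset$series),
                  experiments = run_experiments(dataset$designs))
  path <- file.path(dir, "truth.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tidy metrics table
#'
#' Collects the derived metrics of a fitted model into a tidy data.frame
#' (and optionally a TSV): onset/offset balance, per-category channel
#' contribution ratios, and contrast effect sizes per channel.
#'
#' @param fit A fitted `tcm` (or averaged `tcm_cv`) with both channels.
#' @param preferred Preferred category for the contrast effect size.
#' @param roi Label for the `roi` column.
#' @param path Optional TSV output file.
#' @return data.frame with columns `roi`, `metric`, `channel`, `category`,
#'   `value`.
#' @export
metrics_table <- function(fit, preferred, roi = "roi", path = NULL) {
  betas <- fit$betas
  params <- fit$params
  rows <- list()
  add <- function(metric, channel, category, value)
    rows[[length(rows) + 1]] <<- data.frame(roi = roi, metric = metric,
                                            channel = channel,
                                            category = category, value = value)
  if (all(c("k_on", "k_off") %in% names(params)))
    add("balance", "transient", NA, balance_metric(params[["k_on"]],
                                                   params[["k_off"]]))
  if (all(c("sustained", "transient") %in% rownames(betas)))
    for (cat in colnames(betas))
      add("channel_ratio", NA, cat,
          channel_ratio(betas["sustained", cat], betas["transient", cat]))
  for (ch in rownames(betas))
    add("contrast_effect_size", ch, preferred,
        contrast_effect_size(betas, preferred, channel = ch))
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
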