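# Model-variant registry and the design-matrix pipeline.
#
# The model space spans one benchmark (GLM: stimulus boxcar convolved once
# with the HRF), four single-channel variants (L, CTS, A sustained; S
# transient) and four dual-channel variants (L+Q, C+Q, A+Q, A+S).

.variants <- list(
  "GLM" = list(sustained = NA,      transient = NA,        glm = TRUE,
               free = character()),
  "L"   = list(sustained = "none",  transient = NA,        glm = FALSE,
               free = "tau"),
  "CTS" = list(sustained = "cts",   transient = NA,        glm = FALSE,
               free = c("tau", "epsilon")),
  "A"   = list(sustained = "adapt", transient = NA,        glm = FALSE,
               free = c("tau", "alpha")),
  "S"   = list(sustained = NA,      transient = "sigmoid", glm = FALSE,
               free = c("tau", "lam", "k_on", "k_off")),
  "L+Q" = list(sustained = "none",  transient = "quad",    glm = FALSE,
               free = "tau"),
  "C+Q" = list(sustained = "cts",   transient = "quad",    glm = FALSE,
               free = c("tau", "epsilon")),
  "A+Q" = list(sustained = "adapt", transient = "quad",    glm = FALSE,
               free = c("tau", "alpha")),
  "A+S" = list(sustained = "adapt", transient = "sigmoid", glm = FALSE,
               free = c("tau", "alpha", "lam", "k_on", "k_off"))
)

#' Model variants
#'
#' Names of the supported model variants: `GLM` (stimulus boxcar convolved
#' once with the HRF), single-channel `L`, `CTS`, `A` (linear, compressive,
#' adapting sustained channel) and `S` (sigmoid transient channel, no
#' sustained channel), and dual-channel `L+Q`, `C+Q`, `A+Q` (quadratic
#' transient) and `A+S` (adapting sustained + sigmoid transient, the full
#' model).
#'
#' @return Character vector of variant names.
#' @export
tc_variants <- function() names(.variants)

# canonical variant name ("as", "A+S", "AS" -> "A+S")
variant_name <- function(variant) {
  v <- toupper(gsub("[+[:space:]]", "", variant))
  key <- vapply(names(.variants), function(n) gsub("\\+", "", n), character(1))
  hit <- match(v, key)
  if (is.na(hit))
    stop("unknown model variant '", variant, "'; available: ",
         paste(names(.variants), collapse = ", "), call. = FALSE)
  names(.variants)[hit]
}

variant_info <- function(variant) {
  v <- variant_name(variant)
  c(.variants[[v]], list(name = v,
                         has_sus = !is.na(.variants[[v]]$sustained),
                         has_trans = !is.na(.variants[[v]]$transient)))
}

# channel column labels for a variant, in design-matrix order
variant_channels <- function(info) {
  if (info$glm) return("glm")
  c(if (info$has_sus) "sustained", if (info$has_trans) "transient")
}

#' Default parameters, bounds and optimizer initial values
#'
#' The optimizable constants of the model family with their box constraints:
#' IRF time constant `tau` (4-20 ms), adaptation time constant `alpha`
#' (10-40 s), CTS exponent `epsilon` (0.01-1), sigmoid scale `lam`
#' (0.01-0.5) and sigmoid shapes `k_on`, `k_off` (0.1-6). `init` holds the
#' optimizer's starting point (tau = 4.93 ms, alpha = 20 s, epsilon = 0.1,
#' lam = 0.1, k_on = k_off = 3).
#'
#' @return A list with named numeric vectors `init`, `lower` and `upper`.
#' @export
tc_bounds <- function() {
  list(
    init  = c(tau = 4.93, alpha = 20, epsilon = 0.1, lam = 0.1, k_on = 3, k_off = 3),
    lower = c(tau = 4,    alpha = 10, epsilon = 0.01, lam = 0.01, k_on = 0.1, k_off = 0.1),
    upper = c(tau = 20,   alpha = 40, epsilon = 1,    lam = 0.5,  k_on = 6,   k_off = 6)
  )
}

# fill missing parameters of a variant with the default initial values
complete_params <- function(params, info) {
  full <- tc_bounds()$init
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(full))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    full[names(params)] <- params
  }
  full
}

# ---------------------------------------------------------------------------
# compiled run representation: everything about a design that does not depend
# on the model parameters, laid out per trial so that neural responses are
# only ever computed on the short segment where they are nonzero

compile_runs <- function(designs, resolution_ms = 1, tr_s = 1,
                         categories = c("face", "body", "word"),
                         tail_ms = 1100) {
  if (inherits(designs, "run_design")) designs <- list(designs)
  stopifnot(all(vapply(designs, inherits, logical(1), "run_design")))
  spb <- as.integer(round(tr_s * 1000 / resolution_ms))
  runs <- lapply(designs, function(run) {
    total_ms <- round(run$total_duration_s * 1000)
    n <- total_ms %/% resolution_ms
    if (n %% spb != 0)
      stop("run duration is not an integer multiple of the TR", call. = FALSE)
    trials <- lapply(run$trials, function(tr) {
      ev <- tr$events + tr$onset_ms
      # step-function sample indices, matching render_step_function()
      i0 <- ceiling(ev[, 1] / resolution_ms) + 1
      i1 <- ceiling(ev[, 2] / resolution_ms)
      a_samp <- min(i0)
      b_samp <- min(max(i1) + ceiling(tail_ms / resolution_ms), n)
      a0 <- ((a_samp - 1L) %/% spb) * spb + 1L
      b0 <- (a0 - 1L) %/% spb               # whole TR bins before segment
      nseg <- (((b_samp - a0) %/% spb) + 1L) * spb
      nseg <- min(nseg, n - a0 + 1L)
      # signed unit jumps of the binary step, local to the segment
      pos <- c(i0, i1 + 1L) - a0 + 1L
      val <- rep(c(1, -1), each = nrow(ev))
      keep <- pos <= nseg
      # time since the most recent onset, for the adaptation multiplier;
      # 0 before the first onset, where exp(-t/alpha) = 1 as required
      t_ms <- (a0 + seq_len(nseg) - 2) * resolution_ms
      ons <- sort(ev[, 1])
      idx <- findInterval(t_ms, ons)
      tsince <- t_ms - ons[pmax(idx, 1L)]
      tsince[idx == 0L] <- 0
      list(category = tr$category, a0 = a0, b0 = b0, nseg = nseg,
           pos = pos[keep], val = val[keep], tsince_ms = tsince)
    })
    list(n = n, n_tr = n %/% spb, trials = trials)
  })
  list(runs = runs, resolution_ms = resolution_ms, tr_s = tr_s, spb = spb,
       categories = categories)
}

# neural drive on a trial segment: scatter the step's jumps through the
# kernel, then integrate (exact causal convolution of a piecewise-constant
# signal)
segment_drive <- function(trial, kernel) {
  out <- numeric(trial$nseg + length(kernel))
  for (i in seq_along(trial$pos)) {
    p <- trial$pos[i]
    out[p:(p + length(kernel) - 1L)] <- out[p:(p + length(kernel) - 1L)] +
      trial$val[i] * kernel
  }
  cumsum(out)[seq_len(trial$nseg)]
}

# TR-resolution channel predictors for every run; returns a list of
# (n_tr x channels*categories) matrices with columns "channel.category"
channel_predictors <- function(comp, info, params, hrf) {
  res <- comp$resolution_ms
  spb <- comp$spb
  channels <- variant_channels(info)
  if (!info$glm) {
    irf <- make_irfs(tau_ms = params[["tau"]], resolution_ms = res)
  }
  Hm <- hrf_tr_matrix(as.numeric(hrf), spb)
  cols <- as.vector(outer(channels, comp$categories, paste, sep = "."))
  lapply(comp$runs, function(run) {
    X <- matrix(0, run$n_tr, length(cols), dimnames = list(NULL, cols))
    for (trial in run$trials) {
      for (ch in channels) {
        neural <- switch(ch,
          glm = segment_drive(trial, 1),
          sustained = {
            d <- segment_drive(trial, irf$sustained)
            switch(info$sustained,
              none = d,
              cts = pmax(d, 0)^params[["epsilon"]],
              adapt = d * exp(-trial$tsince_ms / (params[["alpha"]] * 1000)))
          },
          transient = {
            d <- segment_drive(trial, irf$transient) / irf$onset_norm
            switch(info$transient,
              quad = d * d,
              sigmoid = sigmoid_rectifier(d, params[["lam"]],
                                          params[["k_on"]], params[["k_off"]]))
          })
        M <- crossprod(matrix(neural, spb, trial$nseg %/% spb), Hm)
        col <- paste(ch, trial$category, sep = ".")
        X[, col] <- tr_band_add(X[, col], M, trial$b0)
      }
    }
    X
  })
}

#' Build the normalized design matrix for a model variant
#'
#' Runs the full forward pipeline for each run of a design — stimulus step
#' function, channel IRF convolution, the variant's neural nonlinearities,
#' HRF convolution and TR downsampling — and assembles the predictors into a
#' single design matrix with one column per channel x category and one
#' intercept column per run. The predictor block of every channel is scaled
#' to a common maximal height (1), so the fitted channel weights are
#' comparable; the scale factors are recorded in the `normalization`
#' attribute.
#'
#' @param designs A `run_design` or list of them (one per run).
#' @param variant Model variant name (see [tc_variants()]); case and `+`
#'   insensitive.
#' @param params Named numeric vector of the variant's parameters (`tau`,
#'   `alpha`, `epsilon`, `lam`, `k_on`, `k_off` as applicable); unspecified
#'   ones take the default initial values of [tc_bounds()].
#' @param resolution_ms Working resolution in ms (default 1).
#' @param tr_s Repetition time in seconds (default 1).
#' @param hrf Optional hemodynamic kernel at the working resolution (e.g. to
#'   swap in a reference implementation's HRF); defaults to
#'   [canonical_hrf()].
#' @param categories Stimulus categories rendered as predictor columns.
#' @return Numeric matrix of class `tc_design` with attributes `variant`,
#'   `params`, `normalization`, `run_index` (row -> run id), `tr_s` and
#'   `categories`.
#' @examples
#' X <- build_design_matrix(experiment_run(1), "A+S")
#' colnames(X)
#' @export
build_design_matrix <- function(designs, variant, params = NULL,
                                resolution_ms = 1, tr_s = 1, hrf = NULL,
                                categories = c("face", "body", "word")) {
  info <- variant_info(variant)
  params <- complete_params(params, info)
  if (is.null(hrf)) hrf <- canonical_hrf(resolution_ms)
  comp <- compile_runs(designs, resolution_ms, tr_s, categories,
                       tail_ms = irf_tail_ms(max(params[["tau"]], 20)))
  finish_design(comp, info, params, hrf)
}

# support of the slowest filter plus slack, in ms
irf_tail_ms <- function(tau_ms, kappa = 1.33, n2 = 10) {
  ceiling(stats::qgamma(1 - 1e-7, shape = n2, scale = kappa * tau_ms)) + 50
}

# assemble predictors + per-run intercepts and normalize channel blocks
finish_design <- function(comp, info, params, hrf) {
  preds <- channel_predictors(comp, info, params, hrf)
  n_runs <- length(preds)
  pred <- do.call(rbind, preds)
  run_index <- rep(seq_len(n_runs), vapply(preds, nrow, integer(1)))
  channels <- variant_channels(info)
  norm <- numeric(0)
  for (ch in channels) {
    block <- grep(paste0("^", ch, "\\."), colnames(pred))
    m <- max(pred[, block])
    if (m <= 0)
      stop("channel '", ch, "' produced an all-zero predictor block", call. = FALSE)
    pred[, block] <- pred[, block] / m
    norm[ch] <- m
  }
  ints <- matrix(0, nrow(pred), n_runs,
                 dimnames = list(NULL, paste0("intercept.run", seq_len(n_runs))))
  ints[cbind(seq_len(nrow(pred)), run_index)] <- 1
  X <- cbind(pred, ints)
  structure(X, variant = info$name, params = params, normalization = norm,
            run_index = run_index, tr_s = comp$tr_s,
            categories = comp$categories,
            class = c("tc_design", "matrix"))
}
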