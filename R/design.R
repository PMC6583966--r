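#' Construct a single trial's stimulus timing
#'
#' Builds the millisecond-resolution event layout of one trial in the three
#' timing experiments. Experiment 1 presents a single continuous image for the
#' whole trial. Experiments 2 and 3 tile the trial with 30 image/gap cycles:
#' experiment 2 uses 33-ms images separated by blank interstimulus intervals
#' (ISIs) that grow with trial duration (67, 133, 300 and 633 ms for 3-, 5-,
#' 10- and 20-s trials), experiment 3 uses a constant 33-ms ISI and image
#' durations that grow with trial duration (67, 133, 300 and 633 ms).
#'
#' The derived image/gap duration is `duration_s * 1000 / 30 - 33`, floored to
#' a whole millisecond; any sub-millisecond remainder of the 30 cycles is left
#' as extra blank at the end of the trial so the trial keeps its nominal
#' length on an integer millisecond grid.
#'
#' @param experiment Experiment id: 1, 2 or 3.
#' @param duration_s Trial duration in seconds; one of 3, 5, 10, 20 unless
#'   `freeform = TRUE`.
#' @param category Stimulus category label, one of `"face"`, `"body"`,
#'   `"word"`.
#' @param freeform Allow trial durations outside the canonical set (the
#'   30-cycle layout is still used for experiments 2 and 3).
#' @return A `trial_spec` object: a list with `experiment`, `duration_s`,
#'   `duration_ms`, `category` and `events`, a two-column matrix of
#'   half-open `[onset, offset)` image intervals in ms relative to trial
#'   start.
#' @examples
#' tr <- build_trial(2, 3, "body")
#' nrow(tr$events)            # 30 flashes
#' diff(tr$events[1, ])       # each 33 ms long
#' @export
build_trial <- function(experiment, duration_s, category = c("face", "body", "word"),
                        freeform = FALSE) {
  if (!experiment %in% 1:3)
    stop("unsupported experiment id ", experiment, "; must be 1, 2 or 3", call. = FALSE)
  if (!freeform && !duration_s %in% c(3, 5, 10, 20))
    stop("unsupported trial duration ", duration_s,
         " s; must be one of 3, 5, 10, 20 (use freeform = TRUE to override)",
         call. = FALSE)
  if (duration_s <= 0) stop("trial duration must be positive", call. = FALSE)
  category <- match.arg(category)
  dur_ms <- round(duration_s * 1000)

  if (experiment == 1) {
    events <- matrix(c(0, dur_ms), nrow = 1)
  } else {
    n_img <- 30L
    other <- floor(dur_ms / n_img - 33)   # derived image (exp 3) or gap (exp 2) length
    if (other < 1)
      stop("trial of ", duration_s, " s is too short for 30 image/gap cycles",
           call. = FALSE)
    img <- if (experiment == 2) 33 else other
    gap <- if (experiment == 2) other else 33
    cycle <- img + gap
    onsets <- (seq_len(n_img) - 1L) * cycle
    events <- cbind(onsets, onsets + img)
  }
  dimnames(events) <- list(NULL, c("onset_ms", "offset_ms"))
  structure(
    list(experiment = as.integer(experiment), duration_s = duration_s,
         duration_ms = dur_ms, category = category, events = events),
    class = "trial_spec")
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf("Trial: experiment %d, %g s, category '%s', %d image event(s)\n",
              x$experiment, x$duration_s, x$category, nrow(x$events)))
  invisible(x)
}

#' Assemble trials into a run
#'
#' Lays out trials sequentially with a shared blank baseline before, between
#' and after them, so the run duration is the sum of trial durations plus
#' `(n_trials + 1) * baseline_s`.
#'
#' @param trials A list of [build_trial()] objects, in presentation order.
#' @param baseline_s Baseline (blank screen) duration in seconds; default 12.
#' @return A `run_design` object: list with `trials` (each gaining an
#'   `onset_ms` field), `baseline_s`, `total_duration_s` and `experiment`
#'   (the common experiment id, or NA for mixed runs).
#' @examples
#' run <- build_run(list(build_trial(1, 3, "face")))
#' run$total_duration_s  # 12 + 3 + 12
#' @export
build_run <- function(trials, baseline_s = 12) {
  if (length(trials) == 0) stop("a run needs at least one trial", call. = FALSE)
  if (!all(vapply(trials, inherits, logical(1), "trial_spec")))
    stop("'trials' must be a list of trial_spec objects", call. = FALSE)
  if (baseline_s <= 0) stop("baseline_s must be positive", call. = FALSE)
  base_ms <- round(baseline_s * 1000)
  t <- base_ms
  for (i in seq_along(trials)) {
    trials[[i]]$onset_ms <- t
    t <- t + trials[[i]]$duration_ms + base_ms
  }
  exps <- unique(vapply(trials, `[[`, integer(1), "experiment"))
  structure(
    list(trials = trials, baseline_s = baseline_s,
         total_duration_s = t / 1000,
         experiment = if (length(exps) == 1) exps else NA_integer_),
    class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf("Run design: %d trial(s), %g-s baselines, %g s total (experiment %s)\n",
              length(x$trials), x$baseline_s, x$total_duration_s,
              ifelse(is.na(x$experiment), "mixed", x$experiment)))
  invisible(x)
}

#' Full-permutation run for one experiment
#'
#' Convenience constructor for the canonical 270-s run: one trial for every
#' permutation of category (face/body/word) and duration (3, 5, 10, 20 s),
#' separated by 12-s baselines. The presentation order is deterministic by
#' default; pass a `seed` to emulate the randomized order used in the scanner.
#'
#' @param experiment Experiment id (1, 2 or 3).
#' @param durations Trial durations in seconds.
#' @param categories Stimulus categories.
#' @param baseline_s Baseline duration in seconds.
#' @param seed Optional integer; when given, trial order is shuffled
#'   reproducibly.
#' @return A [build_run()] design.
#' @examples
#' experiment_run(1)$total_duration_s  # 270
#' @export
experiment_run <- function(experiment, durations = c(3, 5, 10, 20),
                           categories = c("face", "body", "word"),
                           baseline_s = 12, seed = NULL) {
  grid <- expand.grid(duration = durations, category = categories,
                      stringsAsFactors = FALSE)
  if (!is.null(seed)) {
    ord <- local({ set.seed(seed); sample.int(nrow(grid)) })
    grid <- grid[ord, ]
  }
  trials <- mapply(function(d, cat) build_trial(experiment, d, cat),
                   grid$duration, grid$category, SIMPLIFY = FALSE)
  build_run(trials, baseline_s = baseline_s)
}

#' Render a run as a millisecond-resolution step function
#'
#' Codes the transitions between stimulus and baseline as a binary step
#' function per category: sample i covers `[(i-1)*res, i*res)` ms and is 1
#' when an image of that category is on at the sample onset.
#'
#' @param run A [build_run()] design.
#' @param resolution_ms Sampling resolution in ms; must divide 1000.
#'   The default 1-ms grid represents all canonical event timings exactly.
#' @param categories Category columns to render (default: the canonical
#'   three, so runs missing a category still produce aligned columns).
#' @return A `step_function`: integer matrix (time samples x categories) with
#'   attributes `resolution_ms` and `total_ms`.
#' @examples
#' s <- render_step_function(build_run(list(build_trial(2, 3, "body"))))
#' colSums(s)[["body"]]  # 990 ms of stimulus on
#' @export
render_step_function <- function(run, resolution_ms = 1,
                                 categories = c("face", "body", "word")) {
  stopifnot(inherits(run, "run_design"))
  if (resolution_ms < 1 || 1000 %% resolution_ms != 0)
    stop("resolution_ms must be a positive divisor of 1000", call. = FALSE)
  total_ms <- round(run$total_duration_s * 1000)
  n <- total_ms %/% resolution_ms
  out <- matrix(0L, n, length(categories), dimnames = list(NULL, categories))
  prev_end <- -1
  for (tr in run$trials) {
    if (tr$onset_ms < prev_end)
      stop("overlapping trials in run design", call. = FALSE)
    prev_end <- tr$onset_ms + tr$duration_ms
    if (!tr$category %in% categories) next
    ev <- tr$events + tr$onset_ms
    # sample i (1-based) starts at (i-1)*res; on iff onset <= start < offset
    for (j in seq_len(nrow(ev))) {
      i0 <- ceiling(ev[j, 1] / resolution_ms) + 1
      i1 <- ceiling(ev[j, 2] / resolution_ms)
      if (i1 >= i0) out[i0:min(i1, n), tr$category] <- 1L
    }
  }
  structure(out, resolution_ms = resolution_ms, total_ms = total_ms,
            class = c("step_function", "matrix"))
}

#' Recover stimulus intervals from a step function
#'
#' Inverse of [render_step_function()] at native resolution: returns the
#' half-open `[onset, offset)` intervals (in ms, run clock) during which each
#' category's channel is on.
#'
#' @param step A `step_function`.
#' @return Named list of two-column matrices (onset_ms, offset_ms).
#' @export
step_events <- function(step) {
  res <- attr(step, "resolution_ms")
  lapply(stats::setNames(colnames(step), colnames(step)), function(cat) {
    x <- c(0L, step[, cat], 0L)
    d <- diff(x)
    on <- which(d == 1L)
    off <- which(d == -1L)
    cbind(onset_ms = (on - 1) * res, offset_ms = (off - 1) * res)
  })
}

#' Stimulus onset times per category
#'
#' @param run A `run_design`.
#' @return Named list (by category) of stimulus onset times in ms on the run
#'   clock, sorted.
#' @keywords internal
run_onsets <- function(run) {
  cats <- unique(vapply(run$trials, `[[`, character(1), "category"))
  out <- stats::setNames(vector("list", length(cats)), cats)
  for (tr in run$trials)
    out[[tr$category]] <- c(out[[tr$category]], tr$events[, 1] + tr$onset_ms)
  lapply(out, sort)
}
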