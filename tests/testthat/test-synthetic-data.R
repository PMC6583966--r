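test_that("generation is exactly reproducible given a seed", {
  truth <- ground_truth("ventral-like", noise_sd = 0.4)
  d1 <- generate_dataset(truth, n_runs = 1, seed = 7)
  d2 <- generate_dataset(truth, n_runs = 1, seed = 7)
  d3 <- generate_dataset(truth, n_runs = 1, seed = 8)
  expect_identical(d1$series, d2$series)
  expect_false(identical(d1$series, d3$series))
})

test_that("default designs reproduce the canonical acquisition structure", {
  truth <- ground_truth("ventral-like", noise_sd = 0.1)
  dat <- generate_dataset(truth, seed = 1)   # 4 runs x 3 experiments
  expect_length(dat$designs, 12)
  expect_equal(sort(unique(sapply(dat$designs, `[[`, "experiment"))), 1:3)
  expect_equal(table(sapply(dat$designs, `[[`, "experiment")),
               table(rep(1:3, each = 4)), ignore_attr = TRUE)
  for (d in dat$designs) {
    expect_equal(d$total_duration_s, 270)
    expect_equal(d$baseline_s, 12)
    expect_length(d$trials, 12)
  }
  expect_length(dat$series[[1]], 270)
})

test_that("residual spread matches the requested noise level", {
  truth <- ground_truth("ventral-like", noise_sd = 0.35)
  dat <- generate_dataset(truth, seed = 3)
  resid <- unlist(dat$series) - unlist(dat$clean)
  expect_equal(stats::sd(resid), 0.35, tolerance = 0.1)
  # snr overrides noise_sd on the peak-signal scale
  dat5 <- generate_dataset(truth, n_runs = 1, snr = 5, seed = 3)
  expect_equal(dat5$noise_sd, max(abs(unlist(dat5$clean))) / 5, tolerance = 1e-12)
  # AR(1) noise keeps the requested marginal spread
  t_ar <- ground_truth("ventral-like", noise_sd = 0.35, noise_model = "ar1")
  resid_ar <- unlist(generate_dataset(t_ar, seed = 3)$series) -
    unlist(generate_dataset(t_ar, seed = 3)$clean)
  expect_equal(stats::sd(resid_ar), 0.35, tolerance = 0.1)
  expect_gt(stats::cor(resid_ar[-1], resid_ar[-length(resid_ar)]), 0.15)
})

test_that("noiseless data refit by the generating variant explain everything", {
  truth <- ground_truth("ventral-like", noise_sd = 0)
  dat <- generate_dataset(truth, n_runs = 2, seed = 4)
  cv <- cross_validate(dat, variant = "A+S", params = truth$params,
                       optimize = FALSE)
  expect_equal(unname(cv$x_r2[["overall"]]), 1, tolerance = 1e-9)
  fit <- tcm(dat, variant = "A+S", optimize = FALSE, params = truth$params)
  expect_equal(unname(fit$betas["sustained", ]), unname(truth$beta_S),
               tolerance = 1e-9)
  expect_equal(unname(fit$betas["transient", ]), unname(truth$beta_T),
               tolerance = 1e-9)
})

test_that("flashed-image trials outdrive matched continuous trials under adaptation", {
  # the qualitative signature of strong fMRI-adaptation: 30 brief flashes
  # produce higher peaks than one continuous image of the same trial length
  # (asserted for the 3-10-s trials; at 633-ms ISIs the flashes become too
  # sparse for the summed transients to dominate)
  truth <- ground_truth("ventral-like")
  dat <- generate_dataset(truth, n_runs = 1, seed = 5)
  exps <- sapply(dat$designs, `[[`, "experiment")
  peak_tab <- function(i) {
    d <- dat$designs[[i]]
    w <- t(sapply(d$trials, function(tr)
      c(tr$onset_ms / 1000, (tr$onset_ms + tr$duration_ms) / 1000)))
    data.frame(dur = sapply(d$trials, `[[`, "duration_s"),
               cat = sapply(d$trials, `[[`, "category"),
               peak = peak_trial_amplitude(dat$clean[[i]], w))
  }
  m <- merge(peak_tab(which(exps == 1)[1]), peak_tab(which(exps == 2)[1]),
             by = c("dur", "cat"), suffixes = c(".e1", ".e2"))
  m <- m[m$dur <= 10, ]
  expect_true(all(m$peak.e2 > m$peak.e1))
})

test_that("a pure-transient truth yields near-zero sustained weights when refit", {
  truth <- ground_truth("lateral-like")
  for (s in 41:43) {
    dat <- generate_dataset(truth, n_runs = 2, snr = 5, seed = s)
    fit <- tcm(dat, variant = "A+S", control = tcm_control(iter_max = 8))
    ratio <- channel_ratio(fit$betas["sustained", ], fit$betas["transient", ])
    expect_lt(mean(ratio), 0.1)
  }
})

test_that("offset-dominant transients are recovered as offset-dominant", {
  # strongly asymmetric sigmoid truth in the graded regime, refit at the
  # canonical acquisition size (4 runs per experiment), SNR 5
  truth <- ground_truth("ventral-like", lam = 0.3, k_on = 3, k_off = 0.5,
                        noise_sd = 0)
  expect_gt(balance_metric(truth$params[["k_on"]], truth$params[["k_off"]]), 0.5)
  bal <- sapply(1:10, function(s) {
    dat <- generate_dataset(truth, n_runs = 4, snr = 5, seed = s)
    fit <- tcm(dat, variant = "A+S",
               control = tcm_control(iter_max = 30, rel_tol = 1e-8))
    balance_metric(fit$params[["k_on"]], fit$params[["k_off"]])
  })
  expect_true(all(bal > 0.5))
})

test_that("a balanced sigmoid truth is recovered as balanced on average", {
  truth <- ground_truth("ventral-like", lam = 0.3, k_on = 3, k_off = 3,
                        noise_sd = 0)
  bal <- sapply(1:20, function(s) {
    dat <- generate_dataset(truth, n_runs = 2, snr = 5, seed = s)
    fit <- tcm(dat, variant = "A+S",
               control = tcm_control(iter_max = 12, rel_tol = 1e-7))
    balance_metric(fit$params[["k_on"]], fit$params[["k_off"]])
  })
  expect_lt(abs(mean(bal) - 0.5), 0.1)
})

test_that("recovery experiments report bias for every parameter and weight", {
  truths <- list(ventral = ground_truth("ventral-like"))
  rep_tab <- recovery_experiment(truths, snrs = c(5, 10), seeds = 1:2,
                                 n_runs = 2, optimize = FALSE)
  expect_s3_class(rep_tab, "data.frame")
  expect_setequal(names(rep_tab),
                  c("truth", "snr", "seed", "quantity", "true", "recovered",
                    "error"))
  # 5 nonlinear params + 6 weights per cell, 2 snrs x 2 seeds
  expect_equal(nrow(rep_tab), 4 * 11)
  expect_true(all(is.finite(rep_tab$error)))
  # at high SNR without re-optimization the weights are close to truth
  w <- rep_tab[rep_tab$snr == 10 & grepl("beta", rep_tab$quantity), ]
  expect_lt(max(abs(w$error)), 0.2)
})

test_that("datasets serialize to per-run TSVs plus a truth sidecar", {
  truth <- ground_truth("lateral-like", noise_sd = 0.2)
  dat <- generate_dataset(truth, n_runs = 1, seed = 9)
  dir <- withr::local_tempdir()
  write_dataset(dat, dir)
  expect_length(list.files(dir, pattern = "run[0-9]+\\.tsv"), 3)
  side <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(side$seed, 9)
  expect_equal(side$preset, "lateral-like")
  expect_equal(unlist(side$beta_S), c(face = 0, body = 0, word = 0))
  run1 <- utils::read.delim(file.path(dir, "run01.tsv"))
  expect_equal(names(run1), c("t_s", "signal"))
  expect_equal(run1$signal, dat$series[[1]], tolerance = 1e-12)
})
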