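test_that("the canonical HRF is a unit-peak double gamma peaking near 5 s", {
  h <- canonical_hrf(10)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_equal((which.max(h) - 1) * 10 / 1000, 5, tolerance = 0.02)
  # late tail is negligible relative to peak
  late <- h[seq_along(h) > 30 * 100]
  expect_lt(max(abs(late)), 1e-3)
  # undershoot present and scaled down
  expect_lt(min(h), 0)
  expect_gt(min(h), -0.5)
})

test_that("predict_bold equals the dense convolution sampled at TR onsets", {
  res <- 10
  hrf <- canonical_hrf(res)
  set.seed(2)
  neural <- c(numeric(200), runif(600), numeric(1200))  # 20 s at 10 ms
  fast <- predict_bold(neural, hrf, tr_s = 1, resolution_ms = res)
  oracle <- brute_tr_sample(neural, as.numeric(hrf), spb = 100)
  expect_equal(length(fast), 20)
  expect_lt(max(abs(fast - oracle)), 1e-9)
  expect_equal(predict_bold(numeric(3000), hrf, resolution_ms = res),
               numeric(30))
  expect_error(predict_bold(numeric(2550), hrf, resolution_ms = res),
               "multiple of the TR")
})

test_that("a 33-ms flash produces a predictor with the HRF's shape", {
  hrf <- canonical_hrf(1)
  neural <- c(numeric(2000), rep(1, 33), numeric(30967))
  p <- predict_bold(neural, hrf)
  hs <- predict_bold(c(numeric(2000), 1, numeric(30999)), hrf)
  expect_gt(stats::cor(p, hs), 0.9999)
  expect_equal(which.max(p) - 1, 2 + 5, tolerance = 0.3)
})

test_that("design matrices count, label and normalize their columns", {
  designs <- list(experiment_run(1), experiment_run(2), experiment_run(3),
                  experiment_run(1, seed = 1))
  X <- build_design_matrix(designs, "A+S")
  expect_equal(ncol(X), 2 * 3 + 4)
  expect_equal(nrow(X), 4 * 270)
  expect_setequal(grep("intercept", colnames(X), value = TRUE),
                  paste0("intercept.run", 1:4))
  # max height matched across channels after normalization
  expect_equal(max(X[, grep("^sustained", colnames(X))]),
               max(X[, grep("^transient", colnames(X))]))
  # single-channel variants have one block
  XS <- build_design_matrix(designs[1:2], "S")
  expect_equal(ncol(XS), 3 + 2)
  expect_true(all(grepl("^(transient|intercept)", colnames(XS))))
  expect_error(build_design_matrix(designs[1], "XYZ"), "unknown model variant")
})

test_that("the GLM benchmark is a single convolution of the boxcar with the HRF", {
  run <- build_run(list(build_trial(1, 3, "face"), build_trial(2, 5, "body")))
  X <- build_design_matrix(run, "GLM")
  step <- render_step_function(run)
  hrf <- canonical_hrf(1)
  man <- cbind(predict_bold(step[, "face"], hrf),
               predict_bold(step[, "body"], hrf))
  man <- man / max(man)
  expect_equal(unname(X[, c("glm.face", "glm.body")]), man, tolerance = 1e-12)
})

test_that("the design-matrix pipeline equals the composed public operations", {
  # the internal per-trial segmented evaluation must be algebraically
  # identical to step -> IRF convolution -> nonlinearity -> HRF -> TR sampling
  run <- build_run(list(build_trial(1, 3, "face"), build_trial(2, 3, "body"),
                        build_trial(3, 5, "word")))
  params <- c(tau = 6.2, alpha = 14, lam = 0.12, k_on = 2.5, k_off = 1.2)
  step <- render_step_function(run)
  irf <- make_irfs(params[["tau"]])
  hrf <- canonical_hrf(1)
  ons <- sustran:::run_onsets(run)
  dense <- list()
  for (cat in colnames(step)) {
    ds <- convolve_channel(step[, cat], irf$sustained)
    ds <- apply_adaptation(ds, if (is.null(ons[[cat]])) numeric(0) else ons[[cat]],
                           params[["alpha"]])
    dt <- convolve_channel(step[, cat], irf$transient) / irf$onset_norm
    dt <- sigmoid_rectifier(dt, params[["lam"]], params[["k_on"]], params[["k_off"]])
    dense[[paste0("sustained.", cat)]] <- predict_bold(ds, hrf)
    dense[[paste0("transient.", cat)]] <- predict_bold(dt, hrf)
  }
  D <- do.call(cbind, dense)
  for (ch in c("sustained", "transient")) {
    block <- grep(ch, colnames(D))
    D[, block] <- D[, block] / max(D[, block])
  }
  X <- build_design_matrix(run, "A+S", params)
  expect_lt(max(abs(X[, colnames(D)] - D)), 1e-12)
})

test_that("predictors are insensitive to the working resolution (low-pass HRF)", {
  run <- experiment_run(1)   # exp-1 events lie on every grid that divides 1000
  X1 <- build_design_matrix(run, "L", c(tau = 8), resolution_ms = 1)
  X2 <- build_design_matrix(run, "L", c(tau = 8), resolution_ms = 2)
  d <- X1[, 1:3] - X2[, 1:3]
  expect_lt(sqrt(mean(d^2)) / max(X1[, 1:3]), 0.001)
})

test_that("non-negative neural responses give non-negative predictors", {
  designs <- list(experiment_run(2))
  # with a non-negative HRF the predictors inherit the neural sign exactly;
  # the canonical HRF's undershoot can only dip them by its own ratio
  hrf_pos <- canonical_hrf(1, undershoot_ratio = 0)
  for (v in c("GLM", "L", "CTS", "A", "S", "A+S", "L+Q")) {
    Xp <- build_design_matrix(designs, v, hrf = hrf_pos)
    pred <- Xp[, grep("intercept", colnames(Xp), invert = TRUE), drop = FALSE]
    expect_gt(min(pred), -1e-12)
    X <- build_design_matrix(designs, v)
    pred <- X[, grep("intercept", colnames(X), invert = TRUE), drop = FALSE]
    expect_gt(min(pred), -1 / 6)
  }
})
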