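test_that("channel IRFs have the analytic shape of the gamma cascade", {
  irf <- make_irfs(4.93)
  # gamma density mode at (n1 - 1) * tau; kernel sampled at bin midpoints
  expect_equal((which.max(irf$sustained) - 0.5) * irf$resolution_ms,
               8 * 4.93, tolerance = 1 / (8 * 4.93))
  expect_true(all(irf$sustained >= 0))
  expect_equal(sum(irf$sustained), 1)
  expect_lt(abs(sum(irf$transient)), 1e-6)
  expect_equal(sum(irf$transient[irf$transient > 0]), 1)
  # biphasic: positive lobe first, then negative
  expect_lt(which.max(irf$transient), which.min(irf$transient))
  expect_error(make_irfs(4.93, resolution_ms = 10), "too coarse")
})

test_that("channel convolution matches a brute-force oracle and its identities", {
  irf <- make_irfs(8, resolution_ms = 2)
  expect_equal(convolve_channel(numeric(500), irf$sustained), numeric(500))
  imp <- numeric(400)
  imp[25] <- 1
  out <- convolve_channel(imp, irf$sustained)
  L <- min(length(irf$sustained), 376)
  expect_equal(out[25:(24 + L)], irf$sustained[1:L])
  expect_equal(out[1:24], numeric(24))
  set.seed(5)
  x <- as.numeric(runif(300) > 0.6)
  expect_equal(convolve_channel(x, irf$sustained), brute_conv(x, irf$sustained),
               tolerance = 1e-12)
  expect_equal(convolve_channel(x, irf$transient), brute_conv(x, irf$transient),
               tolerance = 1e-12)
  # unit-area sustained kernel: long stimulus drive plateaus at 1
  long <- convolve_channel(rep(1, 3000), make_irfs(4.93)$sustained)
  expect_equal(long[3000], 1, tolerance = 1e-9)
})

test_that("adaptation decays to 1/e at t = alpha and resets at each onset", {
  alpha <- 20
  drive <- rep(1, 25000)
  ad <- apply_adaptation(drive, 0, alpha_s = alpha)
  expect_equal(ad[alpha * 1000 + 1] / ad[1], exp(-1), tolerance = 1e-9)
  # ~37% of the initial response
  expect_equal(round(ad[alpha * 1000 + 1], 2), 0.37)
  # second onset restores the multiplier to 1
  ad2 <- apply_adaptation(drive, c(0, 10000), alpha_s = alpha)
  expect_equal(ad2[10001], 1)
  expect_lt(ad2[10000], 1)
  # alpha at its upper bound with t << alpha leaves the drive nearly linear
  ad3 <- apply_adaptation(rep(1, 3000), 0, alpha_s = 40)
  expect_gt(min(ad3), 0.9)
})

test_that("CTS is a static power law on the sustained drive", {
  expect_equal(apply_cts(c(0, 0.3, 1), 1), c(0, 0.3, 1))
  expect_equal(apply_cts(0.25, 0.5), 0.5)
  expect_error(apply_cts(c(-0.2, 0.5), 0.5), "non-negative")
  # compression of the 1 vs 0.1 response ratio grows as epsilon shrinks
  ratios <- vapply(seq(1, 0.05, by = -0.05),
                   function(e) apply_cts(1, e) / apply_cts(0.1, e), numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("sigmoid rectifier follows the two-branch cumulative Weibull", {
  expect_equal(sigmoid_rectifier(0, 0.1, 3, 1), 0)
  for (k in c(0.5, 1, 3, 6))
    expect_equal(sigmoid_rectifier(0.1, 0.1, k, 1), 1 - exp(-1))
  # symmetric when k_on = k_off
  x <- seq(-1, 1, by = 0.01)
  expect_equal(sigmoid_rectifier(x, 0.2, 2, 2), sigmoid_rectifier(-x, 0.2, 2, 2))
  # piecewise definition against direct evaluation
  expect_equal(sigmoid_rectifier(-0.3, 0.2, 2, 0.7),
               1 - exp(-(0.3 / 0.2)^0.7))
  # monotone in |x| on each branch, bounded in [0, 1)
  y <- sigmoid_rectifier(seq(0, 5, by = 0.01), 0.2, 1.5, 3)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 1))   # sup is 1, reached only in the limit
  expect_lt(sigmoid_rectifier(0.6, 0.2, 1.5, 3), 1)
})

test_that("smaller k elongates the transient response to a biphasic lobe", {
  irf <- make_irfs(4.93)
  lobe <- convolve_channel(c(rep(1, 500), rep(0, 1500)), irf$transient) /
    irf$onset_norm
  totals <- vapply(seq(0.5, 6, by = 0.5), function(k)
    sum(sigmoid_rectifier(lobe, 0.1, k, k)), numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("quadratic rectifier squares the drive", {
  expect_equal(quadratic_rectifier(0), 0)
  expect_equal(quadratic_rectifier(-0.5), 0.25)
  set.seed(1)
  x <- rnorm(50)
  expect_equal(quadratic_rectifier(x), vapply(x, function(v) v * v, numeric(1)))
})

test_that("transient onset response saturates: identical for 1-s and 10-s stimuli", {
  irf <- make_irfs(4.93)
  mk <- function(dur_ms) {
    step <- c(numeric(1000), rep(1, dur_ms), numeric(12000))
    sigmoid_rectifier(convolve_channel(step, irf$transient) / irf$onset_norm,
                      0.1, 3, 3)
  }
  r1 <- mk(1000)
  r10 <- mk(10000)
  # compare the onset window (stimulus onset + full IRF support)
  w <- 1000 + seq_len(length(irf$transient))
  expect_lt(max(abs(r1[w] - r10[w])), 1e-9)
})

test_that("with alpha at its bound the A model approaches the L model", {
  run <- build_run(list(build_trial(1, 3, "face"), build_trial(2, 3, "body"),
                        build_trial(3, 3, "word")))
  XL <- build_design_matrix(run, "L", c(tau = 4.93))
  XA <- build_design_matrix(run, "A", c(tau = 4.93, alpha = 40))
  # compare peaks on the unnormalized scale (undo max-height scaling)
  for (col in grep("sustained", colnames(XL), value = TRUE)) {
    pL <- max(XL[, col]) * attr(XL, "normalization")[["sustained"]]
    pA <- max(XA[, col]) * attr(XA, "normalization")[["sustained"]]
    if (pL == 0) next
    expect_lt(abs(pA - pL) / pL, 0.15)
  }
})
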