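# sustran

Two-temporal-channel encoding models of fMRI responses: predicting
second-resolution BOLD time series of a region of interest (ROI) from the
millisecond timing of visual stimulation.

## Why

High-level visual cortex responds very differently to one continuous image
and to a train of brief flashes, even when the total stimulation time
matches — behaviour a standard general linear model (stimulus boxcar ⊗
hemodynamic response function) cannot reproduce. `sustran` models the
neural stage explicitly at millisecond resolution with two channels before
the hemodynamics:

```
BOLD(t) = β_S {[(s ⊗ IRF_S) · e^(−t/α)] ⊗ HRF} + β_T {σ(s ⊗ IRF_T) ⊗ HRF}
σ(x) = 1 − exp[−(x/λ)^k_on]  (x ≥ 0),   1 − exp[−(−x/λ)^k_off]  (x < 0)
```

* the **sustained** channel: monophasic neural impulse response (gamma
  cascade, time constant τ) with exponential fMRI-adaptation (decay α,
  restarting at every stimulus onset);
* the **transient** channel: biphasic, zero-area impulse response whose
  onset and offset lobes are compressed by separate cumulative-Weibull
  sigmoids (scale λ, shapes k_on and k_off);
* channel predictions are convolved with the canonical HRF, downsampled to
  TR = 1 s, max-height normalized across channels, and weighted per
  stimulus category by OLS (β_S, β_T).

τ, α, λ, k_on, k_off are estimated by bounded nonlinear least squares
(τ 4–20 ms, α 10–40 s, λ 0.01–0.5, k 0.1–6) and models are scored by
split-half cross-validated R². The asymmetry of the fitted sigmoids is
summarized by the balance metric `k_on / (k_on + k_off)`: 0.5 means onset
and offset responses contribute equally, larger values mean offset-dominant
responses. Alternative architectures (GLM benchmark, L, CTS, A, S, L+Q,
C+Q, A+Q) are available under the same interface for model comparison, and
a seeded generator produces synthetic ROI datasets with the canonical
design (three experiments of 270-s runs: continuous images, 33-ms flashes,
33-ms gaps; 12 trials/run; 12-s baselines) for validation and simulation
studies.

## Worked example

Simulate a "ventral-like" ROI (both channels active, strong adaptation,
offset-dominant transients, moderate noise), refit the full A+S model, and
cross-validate:

```r
library(sustran)
truth <- ground_truth("ventral-like", noise_sd = 0.15)
dat   <- generate_dataset(truth, n_runs = 2, seed = 42)
fit   <- tcm(dat, variant = "A+S", control = tcm_control(iter_max = 30))
fit
#> Two-temporal-channel encoding model (A+S variant)
#>   6 run(s), 1620 time points, R^2 = 0.824
#>   parameters:
#>    tau  alpha    lam   k_on  k_off
#>  5.042 15.307  0.096  1.241  0.413
#>   channel weights (beta):
#>            face  body  word
#> sustained 0.892 0.354 0.333
#> transient 1.131 0.500 0.412

balance_metric(fit$params[["k_on"]], fit$params[["k_off"]])
#> [1] 0.7502337

cross_validate(dat, variant = "A+S", control = tcm_control(iter_max = 15))$x_r2
#>    exp1    exp2    exp3 overall
#>   0.593   0.746   0.892   0.744
```

The generating truth had τ = 4.93 ms, α = 15 s and balance 0.77, with
face-selective weights (β 0.9/0.35/0.3 sustained, 1.1/0.5/0.45 transient):
the fit recovers the timing constants, the category selectivity of both
channels and the offset dominance of the transient channel, and explains
~74% of held-out variance. `compare_models()` tabulates cross-validated R²
across variants on identical folds; `metrics_table()` collects balance,
|β_S/β_T| ratios and contrast effect sizes into a tidy table.

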