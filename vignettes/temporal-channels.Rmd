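---
title: "Modelling sustained and transient temporal channels in fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sustained and transient temporal channels in fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

fMRI samples brain activity about once per second, yet the neural populations
it measures respond to visual events on a millisecond scale. When the same
amount of visual stimulation is delivered either as one continuous image or
as a train of brief flashes, measured BOLD responses in high-level visual
cortex differ dramatically — far more than a linear convolution of the
stimulus with a hemodynamic response function (HRF) can explain. `sustran`
implements an encoding-model family that bridges the two time scales: a
millisecond-resolution neural stage with separate *sustained* and
*transient* temporal channels and channel-specific nonlinearities, followed
by a linear hemodynamic stage.

## The model

For each stimulus category the binary stimulus time course \(s(t)\) (1-ms
resolution) is passed through two neural channels:

* **Sustained channel.** \(s\) is convolved with a monophasic impulse
  response function (IRF) and multiplied by an exponential fMRI-adaptation
  term that restarts at every stimulus onset:
  \((s \otimes \mathrm{IRF}_S)(t)\, e^{-(t - t_{on})/\alpha}\). At
  \(t - t_{on} = \alpha\) the response has decayed to \(1/e\) (~37%) of its
  unadapted value.
* **Transient channel.** \(s\) is convolved with a biphasic IRF whose net
  area is zero, so it responds only at stimulus onsets (positive lobe) and
  offsets (negative lobe). Both lobes are compressed by separate cumulative
  Weibull sigmoids,
  \(\sigma(x) = 1 - e^{-(x/\lambda)^{k_{on}}}\) for \(x \ge 0\) and
  \(1 - e^{-(-x/\lambda)^{k_{off}}}\) for \(x < 0\),
  mapping both to non-negative responses in \([0, 1)\).

Each channel's neural response is convolved with the canonical HRF,
downsampled to the repetition time (TR = 1 s), max-height normalized across
channels, and weighted by category-specific amplitudes \(\beta_S\) and
\(\beta_T\) estimated by ordinary least squares with per-run intercepts.

The IRFs are cascades of leaky integrators (gamma densities): the sustained
kernel has `n1 = 9` stages with time constant \(\tau\); the transient kernel
is the difference between that filter and a slower one (`n2 = 10` stages,
time constant \(\kappa\tau\), \(\kappa = 1.33\)), rescaled to unit
positive-lobe area. Only \(\tau\) is free; the cascade constants are fixed.
Because the difference-of-gammas normalization is not uniquely determined,
we additionally scale the transient *drive* so that an isolated onset of a
long stimulus peaks at exactly 1 — this makes the sigmoid scale \(\lambda\)
(bounds 0.01–0.5) interpretable as a fraction of the maximal onset drive,
and the choice is recorded in the IRF object's metadata.

Alternative architectures are available under the same interface: a `GLM`
benchmark (stimulus boxcar convolved once with the HRF), single-channel
variants `L` (linear sustained), `CTS` (compressive power law
\(x^\varepsilon\)), `A` (adaptation) and `S` (sigmoid transient only), and
dual-channel variants `L+Q`, `C+Q`, `A+Q` that replace the sigmoid with a
quadratic (squaring) transient nonlinearity.

## Parameters, bounds and optimization

| parameter | meaning | units | bounds | initial |
|---|---|---|---|---|
| \(\tau\) | IRF time constant | ms | 4–20 | 4.93 |
| \(\alpha\) | adaptation decay | s | 10–40 | 20 |
| \(\varepsilon\) | CTS exponent | — | 0.01–1 | 0.1 |
| \(\lambda\) | sigmoid scale | fraction of peak drive | 0.01–0.5 | 0.1 |
| \(k_{on}\), \(k_{off}\) | sigmoid shapes | — | 0.1–6 | 3 |

The nonlinear parameters are estimated by minimizing the residual sum of
squares of the nested OLS fit over concatenated training runs, under box
constraints, starting from the initial values above. The default engine is
bounded Levenberg–Marquardt on the residual vector
(`minpack.lm::nls.lm`), which exploits the least-squares structure;
`stats::nlminb` on the summed objective is available through
`tcm_control(engine = "nlminb")`. Optimization is deterministic from the
single canonical start; a seeded multi-start is available
(`tcm_control(multistart = n)`) but off by default, matching the original
single-start procedure. Non-convergence is flagged in the `opt` element and
the best point so far is returned; the final objective never exceeds the
initial one.

Model evaluation uses split-half cross-validation: runs of every experiment
are split in half, parameters and weights are estimated on one half, and
variance explained (x-R²) is computed on the complementary half, per
experiment and overall (the mean across experiments), averaged over both
fold directions. x-R² is \(1 - SS_{res}/SS_{tot}\) on the held-out series
with per-run intercepts removed from both data and prediction before
scoring; it is negative whenever the residual variance of a poor prediction
exceeds the measured variance.

## The experimental designs

The three emulated experiments share trial durations (3, 5, 10, 20 s),
categories (faces, bodies, words) and 12-s blank baselines before and after
every trial, and differ only in how images tile a trial: experiment 1 shows
one continuous image; experiment 2 shows 30 flashes of 33 ms with
interstimulus intervals of 67/133/300/633 ms for the four durations;
experiment 3 shows 30 images of 67/133/300/633 ms separated by constant
33-ms gaps. A run contains every category × duration permutation once
(12 trials, 270 s); the canonical acquisition is four runs per experiment.
Cycle lengths that are not integer milliseconds (the 20-s trials) are
floored to the millisecond and the sub-millisecond remainder is left as
blank at the end of the trial, which reproduces the printed 633-ms values
on an exact 1-ms grid. Intervals are half-open `[onset, offset)` on a
0-based clock.

## Numerical choices

* **Working resolution.** 1 ms by default; coarser grids are accepted when
  they divide 1000 ms, but only the 1-ms grid represents the 33-ms event
  timings exactly.
* **Kernels.** IRFs are sampled at bin midpoints and truncated where the
  remaining mass of the slowest gamma filter is below 1e-6 of total; the
  sustained kernel is renormalized to unit sum, so a long stimulus drives
  it to a plateau of exactly 1. The HRF is a double gamma (peak 5 s,
  undershoot 15 s, ratio 1/6, unit peak, truncated at 32 s) and is
  swappable in every fitting function for a reference kernel.
* **Downsampling.** BOLD predictors are the dense millisecond convolution
  evaluated at TR onsets (the HRF is a strong low-pass filter, so sampling
  at 1 s loses essentially nothing); windowed averaging was considered and
  rejected as it blurs the contract with the dense-convolution oracle.
* **Exact segmented evaluation.** Internally, neural responses are only
  computed on the short window where each trial's drive is nonzero (trial
  plus IRF support), and the HRF stage is evaluated as an exact banded
  matrix product per trial. This is algebraically identical to the naive
  full-run pipeline (the test suite checks equality to 1e-12) but two
  orders of magnitude faster, which is what makes the simulation studies
  below tractable.
* **Degenerate inputs.** Rank-deficient design matrices are rejected with
  the aliased columns named; a zero transient weight makes the
  sustained/transient ratio undefined and it is reported as missing, not
  infinite; the noise ceiling is undefined with fewer than two trials per
  condition and errors accordingly.

## The synthetic-data generator

`generate_dataset()` forward-simulates ROI time series from a ground-truth
parameter set: the truth's variant is evaluated on the canonical designs
(by default four 270-s runs of each experiment), weighted by the truth's
channel weights, and white Gaussian noise (optionally AR(1), \(\rho=0.3\))
is added with a seed recorded in the sidecar. `snr` expresses noise as peak
signal over noise SD. Two presets bracket the response regimes the model
family separates. Their values are illustrative, not fitted values:

* `ventral-like` — both channels contribute, strong adaptation
  (\(\alpha = 15\) s), offset-dominant sigmoid (\(k_{on} = 3.35\),
  \(k_{off} = 1\), balance \(k_{on}/(k_{on}+k_{off}) = 0.77\)),
  category-selective weights in both channels.
* `lateral-like` — transient-only (\(\beta_S = 0\)) with balanced sigmoids
  (\(k_{on} = k_{off} = 3\), balance 0.5).

The preset \(\lambda\) is 0.1. This choice matters: identifiability of the
sigmoid shapes depends on where the drive lobes fall on the sigmoid. When
\(\lambda\) is small relative to the lobes the sigmoid saturates and large
\(k\) values become indistinguishable, so simulation studies that probe
*noisy* shape recovery use a truth in the graded regime
(\(\lambda = 0.3\)) with a strong on/off contrast (\(k_{on} = 3\),
\(k_{off} = 0.5\)) at the full four-runs-per-experiment acquisition —
with fewer runs, single noise realizations can genuinely favour
balance-flipped parameter sets. Conversely, noiseless generative-identity
checks use the preset, whose basin the canonical single start reaches
exactly.

What the generator does *not* emulate: voxel-level spatial structure,
participant variability, scanner drift and physiological noise, fixation
task events, or actual image content. Tests passing on these synthetic
series therefore establish the internal consistency of the pipeline
(timing, convolution, estimation, model selection), not claims about any
particular cortical region.

## Problem sizes used by the test suite

The simulation studies are sized so the whole suite runs in tens of
minutes on a single core: generative-identity and model-comparison
experiments use two runs per experiment (the minimum for split halves);
the model-selection study uses 50 seeded datasets at SNR 5 with a
12-iteration optimizer budget per fit; noisy shape-recovery studies use
the full four-runs-per-experiment acquisition with 10–20 seeds. The
flash-versus-continuous peak signature is asserted for 3–10-s trials: at
the 633-ms interstimulus intervals of the 20-s flash trials the transients
are too sparse for their summed response to dominate the preset's
sustained component.

## Interfaces

All functionality is exposed as R functions returning classed S3 objects
(`tcm`, `tcm_cv`, `tc_dataset`, ...) with the usual methods; run designs
and fit results serialize to JSON and time series, design matrices and
metrics to TSV (`write_run_design()`, `write_timeseries_tsv()`,
`write_design_tsv()`, `write_fit_json()`, `write_dataset()`,
`metrics_table()`). A shell entry point was considered and dropped: the
package's users drive analyses from R, and the exported functions plus
these serializers cover scripted use.

## Known limitations

* The balloon (nonlinear hemodynamic) comparator is not implemented; its
  standard parameter set lives outside this package's scope.
* Adaptation is modelled in the sustained channel only, and the IRF latency
  does not depend on stimulus contrast.
* The sigmoid shape parameters are only weakly identified when the fitted
  \(\lambda\) saturates the observed drive range; interpret per-fit
  \(k_{on}/k_{off}\) (and the balance metric) at noisy, small-data regimes
  with care — the package reports them per fit so they can be averaged
  across splits or datasets.
* x-R² compares models on held-out runs of the same session; it does not
  correct for the measurement noise floor. `noise_ceiling()` estimates that
  floor from inter-trial variability (split-half reliability,
  Spearman–Brown corrected, squared).
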