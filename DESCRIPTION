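Package: sustran
Title: Two-Temporal-Channel Encoding Models of fMRI Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits encoding models that predict region-of-interest fMRI time
    series from millisecond-resolution stimulus sequences via separate
    sustained and transient temporal channels. The sustained channel is a
    monophasic neural impulse response with exponential fMRI-adaptation (or a
    compressive power law); the transient channel is a biphasic impulse
    response whose on and off lobes are compressed by asymmetric cumulative
    Weibull sigmoids. Channel responses are convolved with a canonical
    hemodynamic response function, downsampled to the repetition time, and
    combined by ordinary least squares; timing and nonlinearity constants are
    estimated by bounded nonlinear optimization with split-half
    cross-validation. Includes the alternative single- and dual-channel model
    variants, derived metrics (onset/offset balance, channel contribution
    ratio, contrast effect size, peak amplitudes, noise ceiling), and a
    seeded synthetic-data generator emulating the block/event designs the
    model was developed for.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
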