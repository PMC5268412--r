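Package: flashlag
Title: Delay-Compensated Bayesian Motion Tracking and the Flash-Lag Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the flash-lag effect with a Bayesian state-space model of
    visual motion tracking under a known sensory delay. A particle filter
    estimates the joint posterior over position and velocity of a moving dot
    from noisy grayscale movies using a motion-energy (template matched-filter)
    likelihood, a motion-coherency transition prior with a slow-speed damping
    term, and a delay-compensating extrapolation step ("diagonal" prediction in
    push or pull mode). Includes a synthetic stimulus generator on a toroidal
    space-time domain (standard, flash-initiated, flash-terminated and
    motion-reversal conditions), a position-based-prediction ablation, fixed-lag
    backward smoothing, an exact grid-filter oracle, and read-outs (spatial
    histograms, maximum a posteriori positions, precision, flash-lag
    measurement, parameter sweeps) with tidy data frames and ggplot2 plots
    throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
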