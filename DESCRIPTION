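Package: calibudget
Title: Uncertainty Budgets for Emission-Tomography Calibration Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the decay-corrected calibration factor of a quantitative
    SPECT or PET system and propagates the uncertainties of its inputs (VOI
    counts, VOI volume, activity concentration, clock offset, half-life,
    acquisition duration) to a combined relative standard uncertainty using
    the GUM law of propagation of uncertainty. Provides exact, simplified and
    practical-formula budgets with per-component variance contributions,
    sub-models for voxelization volume uncertainty, clock-offset uncertainty,
    radionuclide half-life lookup and radionuclide-calibrator guidance, an
    independent Monte-Carlo propagation cross-check, half-life parameter
    sweeps, and plain-text configuration and report I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
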