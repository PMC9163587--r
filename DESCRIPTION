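Package: amsa
Title: Apparent Magnetic Susceptibility Anisotropy from Single-Orientation QSM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tract-level estimation of apparent magnetic susceptibility
    anisotropy (aMSA) and isotropic apparent susceptibility from
    single-orientation quantitative susceptibility mapping (QSM).
    Provides a synthetic cohort generator with tract-specific
    fibre-to-field angle distributions, metric binary morphology for
    white-matter and lesion mask construction, per-subject cos-squared
    regression of apparent susceptibility on the fibre-to-field angle,
    a Bayesian multilevel model comparing a patient and a control
    cohort with age-at-onset, disease-duration and lesion-load
    covariates (sampled by Gibbs MCMC via 'rjags'), and posterior
    summaries: maximum a posteriori estimates, highest density
    intervals, tail probabilities and standardized effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    rjags,
    coda,
    RNifti,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
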