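Package: ebdm
Title: Extended Bayesian Decision Models for Perceptual Decision Making
Version: 0.1.0
Authors@R:
    person("Analysis", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-free inference for sequential-sampling
    models of two-alternative perceptual decisions. Implements the pure and
    extended drift-diffusion models (pDDM, eDDM), their Bayesian reformulations
    (BM, eBM) in which evidence accumulation is recursive Bayesian inference
    over noisy stimulus features, and the exact-input variants (EXaM, eEXaM)
    that consume the trial-wise stimulus feature sequence. Provides the exact
    change-of-variables densities that translate inter-trial variability of
    drift and bias into variability of noise level and prior, their inverse
    Gaussian and uniform approximations, synthetic single-dot stimulus
    generation, parameter-sweep experiments (task difficulty, slow versus fast
    errors), ABC-based fitting with an expectation-propagation variant, and
    random-effects Bayesian model selection with protected exceedance
    probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
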