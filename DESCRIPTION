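Package: ldefit
Title: Latent Differential Equation Modeling of Multivariate Panel Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for fitting damped linear oscillator models to intensive
    longitudinal data via latent differential equations (LDE). Provides time
    delay embedding of multi-person, multivariate panels, second-order (SOLDE)
    and constrained fourth-order (FOLDE) structural models with person-specific
    equilibria, full-information maximum likelihood estimation under missing
    data, embedding-dimension selection by stabilization of the frequency
    parameter, wavelength computation, likelihood-ratio model comparison,
    regression and Bartlett factor scores, phase-plane vector fields, and a
    built-in damped-oscillator simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
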