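Package: apgsi
Title: Amyloid Progression and Gamma-Secretase Inhibitor PKPD Modelling in
    Tg2576 Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling age-dependent accumulation of soluble and
    insoluble amyloid-beta (Abeta40/42) in the Tg2576 transgenic mouse and the
    effect of the gamma-secretase inhibitor MRK-560 on that accumulation.
    Provides a two-compartment first-order-absorption pharmacokinetic model
    with dose-, route- and vehicle-dependent bioavailability and a
    plasma-to-brain exposure mapping; a logistic amyloid-progression model of
    age-dependent Abeta levels; an integrated turnover (indirect-response)
    model coupling soluble and insoluble Abeta40 with three candidate drug
    effect models (absolute, relative, and relative with Abeta-level-dependent
    IC50); naive-pooled maximum-likelihood estimation with observed-information
    standard errors and objective-function model comparison; a synthetic study
    generator emulating the in-house MRK-560 study designs; and diagnostics
    including visual predictive checks, treatment-effect summaries and the
    soluble-versus-insoluble reduction regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
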