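Package: eprqg
Title: Quantitative Genetics of Female Extra-Pair Reproduction in Wild
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pedigree-based Bayesian animal models for mixed Gaussian and
    threshold (logit-liability) traits, tailored to predicting evolutionary
    responses to selection on female extra-pair reproduction in wild
    passerine populations.  Provides pedigree validation, kinship and
    additive-relationship algebra with inbreeding, a Gibbs sampler for
    univariate and bivariate animal models with additive genetic, year,
    permanent-individual and residual (co)variance components, selection
    predictions via the secondary theorem of selection (additive genetic
    covariance with relative fitness) and the breeder's equation, and a
    synthetic island-population generator with overlapping generations,
    extra-pair paternity and inbreeding depression for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
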