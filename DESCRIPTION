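Package: sizestructLGCP
Title: Size-Structured Log-Gaussian Cox Process Models for Trawl Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Latent-Gaussian Poisson (log-Gaussian Cox process) models for
    haul-level trawl-survey catches structured by fish size, space, species
    and year. Space is modelled as a Gaussian Markov random field on a water
    lattice so that correlation travels through water rather than over land;
    size correlation follows an oscillating exponential on a transformed
    (natural, log or logistic) length scale or an unconstrained positive
    definite matrix; two species or two years are coupled through a
    positive-definite cross-block with fixed marginals or a separable
    species/year correlation, combined with space by a Kronecker product.
    Models are fitted by maximum likelihood with the latent field integrated
    out by the Laplace approximation (via 'TMB'), compared by hierarchical
    likelihood-ratio tests, and used for conditional prediction of relative
    abundance surfaces, including prediction of one species or year from
    data on the other.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    TMB,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
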