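Package: adatier
Title: Tiered Anti-Drug-Antibody Assay Statistics for ELISA Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical toolkit for validating tiered anti-drug-antibody
    (ADA) ELISA assays and estimating seroprevalence from plate-reader data.
    Implements standard-curve characterization with four-parameter logistic
    fits, minimum-required-dilution determination, balanced-design precision
    gating (fixed versus floating cut point), screening cut points by the
    parametric log-transform method and the immune-inhibition nonparametric
    method, confirmatory percent-inhibition cut points, two-tier donor
    classification with endpoint titration, and stratified prevalence
    reporting.  A synthetic 96-well OD450 plate generator with configurable
    prevalence, 4PL response, matrix attenuation, and nuisance factor
    effects supports end-to-end validation without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
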