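Package: ironear
Title: Iron Requirement Estimation and Dietary Inadequacy Risk for Women
    of Reproductive Age
Version: 0.1.0
Authors@R:
    person("Iron EAR", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives the Estimated Average Requirement (EAR) and Recommended
    Dietary Allowance (RDA) of iron for non-pregnant, non-lactating women of
    reproductive age by a factorial model: basal and menstrual iron losses
    are combined by Monte Carlo convolution and adjusted for dietary
    bioavailability.  Study-level menstrual-loss reports (ranges or moments,
    blood or iron) are converted to lognormal parameters by quantile
    matching and pooled by sample size; cereal-meal iron absorption studies
    are pooled by inverse-standard-error weighting within population strata.
    Population risks of inadequate intake (probability approach and EAR
    cut-point) and of exceeding the tolerable upper level are computed from
    parametric usual-intake distributions fitted by maximum likelihood, under
    baseline, fortification, and supplementation scenarios.  Includes seeded
    synthetic-data generators for intake surveys and menstrual-loss study
    summaries so the whole pipeline can be exercised without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
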