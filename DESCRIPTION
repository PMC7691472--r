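Package: findex
Title: Standardized Genetic Index of Fragmentation for River Barriers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the individual barrier effect of weirs, dams and other
    obstacles on riverine gene flow with a standardized genetic index of
    fragmentation expressed on a 0-100% scale. Observed genetic differentiation
    (Hedrick's G''st and Meirmans' phi'st) between the two populations flanking
    an obstacle is rescaled between a simulated no-barrier floor (GD_min) and a
    simulated total-barrier ceiling (GD_max) that accounts for barrier age and
    expected heterozygosity, a proxy for effective population size. Includes a
    forward-time two-deme Wright-Fisher simulator with bounded stepwise-mutation
    microsatellites, genepop input/output, random-forest calibration surfaces,
    and a validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    randomForest,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
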