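Package: plandscape
Title: Perceptual Landscapes and Stochastic Null Models for Site-Based
    Animal Movement Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds potential ("perceptual") landscapes from timestamped
    records of animals visiting discrete sites, such as RFID-logged stays
    in nest boxes. Transits between sites are modelled as advective
    Brownian bridges with finite endpoint variance, residence at sites as
    parabolic potential wells whose depth is set by inverting a Kramers
    mean first-passage time, and the two surfaces are added to form a
    single landscape raster. A parsimonious continuous-time multi-agent
    null model (Gillespie simulation over box and transit states) with an
    analytic Markov-chain companion and bootstrap comparison machinery
    lets observed social metrics be tested against the hypothesis of
    independent random movement. Includes a synthetic-colony generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    Matrix,
    pracma,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
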