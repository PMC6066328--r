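Package: dfspec
Title: Dynamic Force Spectroscopy and Binding-Probability Analysis for
    Single-Molecule AFM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule atomic force microscopy
    (AFM) experiments on receptor-ligand bonds. Implements Bell-Evans bond
    rupture kinetics and a two-state extended freely jointed chain model of
    poly(ethylene glycol) tethers; a physics-based simulator of tethered
    bond-rupture force curves and of Bernoulli contact-trial outcomes;
    rupture-event detection with total-least-squares tether fitting and
    Gaussian contour-length filtering; loading-rate clustering by k-means;
    robust (Tukey bisquare) Bell-Evans fits of clustered force spectra with
    bootstrap confidence intervals; and adhesion-frequency statistics with
    bootstrap standard errors, nonspecific baselines, and the Poisson
    single-bond fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
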