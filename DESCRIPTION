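Package: coaxtherm
Title: Electromagnetic and Thermal Modelling of a 434 MHz Coaxial TEM
    Hyperthermia Applicator
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: In-silico design and characterization of an open-ended coaxial
    TEM radiofrequency applicator for in vitro hyperthermia at 434 MHz.
    Provides an axisymmetric body-of-revolution finite-difference
    time-domain (FDTD) solver for the harmonic electromagnetic field with
    lumped resistive ports, SAR and power-loss dosimetry over a cubic
    volume of interest (exceedance-volume percentiles, heterogeneity
    coefficients and deposited-power fraction), an implicit finite-volume
    transient heat-conduction solver with power schedules and closed-loop
    temperature control, virtual counterparts of fiber-optic and infrared
    thermometry experiments, and a parametric design study over the
    applicator dimensions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
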