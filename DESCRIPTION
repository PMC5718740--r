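Package: mammobrachy
Title: Dose Perturbation and Tumor Control Modelling for Balloon HDR
    Breast Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models how iodinated contrast medium, source-position deviation
    and balloon deformation perturb the dose delivered by a balloon applicator
    for accelerated partial breast irradiation with a high-dose-rate Ir-192
    source. Provides a contrast/water mixture material model with per-channel
    photon mass attenuation coefficients, a voxel photon Monte Carlo (kerma
    approximation, exact ray-traced tracking, common-random-number pairing)
    for dose reduction factors, an analytic inverse-square point-source dose
    model for source-shift ratios and planning-target-volume dose-volume
    histograms, thermoluminescent-dosimeter calibration arithmetic, and a
    linear-quadratic radiobiology chain (dose-protraction factor, biologically
    effective dose, surviving fraction with repopulation, Poisson tumor
    control probability) that combines these uncertainties into tumor control
    probability tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
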