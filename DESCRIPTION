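Package: breastsim
Title: Virtual Breast Phantoms and Longitudinal Screening-Population Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for longitudinal virtual imaging trials of breast anatomy.
    Generates virtual screening populations with a Student-t copula fitted to
    tabular cohort data (breast volume, dense volume, age, and their annual
    changes), builds 3D voxel breast phantoms from thresholded fractal Perlin
    noise calibrated to a target volumetric breast density, synthesizes and
    inserts irregular soft-tissue lesions, and evolves density, volume and
    tumor diameter across screening ages with population-level or
    individual-level temporal models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
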