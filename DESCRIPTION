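Package: hdxdiff
Title: Differential Hydrogen-Deuterium Exchange Mass Spectrometry Analysis
    and Structure-Based Exchange Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for peptide-level differential hydrogen-deuterium
    exchange mass spectrometry (HDX-MS): reading DynamX-style state tables,
    back-exchange correction against a fully exchanged template peptide,
    single-exponential uptake fitting with uncertainty, spatial refinement by
    overlapping-peptide subtraction, and significance calling of
    free-versus-bound uptake differences. Also implements a structure- and
    molecular-dynamics-based exchange predictor: backbone-amide hydrogen-bond
    classification across trajectory frames, logistic conversion of
    hydrogen-bond occupancy to protection factors, intrinsic amide exchange
    rates from Bai-Englander reference chemistry, predicted deuteration, and
    correlation of uptake with backbone solvent-accessible surface area
    (Shrake-Rupley). A synthetic-data generator provides ground-truth exchange
    landscapes, peptide maps, uptake kinetics, and Bernoulli hydrogen-bond
    series so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
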