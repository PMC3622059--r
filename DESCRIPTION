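Package: clsensr
Title: Simulation and Analysis of Ratiometric Cl-Sensor Chloride Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and analysis of two-wavelength ratiometric
    imaging with the genetically encoded chloride indicator Cl-Sensor
    (CFP fused to a chloride-quenched YFP). Models the chloride-dependent
    quenching of the YFP component, its use-dependent photoinactivation by
    430 nm excitation, compartmental intracellular chloride dynamics driven
    by glycine/GABA-A receptor channels and the K-Cl cotransporter KCC2,
    and a synthetic two-channel camera. Provides the matching analysis
    chain: ROI trace extraction with background subtraction, mixed-binning
    alignment, ratio pairing and normalization, inhibition and half-time
    estimators, Nernst calibration, dose-response fitting and inversion,
    and KCC2 transport assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
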