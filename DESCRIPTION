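Package: neuroquant
Title: Quantitative Characterization of 3D Neural Tissue Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the quantitative characterization
    of soft 3D neural tissue constructs. Calibrates an incompressible one-term
    modified Ogden hyperelastic model to cyclic unconfined-compression
    recordings and reports the apparent Young's modulus; quantifies synapse
    density from traced neuron filaments and 3D puncta coordinates as well as
    neurite lengths and live/dead viability; scores calcium-imaging
    fluorescence traces (delta-F/F0, event detection, AUC, amplitude,
    frequency); and provides a normality-routed group-comparison layer
    (Shapiro-Wilk gated ANOVA/Kruskal-Wallis with matched post hoc
    procedures). A seeded synthetic-data module generates inputs with known
    ground truth for every stage so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
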