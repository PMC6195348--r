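Package: cbpheno
Title: Behavioral Phenotyping and Expression-Dosage Analysis for
    Cerebellar Chemogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for mouse behavioral phenotyping in
    cerebellar chemogenetic experiments. Provides a background-subtraction
    video tracker with zone occupancy and entrance analysis for three-chamber
    social preference, Y-maze and elevated plus-maze arenas; conditioned-
    response detection for eyeblink conditioning from eyelid-position traces;
    grooming-bout filtering; stride and stance measures from paw placements;
    spike-train firing-frequency and CV2 summaries; the full panel of
    behavioral metric formulas; control-space principal component analysis
    ("eigenbehaviors") with high-contribution component selection,
    variance-ratio tests, Cohen's d effect sizes, Kolmogorov-Smirnov
    comparisons and permutation-based Spearman correlation networks; and
    linear dosage models relating per-lobule reporter expression fractions
    to behavioral metrics. A synthetic-data module generates every input
    with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    MASS,
    mgcv,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
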