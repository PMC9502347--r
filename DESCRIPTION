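Package: dermaquant
Title: Quantification of Dermal Penetration Efficacy from Skin-Section
    Fluorescence Micrographs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Measures dermal penetration of fluorescent active-ingredient
    surrogates from vertical skin-cryosection fluorescence micrographs.
    Provides per-image estimates of stratum corneum thickness (SCT), stratum
    corneum autofluorescence (AF-SC), the suprathreshold signal remaining
    after automated removal of skin autofluorescence (AROSA, mean grey
    value per pixel) and the mean penetration depth (MPD), together with
    study-level aggregation, control normalization, penetration-compartment
    classification and an assumption-driven statistical comparison workflow
    (Shapiro-Wilk, Levene, ANOVA/Welch/Kruskal-Wallis with Tukey,
    Games-Howell or Dunn post hoc tests). A synthetic-image generator with
    full ground truth emulates an ex vivo porcine-ear study design so the
    whole pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
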