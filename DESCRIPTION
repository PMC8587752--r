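Package: ftirage
Title: ATR-FTIR Aging Fingerprints of Striated Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Chemometric pipeline for age discrimination in mouse cardiac and
    skeletal muscle from mid-infrared ATR-FTIR spectra: spectral I/O on a
    common wavenumber grid, region cutting, rubberband baseline correction,
    area normalization, Savitzky-Golay second-derivative spectroscopy, PCA
    with Q-residual outlier screening, kernel PLS1 regression against age
    with seeded random cross-validation and score-plot discrimination
    statistics, nine band-intensity biomarker indices (acyl chain length,
    lipid unsaturation, triglycerides, total protein, beta-sheet fractions,
    fibril formation, cholesterol esters, glucose), and two-way ANOVA with
    Sidak-adjusted tissue contrasts. Includes a seeded synthetic cohort
    generator with known age and tissue effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    pracma,
    car,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
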