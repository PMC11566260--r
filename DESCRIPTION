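Package: fgscontrast
Title: Contrast Metrics and Co-Registration for Paired-Modality
    Fluorescence-Guided Surgery Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative comparison of paired fluorescence images of the
    same tissue slice acquired with two imaging systems (e.g. a near-infrared
    and a shortwave-infrared camera). Provides control-point similarity
    registration, region-of-interest contrast metrics (tumor-to-background
    ratio, adapted contrast-to-noise ratio, signal-to-noise ratio in dB with
    the 3-sigma detectability rule), line-profile analysis across the tumor
    border including aCNR = 1 boundary localization, pixel-level agreement
    statistics (R-squared, Bland-Altman, tumor/background intensity overlap),
    instrument characterization tools (tube-profile FWHM, liquid-phantom
    sensitivity series, black-body spectral-response correction), a
    synthetic paired-image generator with known ground truth, and a study
    driver producing median/IQR comparison tables with paired Wilcoxon tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
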