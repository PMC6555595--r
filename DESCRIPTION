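Package: parcortex
Title: Quantification of Reconstructed Cortical Par-Complex Polarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-derived quantification of cortical Par-complex polarity in
    cultured cells: the asymmetric index (ASI) of equatorial fluorescence
    profiles with a polarized/non-polarized classification, membrane-curvature
    radii from three-point circumscribed circles with region classification
    relative to Par-islands, super-resolution meshwork periodicity analysis
    (kernel length densities, multi-Gaussian comb fitting, power spectral
    density of the density's second derivative), segment length and
    full-width-at-half-maximum statistics, aggregate-size morphometrics,
    centrosome-crescent fan geometry, and the associated cohort statistics
    (Kolmogorov-Smirnov, Fisher's exact with Bonferroni correction). A
    seeded synthetic-data generator produces every input with known ground
    truth so the full pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    minpack.lm,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
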