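Package: photodose
Title: Spectral UV Doses and Seasonal Leaf Flavonol Trends in Forest
    Understoreys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating understorey spectral irradiance to leaf
    epidermal UV-A absorbance (the flavonol index) in forest stands.
    Provides spectral irradiance objects with waveband photon integration,
    biological spectral weighting functions (plant growth, generalised
    plant, flavonoid accumulation) and effective UV doses, the red:far-red
    photon ratio, community-weighted trait means, thermal-season
    segmentation with growing-season weather covariates, local-regression
    trend curves with pointwise confidence intervals and overlap
    comparison, Pearson correlation tables with significance brackets, and
    feasible generalised least squares with compound-symmetry correlation
    and heteroscedastic variance structures. A synthetic-data generator
    emulates the full measurement design (canopy-filtered solar spectra,
    weather years, community surveys) so the whole chain is testable
    without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
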