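Package: hempkite
Title: Canopy Kite Morphometrics, Allometry, and Yield Analysis for Hemp Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the morphometric analysis of field trials of cannabinoid
    hemp (Cannabis sativa). Builds a two-dimensional "kite" model of canopy
    architecture from four field measurements and derives its scalar traits
    (area, perimeter, circularity, hypotenuse ratio, branch angle, volume);
    fits model-II (OLS, major axis, standardized and ranged major axis)
    log-log allometric regressions; smooths weekly height series to extract
    growth rates; summarises powdery mildew progress (AUDPC); estimates
    half-sib heritability from one-way variance components; calibrates and
    applies wet-to-dry biomass prediction and cannabinoid yield arithmetic;
    classifies canopy form by archetypal analysis of shape ratios; decomposes
    regression R-squared by LMG relative importance; and extracts per-plant
    traits (geo-location, canopy height/area/volume, vegetation indices) from
    synthetic aerial RGB/multispectral rasters and point clouds. A synthetic
    trial generator emulates the family structure, allometric cascades,
    heritabilities, phenology, disease and chemotype profiles of a hemp
    hybrid trial so every stage is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
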