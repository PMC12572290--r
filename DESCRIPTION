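Package: ldiscore
Title: Location Data Integrity Scoring and Impact Analysis for Reforestation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the spatial integrity of reported reforestation planting
    sites and quantifies planting effects from satellite-derived vegetation
    indices. Harmonizes site tables (points, polygons, multipolygons),
    computes geometric diagnostics (validity, Polsby-Popper circularity,
    administrative-boundary resemblance, nesting/duplicate/intersection
    relations), overlays sites on built-up, land-cover, loss-year and
    elevation rasters and road vectors, binarizes ten integrity indicators
    into the 0-10 Location Data Integrity Score (LDIS), derives NDVI, NDRE
    and SAVI panels for sites and their 500 m buffer annuli, and estimates
    planting impacts via two-period difference-in-differences regression,
    bootstrap confidence intervals, and a bucket-weighted synthetic control.
    A seeded synthetic-data generator emulates every input layer so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
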