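Package: chemrisk
Title: Endpoint-Based Chronic Health Risk Assessment for Chemical Accidents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the multimedia (air and surface-soil) fate of a chemical
    released in an industrial accident on a regular grid, using a vertically
    well-mixed Gaussian-puff dispersion scheme driven by hourly meteorology
    (read from CSV or generated synthetically). Determines the exposure
    endpoint as the last day on which any grid cell's daily-average air
    concentration exceeds the atmospheric background, accumulates
    soil-ingestion dose to that endpoint per age group as a lifetime average
    daily dose (LADD), converts dose to excess cancer risk (ECR) with an oral
    cancer slope factor, classifies red/orange/green risk zones, and exports
    mappable ESRI ASCII rasters together with tabular summaries. Ships a
    worked benzyl chloride release scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
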