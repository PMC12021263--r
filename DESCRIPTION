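Package: traitscape
Title: Trait-Based Analysis of Phytoplankton Salinity Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives physiological trait matrices from batch-culture
    measurements of phytoplankton grown along a salinity gradient (specific
    growth rate from chlorophyll-a fluorescence, per-cell quotas, C:N:P
    stoichiometry, net nutrient uptake rates, and resource use efficiency),
    builds standardized-PCA "trait-scapes", performs hierarchical clustering
    on principal components with Ward's minimum-variance criterion, and
    computes centroid-distance metrics of species trait plasticity and
    interspecific variability. Includes a synthetic culture-experiment
    generator with species-specific Gaussian salinity reaction norms,
    allometric trait scaling, and batch nutrient mass balance, so the whole
    pipeline can be exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
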