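Package: ringflux
Title: Growth and Water-Use Efficiency Analysis for Tree-Ring Chronologies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dendroecological analysis of radial growth and
    intrinsic water-use efficiency (iWUE) across groups of trees: reading
    and writing Tucson/RWL ring-width files, basal area increment (BAI)
    conversion, chronology building with quality statistics (mean
    interseries correlation, expressed population signal), carbon isotope
    discrimination and iWUE from tree-ring d13C with atmospheric (Suess)
    correction, homogenisation of monthly climate records, lagged seasonal
    climate-growth correlation screens, nonparametric group comparisons
    (Kruskal-Wallis with Nemenyi post hoc), and gamma generalized linear
    mixed models of growth with collinearity screening, AICc-based model
    selection, boundary-corrected likelihood ratio tests for random effects
    and predictive-skill diagnostics. Ships a synthetic-forest generator
    with known ground truth for end-to-end validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmmTMB,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
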