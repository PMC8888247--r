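Package: presspulse
Title: Press-Pulse Perturbation Analysis for Mesocosm Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing phytoplankton responses to combined press
    (stepwise nutrient enrichment) and pulse (transient mortality)
    perturbations in mesocosm experiments. Provides a synthetic-data
    generator for chlorophyll-a/nutrient/biovolume timeseries with known
    ground-truth effect sizes, dilution mass-balance dosing calculations and
    N:P limitation classification, automated segmentation of perturbation
    cycles into pre-response, peak and post-event states via least-variance
    moving windows, displacement/resistance/recovery indices (original and
    0-10 rescaled), and mixed-effects estimation of eutrophication and
    sequential-perturbation effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
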