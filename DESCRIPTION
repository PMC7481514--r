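Package: ryeNUE
Title: Image-Based Screening of Nitrogen Use Efficiency in Perennial Ryegrass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for automated image-based screening of
    nitrogen use efficiency (NUE) in perennial ryegrass. Generates fully
    ground-truthed synthetic trials (randomized complete block designs,
    logistic regrowth trajectories, procedural multi-view plant silhouettes,
    harvest records), segments plants from RGB imagery with an excess-green
    recipe, extracts seven silhouette shape features under an exact
    pixel-corner convex-hull convention, derives digital-biomass traits
    (mean projected plant area, digital volumes), growth rates (AGR, RGR),
    supplied-nitrogen mass and NUE, and performs trial-level statistics:
    per-group summaries, Pearson feature-biomass correlations, and
    REML mixed-model BLUEs for genotype and genotype-by-treatment effects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    EBImage,
    lme4,
    car,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
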