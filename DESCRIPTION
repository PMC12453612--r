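Package: volescape
Title: Drone-Based Analysis of Water-Vole Habitat Selection on Dandelion Density
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to measure habitat selection of the fossorial water vole
    (Arvicola amphibius) on dandelion (Taraxacum officinale) density from
    drone orthomosaics of mountain meadows. Provides RGB threshold
    classification of dandelion flowers and vole earth mounds, aggregation
    into 2 m tile tables with a fourth-root dandelion anomaly index,
    logistic colonization and burrow-reuse models with forward-stepwise AIC
    selection, a dandelion population growth-rate regression, and a
    fine-scale depletion profile over logarithmic distance buffers fitted
    with a penalized-spline GAM. A synthetic-scene generator with known
    ground truth (clustered flower patterns, mound colonies, distance-based
    flower thinning) makes every stage testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
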