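Package: psmtools
Title: Untargeted Metabolomics Analysis of Plant Secondary Metabolite Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing untargeted LC-MS feature tables
    of plant secondary metabolites under combinations of abiotic factors.
    Provides dual-polarity feature fusion (cross-polarity mass/retention-time
    matching), phytochemical richness and turnover metrics (Canberra and
    Jaccard dissimilarities), permutational MANOVA with strata-restricted
    permutations, multivariate dispersion tests, mean-dissimilarity
    decomposition, non-metric multidimensional scaling with standard-error
    confidence ellipses, reference-condition abundance-shift classification
    with Venn-set intersections and bootstrap confidence intervals, and
    random-intercept linear mixed models for richness and compound abundance.
    Includes a synthetic-data generator with known ground truth emulating
    blocked factorial and observational sampling designs, so every stage of
    the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
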