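Package: lingscape
Title: Phylogenetic and Spatial Generalized Least Squares for Language
    Diversity Macroecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing ecological correlates of language diversity on
    equal-area grids while correcting for spatial autocorrelation and
    phylogenetic non-independence among grid cells.  The residual correlation
    between cells is modelled as (1 - alpha) I + alpha [beta P + (1 - beta) D],
    where P is PhyloSor phylogenetic similarity computed on a taxonomy-derived
    language tree and D is a Gaussian decay kernel of great-circle distance.
    Includes maximum-likelihood fitting of the generalized least squares model,
    likelihood-ratio drop-one tests, leave-one-out predicted R-squared,
    residual hotspot mapping, grid construction and polygon-overlay diversity
    counts, subsampling regimes, and a synthetic-data generator with clustered
    language families, Gaussian-random-field covariates and known model
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
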