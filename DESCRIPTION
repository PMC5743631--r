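Package: integmod
Title: Morphological Integration and Modularity of Skull Linear Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying morphological integration and modularity
    from specimen-level linear-distance data across species. Estimates pooled
    within-species phenotypic (co)variance matrices (P-matrices) from
    multivariate linear-model residuals with Monte-Carlo repeatability,
    separates isometric (Somers double-centering) and allometric (PC1
    deflation) size variation, tests a priori modularity hypotheses with the
    AVG+/AVG- statistic and parametric-bootstrap confidence intervals,
    compares modularity models by maximum likelihood of Fisher-z transformed
    correlations with AICc weights, compares covariance matrices across
    species by Random Skewers and relative eigenanalysis, and partitions
    P-matrix divergence into phylogenetic, climatic and phylogenetically
    structured climatic fractions via principal coordinates, multivariate
    phylogenetic signal (K_mult) and redundancy analysis. Includes a
    synthetic-clade generator with known ground truth for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phytools
Config/testthat/edition: 3
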