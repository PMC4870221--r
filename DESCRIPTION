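Package: paleofd
Title: Paleoclimatic Legacies in Plant Functional Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the imprint of late-Quaternary climate change on
    continental-scale plant functional diversity. The package links per-cell
    functional diversity (convex-hull functional richness, functional
    dispersion, and richness-preserving null-model standardized effect sizes)
    to historical predictors (climate-change velocity since the Last Glacial
    Maximum, inverse-distance accessibility to glacial refugia) and
    contemporary environmental predictors, using maximum-likelihood spatial
    autoregressive error models, exhaustive AIC multimodel inference with
    Akaike-weight variable importance and model-averaged standardized
    coefficients, and Dutilleul-corrected correlations. Trait gaps are filled
    by a genus- and growth-form-constrained chained-equations imputation with
    predictive mean matching. A synthetic-data generator reproduces the
    statistical structure of atlas-style occurrence data and paired
    present/glacial climate surfaces so the whole pipeline can be exercised
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    optparse
Config/testthat/edition: 3
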