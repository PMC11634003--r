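Package: coraltex
Title: Texture-Based Species Discrimination for Scleractinian Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating coral species from skeletal texture and
    traditional morphometrics. Implements Completed Local Binary Pattern (CLBP)
    texture descriptors with rotation-invariant uniform mapping, a fuzzy
    associative memory classifier with a competitive hidden layer returning
    per-species pertinence scores, discriminant analysis of principal
    components (DAPC) and chi-square-distance nearest-neighbour baselines,
    replicated stratified cross-validation with one-vs-rest True Skill
    Statistic threshold sweeps, class-balanced subsampling, max-TSS
    binarization, and a meta-learning assessment based on logistic regression
    and precision-recall curves. A synthetic generator produces
    pseudo-corallite Voronoi-ridge textures and morphometric tables with
    colony-level random effects and label noise, so the whole pipeline is
    testable without scanning electron micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    graphics,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
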