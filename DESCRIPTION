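Package: soilwebs
Title: Soil Microbial Co-Occurrence Networks, Community Assembly and Soil
    Quality for Factorial Microcosm Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for factorial soil-microcosm amplicon studies
    (residue retention crossed with freeze-thaw intensity and cycle number).
    Provides ASV-table input/output and preprocessing (rarefaction, prevalence
    filtering), alpha diversity, Bray-Curtis ordination with PERMANOVA and
    Mantel permutation tests, normalized stochasticity ratio (NST) community
    assembly analysis with a richness- and frequency-constrained null model,
    Spearman co-occurrence network construction with FDR-controlled edge
    selection, module detection, Zi-Pi node roles and keystone calling,
    network robustness, connectedness and positive/negative edge ratios,
    per-treatment subnetworks, a composite z-score soil quality index, and
    random-forest feature importance linking microbial metrics to soil
    quality.  A synthetic microcosm generator with known ground truth
    (planted correlation modules, treatment responders, soil effect sizes)
    supports desk-scale validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
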