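Package: abselect
Title: NGS-Guided Antibody Lead Selection from Display Campaigns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for selecting antibody lead candidates from
    next-generation sequencing of in vitro display selection outputs
    (phage and yeast display of scFv libraries). Covers inline-barcode
    demultiplexing and Phred quality filtering of long amplicon reads,
    scaffold-anchored CDR/framework annotation, density-based clustering
    of CDR regions over reduced-alphabet Levenshtein distances (OPTICS
    with abundance-seeded iterations and noise rescue), round-to-round
    enrichment statistics with pseudo-count corrections, diversity
    accumulation curves with power-law read-depth modeling, sequence
    liability screening, and gradient-boosted binder classification and
    affinity regression. A campaign simulator with known ground truth
    makes every pipeline stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    mclust,
    minpack.lm,
    pROC,
    S4Vectors,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
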