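Package: gfblupkit
Title: Genomic and Genomic-Feature BLUP for Multi-Population Prediction
Version: 0.1.0
Authors@R: person("gfblupkit", "maintainers", email = "gfblupkit@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction of dairy-cattle traits with traditional GBLUP
    and genomic-feature BLUP (GFBLUP) mixed models. Builds VanRaden (method 1)
    genomic relationship matrices, whole-genome or partitioned across feature
    chromosomes, estimates variance components by average-information REML,
    predicts genomic breeding values for masked validation animals, and
    evaluates predictions with relationship-aware cross-validation and
    heritability-scaled reliabilities. Includes per-population SNP quality
    control, binwise linkage-disequilibrium summaries, and a multi-population
    half-sib simulator so the full pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
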