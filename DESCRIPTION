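Package: fusionprio
Title: Screening, Consensus Validation and Oncogenicity Classification of
    Gene Fusions in Tumour RNA-Seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritises candidate gene fusions called from bulk tumour
    RNA-seq. Implements a filter cascade (reading-frame compatibility,
    absence from matched normal tissue, junction-spanning read support,
    intrachromosomal breakpoint distance), breakpoint-tolerant grouping of
    calls across detection algorithms with a 2-of-3 cross-validation rule,
    reconstruction of the fusion coding sequence from transcript models
    with junction-phase and protein-domain retention analysis,
    expression-outlier detection in fusion carriers, a rule-based oncogenic
    classification, hard-filtering of somatic variants with a permutation
    test of fusion/oncogene mutual exclusivity, clinicopathological
    association and survival analyses, and a synthetic cohort generator
    that emulates the statistical structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    rtracklayer,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
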