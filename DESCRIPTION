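Package: pathprs
Title: Pathway-Partitioned Polygenic Risk Scores with Circular Genomic Permutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene-set polygenic risk scores (PRSs) and their
    whole-genome complements from GWAS summary statistics by clumping and
    p-value thresholding, derives composite neuroimaging and rare binary
    psychotic-like-experience phenotypes, fits joint set-plus-complement
    association models (linear, bilateral mixed, logistic) with
    Benjamini-Hochberg false-discovery-rate control per phenotype, and
    assesses significant gene-set associations with circular genomic
    permutation. Ships a synthetic-data generator producing LD-blocked
    genotypes, spike-and-slab summary statistics, bilateral imaging-like
    phenotypes and rare binary items with known ground truth, so the whole
    pipeline is exercisable and calibratable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
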