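Package: lncrecur
Title: Recurrence-Based Discovery of Tumor-Specific lncRNAs from Matched
    Tumor-Normal RNA-Seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering tumor-specific long
    non-coding RNAs (lncRNAs) from cohorts of matched tumor-normal RNA-seq
    pairs. Classifies transcripts into known and novel candidate lncRNAs
    by length and a coding-potential consensus, tests each transcript for
    differential expression within every matched pair using a local
    pooled error (LPE) test that needs no replicates, aggregates per-pair
    calls into occurrence counts and direction-consistency classes, ranks
    candidates by fold change and occurrence, predicts cis targets by a
    genomic-window rule and trans targets by co-expression, and runs
    hypergeometric over-representation of predicted targets. Includes a
    negative-binomial cohort simulator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
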