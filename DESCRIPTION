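Package: sumtwas
Title: Summary-Based TWAS with Permutation Filtering, Expression-Profiling
    Integration and Gene-Set Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a summary-statistics transcriptome-wide association
    study (TWAS) pipeline: the LD-adjusted weighted z-score statistic
    w'Z / sqrt(w'Dw) computed from GWAS summary statistics, cis expression
    weights and a SNP-correlation matrix; a permutation filter that shuffles
    expression weights conditional on the observed GWAS signal; allele
    harmonization of summary statistics against an LD reference; the genomic
    inflation factor; intersection of transcriptome-wide significant features
    with a microarray-style differential-expression gene list; and
    hypergeometric / EASE over-representation analysis against GMT gene-set
    annotations. A seeded synthetic-data generator produces LD-structured
    GWAS z-scores, sparse multi-panel expression weights, a case-control
    differential-expression table and gene-set annotations with planted
    ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
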