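Package: homeoexpr
Title: Homoeolog Expression Silencing and Bias in Allodiploid Hybrids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of subgenome expression dominance in allodiploid
    hybrid transcriptomes. Assigns hybrid RNA-seq reads to parental
    subgenomes using species-specific diagnostic SNPs, tallies
    per-homoeolog read counts, and classifies homoeolog pairs into
    silenced (HES), biased (HEB), specifically expressed and normal
    categories with dominance summaries. Includes reciprocal-best-hit
    ortholog pairing, FPKM quantification, a replicate outlier screen,
    differential homoeolog-expression bookkeeping, a 2^-ddCt qPCR
    utility, and a fully seeded synthetic-data generator (parental
    transcriptomes, SNP catalogs, hybrid reads with truth alignments)
    so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    Rsamtools,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, RNASeq, GeneExpression, Sequencing
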