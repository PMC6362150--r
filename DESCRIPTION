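Package: imprintkit
Title: Detection of Genomic Imprinting from Allele-Specific RNA-Seq of
    Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls imprinted genes (maternally and paternally expressed
    genes, MEGs and PEGs) from allele-specific RNA-seq read counts of
    reciprocal F1 crosses. Implements allelic read counting at parental
    SNPs from alignments, TMM normalization, and a paired negative
    binomial generalized linear model with empirical-Bayes moderated
    (tagwise) dispersions that tests each gene for deviation from the
    tissue-specific expected allelic ratio (2:1 in triploid endosperm,
    1:1 in diploid tissues). Includes two count-test baselines (Fisher's
    exact test on summed crosses, and per-cross Fisher tests combined by
    Stouffer's method), a spike-in simulation generator of allelic count
    tables, and benchmarking utilities (ROC, count-quartile true
    positive rates, concordance and saturation analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    DESeq2,
    pROC
Config/testthat/edition: 3
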