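Package: MethylQV
Title: Quantitative CpG Methylation from Nanopore Basecall Quality Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates per-CpG 5mC methylation levels from basecalled,
    aligned nanopore reads without raw electrical signals. Features are
    high-order moments (mean, covariance, coskewness, cokurtosis) of base
    quality values and pairwise joint sequencing-error rates computed over
    a 21-position window centred on each candidate cytosine, together with
    a binary encoding of the reference sequence context. A gradient-boosted
    tree ensemble regresses logit-transformed methylation levels on these
    features. Includes bedMethyl-dialect parsing, strand averaging of CpG
    records, trimmed-mean aggregation over genomic regions (CpG islands,
    imprinting control regions, histone-mark intervals), and a synthetic
    aligned-read simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Sequencing, MethylSeq
RoxygenNote: 7.3.3
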