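## Programmatic fixtures: tiny FASTA / SAM->BAM files built at test time.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Rsamtools)
})

writeTestFasta <- function(seqstring, chrom = "chrT",
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
    path <- file.path(dir, "ref.fa")
    writeLines(c(paste0(">", chrom), seqstring), path)
    Rsamtools::indexFa(path)
    path
}

## reads: list of lists with pos (1-based), cigar, seq, qual (string),
## flag (default 0). Returns the BAM path.
writeTestBam <- function(reads, chrom = "chrT", reflen = 200L,
                         dir = withr::local_tempdir(.local_envir = parent.frame())) {
    recs <- vapply(seq_along(reads), function(i) {
        r <- reads[[i]]
        flag <- if (is.null(r$flag)) 0L else r$flag
        paste(sprintf("r%03d", i), flag, chrom, r$pos, 60L, r$cigar,
              "*", 0L, 0L, r$seq, r$qual, sep = "\t")
    }, character(1))
    ord <- order(vapply(reads, function(r) r$pos, numeric(1)))
    sam <- file.path(dir, "t.sam")
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", chrom, reflen),
                 recs[ord]), sam)
    suppressMessages(Rsamtools::asBam(sam, file.path(dir, "t"),
                                      overwrite = TRUE,
                                      indexDestination = TRUE))
}

qualString <- function(qvs) intToUtf8(qvs + 33L)

writeLociFile <- function(rows, dir = withr::local_tempdir(.local_envir = parent.frame())) {
    ## rows: data.frame chrom, start, strand, score, coverage, percent
    path <- file.path(dir, "loci.tsv")
    writeLines(sprintf("%s\t%d\t%d\t5mC\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%s",
                       rows$chrom, rows$start, rows$start + 1L, rows$score,
                       rows$strand, rows$start, rows$start + 1L,
                       rows$coverage, format(rows$percent)), path)
    path
}

kernelAt_test <- function(flank, offsets, value) {
    k <- numeric(2L * flank + 1L)
    k[flank + 1L + offsets] <- value
    k
}
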