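#' @importFrom stats rbeta rbinom rnorm runif
NULL

## Run code under a fixed seed without clobbering the caller's RNG state.
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

kernelAt <- function(flank, offsets, value) {
    k <- numeric(2L * flank + 1L)
    k[flank + 1L + offsets] <- value
    k
}

#' Configuration of the synthetic nanopore dataset
#'
#' Describes a small reference genome with planted CpG sites and
#' single-end aligned reads whose QV distribution and error rates shift
#' with the per-read methylation state inside the feature window. The
#' defaults encode the simulation study this package validates itself on:
#' 400 CpG sites at 30x coverage, bimodal Beta(0.3, 0.3) true levels, a
#' QV depression of 6 Phred units at offsets -2..+2 for methylated reads,
#' and an extra 5% substitution / 3% deletion probability at the site
#' itself. Baseline QVs are drawn from a discretized normal (mean 20,
#' sd 6, truncated to \[1, 50\]) over baseline substitution/deletion
#' rates of 5% / 2%, typical of basecalled nanopore data.
#'
#' @param nCpG number of CpG sites (default 400).
#' @param coverage reads per site (default 30).
#' @param genomeLength reference length; the default leaves at least
#'   25 bases between sites and from the contig ends.
#' @param methylationPrior Beta shape parameters of the true levels
#'   (default `c(0.3, 0.3)`).
#' @param qvBaseline named vector `c(mean=, sd=)` of the unmethylated QV
#'   distribution (default mean 20, sd 6).
#' @param qvShiftKernel length-21 additive QV shift for methylated reads,
#'   by window offset (default -6 at offsets -2..+2).
#' @param errorBaseline named vector `c(substitution=, deletion=)` of
#'   per-base baseline error probabilities (default 0.05 / 0.02).
#' @param substitutionShiftKernel length-21 additive substitution
#'   probability for methylated reads (default +0.05 at offset 0).
#' @param deletionShiftKernel length-21 additive deletion probability for
#'   methylated reads (default +0.03 at offset 0).
#' @param flank window half-width (default 10).
#' @param readPad extra aligned bases beyond the window on each side
#'   (default 5).
#' @param reverseRecords also emit the reverse-strand CpG record at
#'   position + 1 in the loci table (for strand-averaging tests).
#' @param chrom contig name (default `"simchr"`).
#' @param seed RNG seed (default 0).
#' @return a validated `list` of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nCpG = 400L, coverage = 30L,
                             genomeLength = 25L * nCpG + 2000L,
                             methylationPrior = c(0.3, 0.3),
                             qvBaseline = c(mean = 20, sd = 6),
                             qvShiftKernel = kernelAt(flank, -2:2, -6),
                             errorBaseline = c(substitution = 0.05,
                                               deletion = 0.02),
                             substitutionShiftKernel = kernelAt(flank, 0, 0.05),
                             deletionShiftKernel = kernelAt(flank, 0, 0.03),
                             flank = 10L, readPad = 5L,
                             reverseRecords = FALSE,
                             chrom = "simchr", seed = 0L) {
    cfg <- list(nCpG = as.integer(nCpG), coverage = as.integer(coverage),
                genomeLength = as.integer(genomeLength),
                methylationPrior = methylationPrior,
                qvBaseline = qvBaseline, qvShiftKernel = qvShiftKernel,
                errorBaseline = errorBaseline,
                substitutionShiftKernel = substitutionShiftKernel,
                deletionShiftKernel = deletionShiftKernel,
                flank = as.integer(flank), readPad = as.integer(readPad),
                reverseRecords = isTRUE(reverseRecords),
                chrom = chrom, seed = as.integer(seed))
    w <- 2L * cfg$flank + 1L
    if (length(cfg$qvShiftKernel) != w ||
        length(cfg$substitutionShiftKernel) != w ||
        length(cfg$deletionShiftKernel) != w)
        mqvStop("shift kernels must have length 2*flank + 1", "configError")
    psMax <- cfg$errorBaseline[["substitution"]] +
        max(c(0, cfg$substitutionShiftKernel))
    pdMax <- cfg$errorBaseline[["deletion"]] +
        max(c(0, cfg$deletionShiftKernel))
    if (any(cfg$errorBaseline < 0) || psMax > 1 || pdMax > 1 ||
        psMax + pdMax > 1)
        mqvStop("substitution + deletion probabilities must stay within [0, 1]",
                "configError")
    if (cfg$coverage < 1L)
        mqvStop("coverage must be at least 1", "configError")
    class(cfg) <- "SimulationConfig"
    cfg
}

## Place nCpG site positions (0-based C coordinates) with pairwise spacing
## >= 25 and margin >= 30 from both contig ends.
placeSites <- function(nCpG, genomeLength) {
    spacing <- 25L
    margin <- 30L
    slack <- genomeLength - 2L * margin - spacing * nCpG
    if (slack < 0L)
        mqvStop(sprintf("cannot place %d sites >= %d bases apart in a %d-base contig",
                        nCpG, spacing, genomeLength), "configError")
    jitter <- sort(sample.int(slack + 1L, nCpG, replace = TRUE)) - 1L
    margin + spacing * (seq_len(nCpG) - 1L) + jitter
}

simulateRead <- function(refBases, rs, c0, methylated, cfg) {
    ## rs: 0-based leftmost aligned reference position.
    span <- length(refBases)
    offs <- (rs + seq_len(span) - 1L) - c0         # window offsets
    inWin <- abs(offs) <= cfg$flank
    kidx <- offs[inWin] + cfg$flank + 1L
    ps <- rep(cfg$errorBaseline[["substitution"]], span)
    pd <- rep(cfg$errorBaseline[["deletion"]], span)
    qshift <- numeric(span)
    if (methylated) {
        ps[inWin] <- ps[inWin] + cfg$substitutionShiftKernel[kidx]
        pd[inWin] <- pd[inWin] + cfg$deletionShiftKernel[kidx]
        qshift[inWin] <- cfg$qvShiftKernel[kidx]
    }
    u <- runif(span)
    isDel <- u < pd
    isSub <- !isDel & u < pd + ps
    bases <- refBases
    if (any(isSub)) {
        ## substitute with a uniformly chosen different base
        alt <- vapply(refBases[isSub], function(b)
            sample(setdiff(BASE_ALPHABET, b), 1L), character(1))
        bases[isSub] <- alt
    }
    qv <- pmin(pmax(round(rnorm(span, cfg$qvBaseline[["mean"]] + qshift,
                                cfg$qvBaseline[["sd"]])), 1), 50)
    keep <- !isDel
    ## CIGAR from the deletion mask (M/D runs)
    r <- rle(isDel)
    cigar <- paste0(r$lengths, ifelse(r$values, "D", "M"), collapse = "")
    list(pos = rs + 1L,                            # SAM is 1-based
         cigar = cigar,
         seq = paste(bases[keep], collapse = ""),
         qual = intToUtf8(qv[keep] + 33L))
}

#' Simulate a reference, aligned reads and a loci table
#'
#' Generates the full synthetic dataset: a FASTA reference with CpG
#' dinucleotides planted at well-separated sites, true methylation levels
#' drawn from the Beta prior, and `coverage` single-end primary reads per
#' site whose QVs and substitution/deletion rates shift inside the
#' feature window according to the read's Bernoulli(true level)
#' methylation state. Reads are written as coordinate-sorted SAM,
#' converted to an indexed BAM; the loci table is written in the extended
#' bedMethyl dialect with the realized methylated-read fraction as the
#' percent column, score 1000 and the configured coverage. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory (created if missing).
#' @return list with paths `fasta`, `bam`, `loci`, `truthFile`, and the
#'   truth `data.frame` (`chrom`, 0-based `position`, `strand`,
#'   `trueLevel`, `methylatedReads`, `realizedLevel`).
#' @export
simulateDataset <- function(cfg, dir) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    withSeed(cfg$seed, {
        genome <- sample(BASE_ALPHABET, cfg$genomeLength, replace = TRUE)
        sites <- placeSites(cfg$nCpG, cfg$genomeLength)
        genome[sites + 1L] <- "C"
        genome[sites + 2L] <- "G"
        trueLevel <- rbeta(cfg$nCpG, cfg$methylationPrior[1],
                           cfg$methylationPrior[2])
        span <- 2L * (cfg$flank + cfg$readPad) + 1L
        sam <- character(cfg$nCpG * cfg$coverage)
        methCount <- integer(cfg$nCpG)
        k <- 0L
        for (i in seq_len(cfg$nCpG)) {
            c0 <- sites[i]
            rs <- c0 - cfg$flank - cfg$readPad
            refBases <- genome[rs + seq_len(span)]
            states <- runif(cfg$coverage) < trueLevel[i]
            methCount[i] <- sum(states)
            for (j in seq_len(cfg$coverage)) {
                rec <- simulateRead(refBases, rs, c0, states[j], cfg)
                k <- k + 1L
                sam[k] <- paste(sprintf("site%05d_read%04d", i, j), 0L,
                                cfg$chrom, rec$pos, 60L, rec$cigar,
                                "*", 0L, 0L, rec$seq, rec$qual,
                                sep = "\t")
            }
        }
        fastaPath <- file.path(dir, "reference.fa")
        writeLines(c(paste0(">", cfg$chrom),
                     substring(paste(genome, collapse = ""),
                               seq(1, cfg$genomeLength, 60),
                               pmin(seq(60, cfg$genomeLength + 59, 60),
                                    cfg$genomeLength))),
                   fastaPath)
        indexFa(fastaPath)
        samPath <- file.path(dir, "reads.sam")
        writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                     sprintf("@SQ\tSN:%s\tLN:%d", cfg$chrom,
                             cfg$genomeLength),
                     sam), samPath)
        bamPath <- suppressMessages(
            asBam(samPath, file.path(dir, "reads"), overwrite = TRUE,
                  indexDestination = TRUE))
        realized <- methCount / cfg$coverage
        lociPath <- file.path(dir, "loci.tsv")
        bedRow <- function(pos0, strandChar)
            sprintf("%s\t%d\t%d\t5mC\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%.2f",
                    cfg$chrom, pos0, pos0 + 1L, 1000L, strandChar,
                    pos0, pos0 + 1L, cfg$coverage, 100 * realized)
        rows <- bedRow(sites, "+")
        if (cfg$reverseRecords)
            rows <- as.vector(rbind(rows, bedRow(sites + 1L, "-")))
        writeLines(rows, lociPath)
        truth <- data.frame(chrom = cfg$chrom, position = sites,
                            strand = "+", trueLevel = trueLevel,
                            methylatedReads = methCount,
                            realizedLevel = realized,
                            stringsAsFactors = FALSE)
        truthPath <- file.path(dir, "truth.tsv")
        write.table(truth, truthPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        list(fasta = fastaPath, bam = bamPath, loci = lociPath,
             truthFile = truthPath, truth = truth, config = cfg)
    })
}

#' Split simulated sites into disjoint train and test sets
#'
#' Mirrors the train-on-one-region / evaluate-on-another protocol: a
#' seeded random partition of the truth table's sites.
#'
#' @param truth the truth `data.frame` from [simulateDataset()].
#' @param fraction fraction of sites assigned to training (in (0, 1)).
#' @param seed RNG seed.
#' @return list with `train` and `test` data frames (disjoint, union =
#'   all sites).
#' @export
splitTrainTest <- function(truth, fraction = 0.75, seed = 0L) {
    if (fraction <= 0 || fraction >= 1)
        mqvStop("fraction must lie in (0, 1)", "domainError")
    n <- nrow(truth)
    withSeed(seed, {
        idx <- sample.int(n, round(fraction * n))
        list(train = truth[sort(idx), , drop = FALSE],
             test = truth[setdiff(seq_len(n), idx), , drop = FALSE])
    })
}
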