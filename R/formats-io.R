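#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end strand
#'   strand<-
#' @importFrom IRanges IRanges
#' @importFrom Biostrings getSeq DNAStringSet
#' @importFrom Rsamtools FaFile scanFa scanFaIndex scanBam ScanBamParam
#'   scanBamHeader indexFa asBam indexBam BamFile
#' @importFrom utils read.table write.table
NULL

## Classed conditions so that callers (the pipeline driver in particular)
## can skip a locus on window-out-of-bounds / unencodable-context signals
## while still failing hard on real I/O problems.
mqvStop <- function(msg, class, call. = FALSE) {
    stop(errorCondition(msg, class = c(class, "MethylQVError", "error")))
}

#' Construct per-strand CpG methylation records
#'
#' Methylation records are represented as a [GenomicRanges::GRanges] of
#' width-1 cytosine positions with metadata columns `score` (0-1000),
#' `depth` (filtered read count) and `level` (methylation fraction in
#' \[0, 1\]). Positions follow the usual GRanges 1-based convention;
#' file readers and writers convert from/to the 0-based BED-style
#' coordinates of the on-disk formats.
#'
#' @param chrom character vector of contig names.
#' @param start0 integer vector, 0-based cytosine positions.
#' @param strand character vector, `"+"` or `"-"`.
#' @param level numeric vector, methylation fractions in \[0, 1\].
#' @param depth integer vector, read counts (default 0).
#' @param score integer vector, bedMethyl scores in \[0, 1000\]
#'   (default 1000).
#' @return a `GRanges` with the metadata columns described above.
#' @examples
#' methylationRecords("chr1", c(100L, 101L), c("+", "-"), c(0.8, 0.6),
#'                    depth = c(12L, 15L))
#' @export
methylationRecords <- function(chrom, start0, strand, level,
                               depth = 0L, score = 1000L) {
    if (any(level < 0 | level > 1))
        mqvStop("methylation levels must lie in [0, 1]", "domainError")
    if (any(score < 0 | score > 1000))
        mqvStop("scores must lie in [0, 1000]", "domainError")
    if (any(depth < 0))
        mqvStop("depth must be non-negative", "domainError")
    if (!all(strand %in% c("+", "-")))
        mqvStop("strand must be '+' or '-'", "domainError")
    gr <- GRanges(chrom, IRanges(start = as.integer(start0) + 1L, width = 1L),
                  strand = strand)
    n <- length(gr)
    mcols(gr)$score <- rep(as.integer(score), length.out = n)
    mcols(gr)$depth <- rep(as.integer(depth), length.out = n)
    mcols(gr)$level <- rep(as.numeric(level), length.out = n)
    gr
}

#' Read a bedMethyl-dialect loci table with depth/score filtering
#'
#' Parses the extended bedMethyl dialect emitted by per-locus CpG
#' methylation callers: at least 11 tab-separated columns, with the
#' bedMethyl score in column 5, strand in column 6, read coverage in
#' column 10 and methylation percent in column 11. Loci with coverage
#' below `minDepth` or score below `minScore` are dropped; the defaults
#' reproduce the training filter of removing loci below 10x depth or
#' score under 800.
#'
#' @param path path to the tab-separated loci table.
#' @param minDepth minimum coverage to retain a locus (default 10).
#' @param minScore minimum bedMethyl score to retain a locus (default 800).
#' @param quiet suppress the message reporting retained/dropped counts.
#' @return a `GRanges` of per-strand records (see [methylationRecords()]);
#'   `level` is the percent column divided by 100.
#' @export
readLociTable <- function(path, minDepth = 10L, minScore = 800L,
                          quiet = FALSE) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(methylationRecords(character(), integer(), character(),
                                  numeric()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
        mqvStop(sprintf("line %d: expected >= 11 tab-separated columns, got %d",
                        which(nf < 11L)[1], nf[which(nf < 11L)[1]]),
                "parseError")
    getcol <- function(i) vapply(fields, `[[`, character(1), i)
    numcol <- function(i, what) {
        v <- suppressWarnings(as.numeric(getcol(i)))
        if (anyNA(v))
            mqvStop(sprintf("line %d: non-numeric %s", which(is.na(v))[1],
                            what), "parseError")
        v
    }
    chrom <- getcol(1)
    start0 <- numcol(2, "start")
    score <- numcol(5, "score")
    str <- getcol(6)
    depth <- numcol(10, "coverage")
    pct <- numcol(11, "methylation percent")
    if (any(pct < 0 | pct > 100))
        mqvStop(sprintf("line %d: methylation percent outside [0, 100]",
                        which(pct < 0 | pct > 100)[1]), "parseError")
    if (!all(str %in% c("+", "-")))
        mqvStop(sprintf("line %d: strand must be '+' or '-'",
                        which(!str %in% c("+", "-"))[1]), "parseError")
    keep <- depth >= minDepth & score >= minScore
    if (!quiet)
        message(sprintf("readLociTable: %d loci retained, %d dropped (depth < %d or score < %d)",
                        sum(keep), sum(!keep), minDepth, minScore))
    methylationRecords(chrom[keep], start0[keep], str[keep], pct[keep] / 100,
                       depth = depth[keep], score = score[keep])
}

#' Extract the reference bases of a candidate-site window
#'
#' Returns the `2*flank + 1` upper-cased reference bases centred on a
#' 0-based position. Signals a classed condition when the window crosses
#' a contig boundary (`windowOutOfBounds`) or contains a base outside
#' `{A,C,G,T}` (`contextUnencodable`); pipeline drivers catch these and
#' skip the locus.
#'
#' @param fasta path to an indexed FASTA file (a `.fai` is created if
#'   absent), or an open [Rsamtools::FaFile].
#' @param chrom contig name.
#' @param center 0-based position of the candidate base.
#' @param flank window half-width (default 10, a 21-base window).
#' @return character vector of `2*flank + 1` single bases.
#' @export
readReferenceWindow <- function(fasta, chrom, center, flank = 10L) {
    fa <- if (is(fasta, "FaFile")) fasta else {
        if (!file.exists(paste0(path.expand(fasta), ".fai"))) indexFa(fasta)
        FaFile(fasta)
    }
    idx <- scanFaIndex(fa)
    hit <- which(as.character(seqnames(idx)) == chrom)
    if (length(hit) == 0L)
        mqvStop(sprintf("contig '%s' not found in FASTA", chrom),
                "lookupError")
    clen <- end(idx)[hit[1]]
    lo <- center - flank          # 0-based inclusive
    hi <- center + flank
    if (lo < 0L || hi >= clen)
        mqvStop(sprintf("window [%d, %d] out of bounds for contig '%s' (length %d)",
                        lo, hi, chrom, clen), "windowOutOfBounds")
    seq <- as.character(scanFa(fa, GRanges(chrom, IRanges(lo + 1L, hi + 1L))))
    bases <- toupper(strsplit(seq, "", fixed = TRUE)[[1]])
    if (!all(bases %in% BASE_ALPHABET))
        mqvStop(sprintf("window at %s:%d contains a non-ACGT reference base",
                        chrom, center), "contextUnencodable")
    bases
}

## Map the window's reference positions to query indices for one read:
## > 0 query index (1-based), 0 deletion, NA not aligned (clipped, skipped,
## or outside the read). ws/we are 1-based reference coordinates.
cigarWindowMap <- function(pos, cigar, ws, we) {
    toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
    ops <- substr(toks, nchar(toks), nchar(toks))
    qidx <- rep(NA_integer_, we - ws + 1L)
    refp <- pos
    qp <- 1L
    for (k in seq_along(ops)) {
        len <- lens[k]
        op <- ops[k]
        if (op == "M" || op == "=" || op == "X") {
            lo <- max(refp, ws); hi <- min(refp + len - 1L, we)
            if (lo <= hi)
                qidx[(lo:hi) - ws + 1L] <- qp + (lo:hi) - refp
            refp <- refp + len
            qp <- qp + len
        } else if (op == "D") {
            lo <- max(refp, ws); hi <- min(refp + len - 1L, we)
            if (lo <= hi) qidx[(lo:hi) - ws + 1L] <- 0L
            refp <- refp + len
        } else if (op == "N") {
            refp <- refp + len
        } else if (op == "I" || op == "S") {
            qp <- qp + len
        }                                   # H and P consume nothing
    }
    qidx
}

#' Collect the reads fully covering a candidate-site window
#'
#' Builds a [WindowPileup-class] from a sorted, indexed BAM: the
#' rectangular stack of bases and QVs of every read whose alignment covers
#' all `2*flank + 1` positions of the window with match, mismatch or
#' deletion operations. Reads that start or end inside the window, span it
#' with a reference skip, carry an `N` base in the window, or match any
#' bit of `flagExclude` are excluded. Insertions between window positions
#' are ignored; deletions appear as base `"D"` with QV `deletionQV`.
#'
#' The default flag mask 4079 mirrors the upstream `samtools view -F 4079`
#' filter: it drops unmapped, secondary, supplementary, duplicate and
#' QC-fail records and every pairing-related record, which is deliberate
#' for single-end nanopore data and configurable for anything else.
#'
#' @param bam path to a sorted, indexed BAM file.
#' @param chrom contig name.
#' @param center 0-based position of the candidate base.
#' @param flank window half-width (default 10).
#' @param flagExclude integer bitmask of SAM flags to exclude
#'   (default 4079).
#' @param deletionQV placeholder QV recorded at deleted positions
#'   (default 0).
#' @param context optional pre-fetched reference context (character vector
#'   of window bases); when `NULL` it must be attached later.
#' @param strand strand of the candidate cytosine (annotation only).
#' @return a `WindowPileup`.
#' @export
collectWindowReads <- function(bam, chrom, center, flank = 10L,
                               flagExclude = 4079L, deletionQV = 0,
                               context = NULL, strand = "+") {
    ws <- center - flank + 1L     # 1-based window bounds
    we <- center + flank + 1L
    w <- 2L * flank + 1L
    hdr <- scanBamHeader(bam)[[1]]$targets
    if (!chrom %in% names(hdr))
        mqvStop(sprintf("contig '%s' absent from BAM header", chrom),
                "lookupError")
    param <- ScanBamParam(
        which = GRanges(chrom, IRanges(max(ws, 1L), we)),
        what = c("pos", "cigar", "seq", "qual", "flag")
    )
    res <- scanBam(bam, param = param)[[1]]
    nres <- length(res$pos)
    Q <- matrix(numeric(0), nrow = 0L, ncol = w)
    R <- matrix(character(0), nrow = 0L, ncol = w)
    if (nres > 0L) {
        seqs <- as.character(res$seq)
        quals <- as(res$qual, "IntegerList")
        for (r in seq_len(nres)) {
            if (bitwAnd(res$flag[r], flagExclude) != 0L) next
            if (is.na(res$pos[r]) || is.na(res$cigar[r])) next
            qidx <- cigarWindowMap(res$pos[r], res$cigar[r], ws, we)
            if (anyNA(qidx)) next                    # not fully covering
            bases <- rep("D", w)
            qv <- rep(as.numeric(deletionQV), w)
            aligned <- qidx > 0L
            if (any(aligned)) {
                chars <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
                bases[aligned] <- chars[qidx[aligned]]
                qv[aligned] <- as.numeric(quals[[r]][qidx[aligned]])
            }
            if (any(!bases %in% READ_ALPHABET)) next # e.g. an in-window N
            Q <- rbind(Q, qv)
            R <- rbind(R, bases)
        }
    }
    dimnames(Q) <- NULL
    dimnames(R) <- NULL
    if (is.null(context)) context <- rep("A", w)   # placeholder context
    new("WindowPileup", Q = Q, R = R, context = context,
        chrom = chrom, center = as.integer(center),
        strand = strand, flank = as.integer(flank))
}

#' Write per-CpG methylation predictions
#'
#' Writes a deterministic tab-separated table (one row per record, sorted
#' by chrom, start, strand): `chrom`, 0-based `start`, `end`, `strand`,
#' `depth`, and `level` as a percent with two decimals.
#'
#' @param records a `GRanges` of methylation records
#'   (see [methylationRecords()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePredictions <- function(records, path) {
    df <- data.frame(
        chrom = as.character(seqnames(records)),
        start = start(records) - 1L,
        end = end(records),
        strand = as.character(strand(records)),
        depth = mcols(records)$depth,
        level = sprintf("%.2f", 100 * mcols(records)$level),
        stringsAsFactors = FALSE
    )
    df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("chrom", "start", "end", "strand", "depth", "level"),
                     collapse = "\t"), con)
    if (nrow(df))
        write.table(df, con, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read back a prediction table written by [writePredictions()]
#'
#' @param path path to the prediction TSV.
#' @return a `GRanges` of methylation records (score set to 1000).
#' @export
readPredictions <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c("character", "integer", "integer",
                                    "character", "integer", "numeric"))
    methylationRecords(df$chrom, df$start, df$strand, df$level / 100,
                       depth = df$depth)
}

#' Read a BED3/BED4 region file
#'
#' @param path path to a BED file (tab-separated; columns chrom, start,
#'   end and optionally name; further columns ignored).
#' @return a `GRanges`; the BED name column, when present, is kept as
#'   metadata column `name`.
#' @export
readRegions <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
    if (length(lines) == 0L)
        return(GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L))
        mqvStop("BED lines must have at least 3 columns", "parseError")
    chrom <- vapply(fields, `[[`, character(1), 1)
    s0 <- as.integer(vapply(fields, `[[`, character(1), 2))
    e0 <- as.integer(vapply(fields, `[[`, character(1), 3))
    if (any(is.na(s0)) || any(is.na(e0)) || any(s0 >= e0))
        mqvStop("BED intervals must satisfy start < end", "parseError")
    gr <- GRanges(chrom, IRanges(s0 + 1L, e0))
    if (all(lengths(fields) >= 4L))
        mcols(gr)$name <- vapply(fields, `[[`, character(1), 4)
    gr
}
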