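test_that("loci table filtering keeps rows passing both depth and score thresholds", {
    rows <- data.frame(chrom = "chr1", start = c(100L, 200L, 300L, 400L),
                       strand = "+", score = c(900L, 799L, 800L, 1000L),
                       coverage = c(5L, 10L, 30L, 12L),
                       percent = c("10.00", "20.00", "30.00", "100.00"))
    path <- writeLociFile(rows)
    gr <- readLociTable(path, minDepth = 10, minScore = 800, quiet = TRUE)
    expect_length(gr, 2L)
    expect_equal(start(gr) - 1L, c(300L, 400L))
    expect_equal(mcols(gr)$level, c(0.30, 1.0))
    expect_equal(mcols(gr)$depth, c(30L, 12L))
    ## null thresholds retain every well-formed row
    expect_length(readLociTable(path, 0, 0, quiet = TRUE), 4L)
    ## empty file -> empty result
    empty <- tempfile(); writeLines(character(), empty)
    expect_length(readLociTable(empty, quiet = TRUE), 0L)
})

test_that("malformed loci tables raise parse errors naming the line", {
    bad <- tempfile()
    writeLines("chr1\t100\t101\t5mC\t900\t+", bad)          # 6 columns
    expect_error(readLociTable(bad, quiet = TRUE), "line 1",
                 class = "parseError")
    writeLines(c("chr1\t1\t2\tm\t900\t+\t1\t2\tc\t20\t50",
                 "chr1\t5\t6\tm\tXX\t+\t5\t6\tc\t20\t50"), bad)
    expect_error(readLociTable(bad, quiet = TRUE), "line 2",
                 class = "parseError")
    writeLines("chr1\t1\t2\tm\t900\t+\t1\t2\tc\t20\t150", bad)
    expect_error(readLociTable(bad, quiet = TRUE), "percent",
                 class = "parseError")
})

test_that("reference windows are extracted, bounded and alphabet-checked", {
    fa <- writeTestFasta("ACGTACGTACGTACGTACGTACGT")   # 24 bases
    win <- readReferenceWindow(fa, "chrT", center = 10, flank = 10)
    expect_length(win, 21L)
    expect_equal(paste(win, collapse = ""), "ACGTACGTACGTACGTACGTA")
    expect_error(readReferenceWindow(fa, "chrT", center = 5, flank = 10),
                 class = "windowOutOfBounds")
    expect_error(readReferenceWindow(fa, "chrT", center = 20, flank = 10),
                 class = "windowOutOfBounds")
    expect_error(readReferenceWindow(fa, "chrX", center = 10, flank = 10),
                 class = "lookupError")
    faN <- writeTestFasta("ACGTACGTACGNACGTACGTACGT")
    expect_error(readReferenceWindow(faN, "chrT", center = 10, flank = 10),
                 class = "contextUnencodable")
})

test_that("window pileup keeps only fully covering, unflagged, N-free reads", {
    ## window: center 0-based 30, flank 5 -> ref positions 26..36 (1-based)
    ref <- paste(rep("ACGTT", 20), collapse = "")
    refv <- strsplit(ref, "")[[1]]
    span <- function(pos, len) paste(refv[pos:(pos + len - 1)], collapse = "")
    reads <- list(
        list(pos = 20, cigar = "30M", seq = span(20, 30),
             qual = qualString(rep(20, 30))),
        list(pos = 25, cigar = "20M", seq = span(25, 20),
             qual = qualString(rep(25, 20))),
        list(pos = 26, cigar = "15M", seq = span(26, 15),
             qual = qualString(rep(30, 15))),
        ## starts inside the window -> excluded
        list(pos = 30, cigar = "20M", seq = span(30, 20),
             qual = qualString(rep(15, 20))),
        ## supplementary -> excluded by the default mask
        list(pos = 20, cigar = "30M", seq = span(20, 30),
             qual = qualString(rep(20, 30)), flag = 2048L)
    )
    bam <- writeTestBam(reads, reflen = 100L)
    pu <- collectWindowReads(bam, "chrT", center = 30, flank = 5)
    expect_s4_class(pu, "WindowPileup")
    expect_equal(readCount(pu), 3L)
    expect_equal(windowWidth(pu), 11L)
    for (r in 1:3)                         # error-free reads echo the reference
        expect_equal(unname(baseMatrix(pu)[r, ]), refv[26:36])
    ## flagExclude = 0 admits the supplementary read too
    pu0 <- collectWindowReads(bam, "chrT", center = 30, flank = 5,
                              flagExclude = 0L)
    expect_equal(readCount(pu0), 4L)
    expect_error(collectWindowReads(bam, "nope", 30, 5),
                 class = "lookupError")
})

test_that("deletions map to D with the placeholder QV; in-window N drops the read", {
    ref <- strsplit(paste(rep("ACGTT", 8), collapse = ""), "")[[1]]
    sq <- function(pos, len) paste(ref[pos:(pos + len - 1)], collapse = "")
    ## read 1: 10M 2D 8M starting at 15 -> deletion at ref 25,26
    reads <- list(
        list(pos = 15, cigar = "10M2D8M",
             seq = paste0(sq(15, 10), sq(27, 8)),
             qual = qualString(rep(20, 18))),
        list(pos = 15, cigar = "20M", seq = sq(15, 20),
             qual = qualString(rep(20, 20))),
        list(pos = 15, cigar = "20M",
             seq = paste0(sq(15, 5), "N", sq(21, 14)),
             qual = qualString(rep(20, 20)))
    )
    bam <- writeTestBam(reads, reflen = 50L)
    pu <- collectWindowReads(bam, "chrT", center = 23, flank = 5,
                             deletionQV = 0)
    expect_equal(readCount(pu), 2L)      # N-containing read dropped
    ## window 0-based 18..28 -> 1-based 19..29; deletion at cols 7,8
    expect_equal(baseMatrix(pu)[1, 7:8], c("D", "D"))
    expect_equal(qvMatrix(pu)[1, 7:8], c(0, 0))
    expect_true(all(baseMatrix(pu)[2, ] != "D"))
    ## flank 0 gives the classic single-column pileup; the N-carrying read
    ## is admitted because its N lies outside the single-position window
    pu1 <- collectWindowReads(bam, "chrT", center = 23, flank = 0)
    expect_equal(dim(qvMatrix(pu1)), c(3L, 1L))
})

test_that("prediction tables are formatted, sorted and round-trippable", {
    gr <- methylationRecords(c("chr2", "chr1"), c(200L, 100L), c("+", "+"),
                             c(0.123, 0.5), depth = c(7L, 15L))
    path <- tempfile()
    writePredictions(gr, path)
    lines <- readLines(path)
    expect_equal(lines[1], "chrom\tstart\tend\tstrand\tdepth\tlevel")
    expect_equal(lines[2], "chr1\t100\t101\t+\t15\t50.00")
    expect_equal(lines[3], "chr2\t200\t201\t+\t7\t12.30")
    back <- readPredictions(path)
    expect_equal(as.character(seqnames(back)), c("chr1", "chr2"))
    expect_equal(start(back) - 1L, c(100L, 200L))
    expect_equal(mcols(back)$depth, c(15L, 7L))
    expect_lt(max(abs(mcols(back)$level - c(0.5, 0.123))), 0.005)
    ## empty set -> header-only file
    writePredictions(gr[0], path)
    expect_length(readLines(path), 1L)
})

test_that("BED region files parse with optional names", {
    path <- tempfile()
    writeLines(c("chr1\t10\t20\tcpgi1", "chr1\t100\t150\tcpgi2"), path)
    gr <- readRegions(path)
    expect_length(gr, 2L)
    expect_equal(start(gr) - 1L, c(10L, 100L))
    expect_equal(mcols(gr)$name, c("cpgi1", "cpgi2"))
    writeLines("chr1\t50\t40", path)
    expect_error(readRegions(path), class = "parseError")
})
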