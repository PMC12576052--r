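test_that("simulation is byte-identical under a fixed seed", {
    cfg <- simulationConfig(nCpG = 12L, coverage = 8L, seed = 21L)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    s1 <- simulateDataset(cfg, d1)
    s2 <- simulateDataset(cfg, d2)
    expect_identical(readLines(s1$fasta), readLines(s2$fasta))
    expect_identical(readLines(file.path(d1, "reads.sam")),
                     readLines(file.path(d2, "reads.sam")))
    expect_identical(readLines(s1$loci), readLines(s2$loci))
    expect_identical(s1$truth, s2$truth)
    ## a different seed changes the reads
    s3 <- simulateDataset(simulationConfig(nCpG = 12L, coverage = 8L,
                                           seed = 22L),
                          withr::local_tempdir())
    expect_false(identical(readLines(file.path(d1, "reads.sam")),
                           readLines(s3$truthFile)))
})

test_that("simulated loci carry planted CpGs and full default-filter depth", {
    cfg <- simulationConfig(nCpG = 10L, coverage = 15L, seed = 5L)
    sim <- simulateDataset(cfg, withr::local_tempdir())
    ## CpG dinucleotide planted at every site
    for (pos in sim$truth$position[1:5]) {
        win <- readReferenceWindow(sim$fasta, cfg$chrom, pos, flank = 1)
        expect_equal(win[2:3], c("C", "G"))
    }
    ## spacing and edge margins
    expect_true(all(diff(sim$truth$position) >= 25L))
    ## pileup depth equals coverage after the default flag filter
    for (pos in sim$truth$position[1:5]) {
        pu <- collectWindowReads(sim$bam, cfg$chrom, pos, flank = 10)
        expect_equal(readCount(pu), 15L)
    }
    ## loci table parses under the training filter
    gr <- readLociTable(sim$loci, quiet = TRUE)
    expect_length(gr, 10L)
    expect_equal(mcols(gr)$depth, rep(15L, 10L))
    ## percent column carries two decimals
    expect_equal(mcols(gr)$level, sim$truth$realizedLevel,
                 tolerance = 1e-4)
})

test_that("a null effect and zero error rates produce error-free pileups", {
    cfg <- simulationConfig(nCpG = 6L, coverage = 10L, seed = 9L,
                            errorBaseline = c(substitution = 0,
                                              deletion = 0),
                            qvShiftKernel = numeric(21),
                            substitutionShiftKernel = numeric(21),
                            deletionShiftKernel = numeric(21))
    sim <- simulateDataset(cfg, withr::local_tempdir())
    for (pos in sim$truth$position[1:3]) {
        ctx <- readReferenceWindow(sim$fasta, cfg$chrom, pos, flank = 10)
        pu <- collectWindowReads(sim$bam, cfg$chrom, pos, flank = 10,
                                 context = ctx)
        expect_true(all(jointErrorRates(pu)@E == 0))
        expect_true(all(baseMatrix(pu) != "D"))
    }
})

test_that("the realized per-site methylated fraction is binomially consistent", {
    cfg <- simulationConfig(nCpG = 50L, coverage = 40L, seed = 31L)
    sim <- simulateDataset(cfg, withr::local_tempdir())
    ## 99% binomial band around the true level, site by site
    p <- sim$truth$trueLevel
    k <- sim$truth$methylatedReads
    lo <- qbinom(0.005, cfg$coverage, p)
    hi <- qbinom(0.995, cfg$coverage, p)
    expect_gte(mean(k >= lo & k <= hi), 0.90)
})

test_that("a strong deletion shift shows up at the expected binomial rate", {
    ## fully methylated sites, deletions only at the centre, 50% rate
    cfg <- simulationConfig(
        nCpG = 4L, coverage = 200L, seed = 17L,
        methylationPrior = c(5000, 0.001),
        errorBaseline = c(substitution = 0, deletion = 0),
        qvShiftKernel = numeric(21),
        substitutionShiftKernel = numeric(21),
        deletionShiftKernel = kernelAt_test(10L, 0L, 0.5))
    sim <- simulateDataset(cfg, withr::local_tempdir())
    expect_true(all(sim$truth$trueLevel > 0.999))
    for (pos in sim$truth$position) {
        pu <- collectWindowReads(sim$bam, cfg$chrom, pos, flank = 10)
        delFrac <- mean(baseMatrix(pu)[, 11] == "D")
        expect_gt(delFrac, 0.40)   # 99.8% binomial band at n = 200
        expect_lt(delFrac, 0.60)
    }
})

test_that("the injected methylation effect moves QVs and error rates as configured", {
    ## compare a fully methylated against a fully unmethylated simulation
    base <- list(nCpG = 15L, coverage = 40L, seed = 23L)
    mk <- function(prior) {
        cfg <- simulationConfig(nCpG = base$nCpG, coverage = base$coverage,
                                seed = base$seed,
                                methylationPrior = prior)
        simulateDataset(cfg, withr::local_tempdir(.local_envir = parent.frame()))
    }
    hyper <- mk(c(5000, 0.001))     # ~fully methylated
    hypo <- mk(c(0.001, 5000))      # ~fully unmethylated
    stat <- function(sim) {
        qc <- 0; ec <- 0
        for (pos in sim$truth$position) {
            ctx <- readReferenceWindow(sim$fasta, "simchr", pos, flank = 10)
            pu <- collectWindowReads(sim$bam, "simchr", pos, flank = 10,
                                     context = ctx)
            qc <- qc + mean(meanQV(pu)[9:13])      # offsets -2..+2
            ec <- ec + sum(jointErrorRates(pu)@E[, , 11, 11])
        }
        c(qv = qc, err = ec) / length(sim$truth$position)
    }
    sh <- stat(hyper); so <- stat(hypo)
    expect_lt(sh[["qv"]], so[["qv"]] - 3)     # QV depressed by the shift
    expect_gt(sh[["err"]], so[["err"]])       # centre error rate raised
})

test_that("train/test splits are disjoint, exhaustive and seed-stable", {
    cfg <- simulationConfig(nCpG = 100L, coverage = 5L, seed = 2L)
    sim <- simulateDataset(cfg, withr::local_tempdir())
    sp <- splitTrainTest(sim$truth, 0.5, seed = 3L)
    expect_equal(nrow(sp$train), 50L)
    expect_equal(nrow(sp$test), 50L)
    expect_length(intersect(sp$train$position, sp$test$position), 0L)
    expect_setequal(c(sp$train$position, sp$test$position),
                    sim$truth$position)
    sp2 <- splitTrainTest(sim$truth, 0.5, seed = 3L)
    expect_identical(sp, sp2)
    expect_false(identical(sp, splitTrainTest(sim$truth, 0.5, seed = 4L)))
    expect_error(splitTrainTest(sim$truth, 1.5), class = "domainError")
})

test_that("impossible site spacing is rejected", {
    expect_error(
        simulateDataset(simulationConfig(nCpG = 100L, coverage = 2L,
                                         genomeLength = 500L),
                        withr::local_tempdir()),
        class = "configError")
    expect_error(simulationConfig(nCpG = 5L, coverage = 0L),
                 class = "configError")
    expect_error(
        simulationConfig(errorBaseline = c(substitution = 0.9,
                                           deletion = 0.5)),
        class = "configError")
})
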