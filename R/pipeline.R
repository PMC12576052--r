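#' @importFrom utils write.table read.table head
NULL

#' Build the feature table for a set of candidate loci
#'
#' The first pipeline step: for every locus in the (already filtered)
#' loci table, fetch the reference window, collect the fully covering
#' reads from the BAM and extract the feature vector. Loci whose window
#' crosses a contig edge, contains a non-ACGT reference base, or is
#' covered by fewer than `max(2, minDepth)` eligible reads are skipped
#' and counted.
#'
#' @param bam path to the sorted, indexed BAM.
#' @param fasta path to the indexed reference FASTA.
#' @param loci a `GRanges` of candidate records (see [readLociTable()])
#'   or a path to a bedMethyl-dialect file (filtered with `minDepth` and
#'   `minScore`).
#' @param flank window half-width (default 10).
#' @param minDepth minimum pileup depth for feature extraction and, when
#'   `loci` is a path, the loci-table depth filter (default 10).
#' @param minScore loci-table score filter when `loci` is a path
#'   (default 800).
#' @param flagExclude SAM flag bitmask for read exclusion (default 4079).
#' @param deletionQV placeholder QV at deleted positions (default 0).
#' @param sigmaDdof spread divisor for the standardized moments
#'   (default 0, population).
#' @param chrom optional contig name; restricts processing to that contig.
#' @param quiet suppress the summary message.
#' @return list with `X` (numeric feature matrix, one row per kept
#'   locus), `loci` (`GRanges` of kept loci), `layoutVersion`, `flank`,
#'   and `skipped` (named counts by reason: `edge`, `context`, `depth`).
#' @export
buildFeatureTable <- function(bam, fasta, loci, flank = 10L,
                              minDepth = 10L, minScore = 800L,
                              flagExclude = 4079L, deletionQV = 0,
                              sigmaDdof = 0L, chrom = NULL,
                              quiet = FALSE) {
    if (is.character(loci))
        loci <- readLociTable(loci, minDepth, minScore, quiet = quiet)
    if (!is.null(chrom))
        loci <- loci[as.character(seqnames(loci)) == chrom]
    fa <- if (file.exists(paste0(path.expand(fasta), ".fai"))) FaFile(fasta)
          else { indexFa(fasta); FaFile(fasta) }
    n <- length(loci)
    seg <- featureSegmentLengths(flank)
    keep <- logical(n)
    depth <- integer(n)
    rows <- vector("list", n)
    skipped <- c(edge = 0L, context = 0L, depth = 0L)
    minN <- max(2L, minDepth)
    for (i in seq_len(n)) {
        center <- start(loci)[i] - 1L
        ch <- as.character(seqnames(loci)[i])
        ctx <- tryCatch(
            readReferenceWindow(fa, ch, center, flank),
            windowOutOfBounds = function(e) {
                skipped["edge"] <<- skipped["edge"] + 1L; NULL },
            contextUnencodable = function(e) {
                skipped["context"] <<- skipped["context"] + 1L; NULL })
        if (is.null(ctx)) next
        pu <- collectWindowReads(bam, ch, center, flank, flagExclude,
                                 deletionQV, context = ctx,
                                 strand = as.character(strand(loci)[i]))
        if (readCount(pu) < minN) {
            skipped["depth"] <- skipped["depth"] + 1L
            next
        }
        rows[[i]] <- featureValues(extractFeatures(pu, sigmaDdof))
        depth[i] <- readCount(pu)
        keep[i] <- TRUE
    }
    X <- if (any(keep)) do.call(rbind, rows[keep])
         else matrix(numeric(0), 0L, sum(seg))
    kept <- loci[keep]
    if (length(kept)) mcols(kept)$depth <- depth[keep]
    if (!quiet)
        message(sprintf(
            "buildFeatureTable: %d loci featurized, skipped %d (edge %d, context %d, depth %d)",
            sum(keep), sum(skipped), skipped["edge"], skipped["context"],
            skipped["depth"]))
    list(X = X, loci = kept, layoutVersion = FEATURE_LAYOUT_VERSION,
         flank = as.integer(flank), skipped = skipped)
}

#' Write / read a feature table
#'
#' Tab-separated, one row per locus: `chrom`, 0-based `start`, `strand`,
#' `depth`, then the feature columns. The first line is a `#`-prefixed
#' header embedding the layout version and flank, checked on reading.
#'
#' @param ft a feature-table list from [buildFeatureTable()].
#' @param path output path.
#' @return the path ([writeFeatureTable()]) or a feature-table list
#'   ([readFeatureTable()]).
#' @export
writeFeatureTable <- function(ft, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#layout=%s\tflank=%d", ft$layoutVersion, ft$flank),
               con)
    df <- data.frame(chrom = as.character(seqnames(ft$loci)),
                     start = start(ft$loci) - 1L,
                     strand = as.character(strand(ft$loci)),
                     depth = mcols(ft$loci)$depth,
                     stringsAsFactors = FALSE)
    nfeat <- ncol(ft$X)
    hdr <- c("chrom", "start", "strand", "depth",
             sprintf("f%05d", seq_len(nfeat)))
    writeLines(paste(hdr, collapse = "\t"), con)
    if (nrow(ft$X))
        write.table(cbind(df, as.data.frame(ft$X)), con, sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    first <- readLines(path, n = 1L)
    if (!startsWith(first, "#layout="))
        mqvStop("not a feature table: missing #layout header", "parseError")
    parts <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    meta <- structure(vapply(kv, `[[`, character(1), 2),
                      names = vapply(kv, `[[`, character(1), 1))
    df <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                     comment.char = "", check.names = FALSE)
    flank <- as.integer(meta[["flank"]])
    X <- as.matrix(df[, -(1:4), drop = FALSE])
    dimnames(X) <- NULL
    loci <- GRanges(df$chrom, IRanges(df$start + 1L, width = 1L),
                    strand = df$strand)
    mcols(loci)$depth <- df$depth
    list(X = X, loci = loci, layoutVersion = meta[["layout"]],
         flank = flank, skipped = c(edge = NA, context = NA, depth = NA))
}

#' Pipeline step: featurize candidate loci (CLI `prepdata`)
#'
#' @param bam,fasta,lociPath input paths (BAM + index, FASTA, bedMethyl
#'   loci table).
#' @param out output feature-table path.
#' @param ... passed to [buildFeatureTable()] (`flank`, `minDepth`,
#'   `minScore`, `flagExclude`, `chrom`, ...).
#' @return the feature-table list, invisibly.
#' @export
cmdPrepData <- function(bam, fasta, lociPath, out, ...) {
    ft <- buildFeatureTable(bam, fasta, lociPath, ...)
    writeFeatureTable(ft, out)
    invisible(ft)
}

alignFeaturesToLoci <- function(ft, labels) {
    keyOf <- function(gr) paste(as.character(seqnames(gr)), start(gr),
                                as.character(strand(gr)), sep = ":")
    idx <- match(keyOf(ft$loci), keyOf(labels))
    if (anyNA(idx))
        mqvStop(sprintf("feature locus %s has no label record",
                        keyOf(ft$loci)[which(is.na(idx))[1]]),
                "alignmentError")
    mcols(labels)$level[idx]
}

#' Pipeline step: train a model (CLI `train`)
#'
#' Joins the feature table with the label loci table by
#' (chrom, start, strand) and fits the boosted regressor.
#'
#' @param featuresPath feature-table path (from [cmdPrepData()]) or a
#'   feature-table list.
#' @param lociPath bedMethyl loci table carrying the training labels, or
#'   a `GRanges` of records.
#' @param outModel output model directory.
#' @param minDepth,minScore loci-table filters (defaults 10 / 800).
#' @param ... passed to [trainModel()] (`alpha`, `mode`, `eta`,
#'   `numRound`, `maxDepth`, `seed`, `featureMask`, ...).
#' @return the [MethylModel-class], invisibly.
#' @export
cmdTrain <- function(featuresPath, lociPath, outModel,
                     minDepth = 10L, minScore = 800L, ...) {
    ft <- if (is.character(featuresPath)) readFeatureTable(featuresPath)
          else featuresPath
    labels <- if (is.character(lociPath))
        readLociTable(lociPath, minDepth, minScore, quiet = TRUE)
        else lociPath
    y <- alignFeaturesToLoci(ft, labels)
    model <- trainModel(ft$X, y, flank = ft$flank, ...)
    saveModel(model, outModel)
    invisible(model)
}

#' Pipeline step: predict methylation levels (CLI `predict`)
#'
#' Loads the model, predicts every locus of the feature table, averages
#' CpG strands and writes the prediction table.
#'
#' @param modelDir model directory (from [cmdTrain()]) or a
#'   [MethylModel-class].
#' @param featuresPath feature-table path or list.
#' @param out output prediction TSV.
#' @param averageCpGStrands merge forward/reverse records of each CpG
#'   site (default TRUE).
#' @return the predicted `GRanges`, invisibly.
#' @export
cmdPredict <- function(modelDir, featuresPath, out,
                       averageCpGStrands = TRUE) {
    model <- if (is.character(modelDir)) loadModel(modelDir) else modelDir
    ft <- if (is.character(featuresPath)) readFeatureTable(featuresPath)
          else featuresPath
    if (!identical(ft$layoutVersion, model@layoutVersion) ||
        !identical(as.integer(ft$flank), model@flank))
        mqvStop(sprintf(
            "feature table (layout %s, flank %d) incompatible with model (layout %s, flank %d)",
            ft$layoutVersion, ft$flank, model@layoutVersion, model@flank),
            "layoutError")
    pred <- predictLoci(model, ft$X, ft$loci)
    if (averageCpGStrands) pred <- averageStrands(pred)
    writePredictions(pred, out)
    invisible(pred)
}

#' Pipeline step: aggregate predictions over regions (CLI `aggregate`)
#'
#' @param predictionsPath prediction TSV (from [cmdPredict()]) or a
#'   `GRanges` of records.
#' @param regionsPath BED3/BED4 region file or a `GRanges`.
#' @param out output summary TSV.
#' @param method `"range_trim"` or `"tail_trim"`.
#' @param ... passed to [summarizeRegions()] (`tailFraction`, `spread`).
#' @return the summary `data.frame`, invisibly.
#' @export
cmdAggregate <- function(predictionsPath, regionsPath, out,
                         method = c("range_trim", "tail_trim"), ...) {
    method <- match.arg(method)
    records <- if (is.character(predictionsPath))
        readPredictions(predictionsPath) else predictionsPath
    regions <- if (is.character(regionsPath)) readRegions(regionsPath)
               else regionsPath
    summary <- summarizeRegions(records, regions, method, ...)
    write.table(summary, out, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(summary)
}
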