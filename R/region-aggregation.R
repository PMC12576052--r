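#' @importFrom GenomicRanges findOverlaps reduce intersect sort
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Range-trimmed mean of methylation levels
#'
#' The aggregation rule used for CpG islands and similar regions: compute
#' the median `m` and the variance `v` of the levels, then average only
#' the values inside `[m - v, m + v]`. The band always contains the
#' median; when no data point falls inside it (possible for an even
#' count, where the median is interpolated), the value(s) nearest the
#' median are kept, so at least one value is always retained. A single
#' value is returned unchanged.
#'
#' @param levels numeric vector of methylation fractions.
#' @param spread `"variance"` (default) for a band half-width of the
#'   sample variance, or `"sd"` for the sample standard deviation (the
#'   two differ in units; variance is the literal reading of
#'   median +/- variance).
#' @return list with `mean` (trimmed mean), `nUsed` (values retained) and
#'   `nTotal`. An empty input yields `mean = NA` and `nUsed = 0`.
#' @export
rangeTrimmedMean <- function(levels, spread = c("variance", "sd")) {
    spread <- match.arg(spread)
    n <- length(levels)
    if (n == 0L)
        return(list(mean = NA_real_, nUsed = 0L, nTotal = 0L))
    if (n == 1L)
        return(list(mean = levels, nUsed = 1L, nTotal = 1L))
    m <- stats::median(levels)
    v <- stats::var(levels)
    half <- if (spread == "variance") v else sqrt(v)
    keep <- levels >= m - half & levels <= m + half
    if (!any(keep)) {
        ## with an even count the median need not be a data point and a
        ## narrow band can exclude everything; fall back to the value(s)
        ## nearest the median so the estimator is total
        d <- abs(levels - m)
        keep <- d == min(d)
    }
    list(mean = mean(levels[keep]), nUsed = sum(keep), nTotal = n)
}

#' Tail-trimmed mean and variance
#'
#' The aggregation rule used for imprinting control regions: sort the
#' values, discard the lowest and highest `floor(tailFraction * n)`
#' values, and report the mean and sample variance of the remainder.
#' With fewer than `1 / tailFraction` values nothing is discarded.
#'
#' @param values numeric vector.
#' @param tailFraction fraction trimmed from each end (default 0.05).
#' @return list with `mean`, `variance` (NA for a single value), `nUsed`
#'   and `nTotal`. An empty input yields `mean = NA` and `nUsed = 0`.
#' @export
tailTrimmedStats <- function(values, tailFraction = 0.05) {
    if (tailFraction < 0 || tailFraction >= 0.5)
        mqvStop("tailFraction must lie in [0, 0.5)", "domainError")
    n <- length(values)
    if (n == 0L)
        return(list(mean = NA_real_, variance = NA_real_,
                    nUsed = 0L, nTotal = 0L))
    k <- floor(tailFraction * n)
    kept <- sort(values)[seq.int(k + 1L, n - k)]
    list(mean = mean(kept),
         variance = if (length(kept) > 1L) stats::var(kept) else NA_real_,
         nUsed = length(kept), nTotal = n)
}

#' Summarize methylation over genomic regions
#'
#' Collects the levels of all (strand-averaged) CpG records whose
#' cytosine position falls inside each region — half-open membership on
#' the 0-based C coordinate — and aggregates them with the chosen
#' trimming rule.
#'
#' @param records a `GRanges` of site-level methylation records (see
#'   [averageStrands()]).
#' @param regions a `GRanges` of regions (e.g. from [readRegions()]).
#' @param method `"range_trim"` (CpG-island rule, default) or
#'   `"tail_trim"` (ICR rule).
#' @param tailFraction tail fraction for `"tail_trim"` (default 0.05).
#' @param spread band half-width for `"range_trim"` (see
#'   [rangeTrimmedMean()]).
#' @return a `data.frame` with one row per region: `chrom`, 0-based
#'   `start`, `end`, `name`, `method`, `nTotal`, `nUsed`, `meanLevel`,
#'   and `variance` (tail trim only).
#' @export
summarizeRegions <- function(records, regions,
                             method = c("range_trim", "tail_trim"),
                             tailFraction = 0.05,
                             spread = c("variance", "sd")) {
    method <- match.arg(method)
    spread <- match.arg(spread)
    hits <- findOverlaps(records, regions, ignore.strand = TRUE)
    nm <- if (!is.null(mcols(regions)$name)) mcols(regions)$name
          else rep(NA_character_, length(regions))
    lv <- mcols(records)$level
    out <- lapply(seq_along(regions), function(i) {
        vals <- lv[queryHits(hits)[subjectHits(hits) == i]]
        if (method == "range_trim") {
            r <- rangeTrimmedMean(vals, spread)
            r$variance <- NA_real_
        } else {
            r <- tailTrimmedStats(vals, tailFraction)
        }
        data.frame(chrom = as.character(seqnames(regions)[i]),
                   start = start(regions)[i] - 1L,
                   end = end(regions)[i],
                   name = nm[i], method = method,
                   nTotal = r$nTotal, nUsed = r$nUsed,
                   meanLevel = r$mean, variance = r$variance,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Intersect two region sets
#'
#' Pairwise interval intersections of two `GRanges`, merged per
#' chromosome and sorted — e.g. the overlap of H3K4me3 peaks with
#' DNase-hypersensitive regions. Strand is ignored.
#'
#' @param a,b `GRanges` of regions.
#' @return a `GRanges` of merged, sorted intersections.
#' @export
intersectRegions <- function(a, b) {
    GenomicRanges::intersect(reduce(a, ignore.strand = TRUE),
                             reduce(b, ignore.strand = TRUE),
                             ignore.strand = TRUE)
}
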