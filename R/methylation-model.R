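#' @importFrom xgboost xgb.train xgb.DMatrix xgb.save xgb.load
#' @importFrom jsonlite write_json read_json
#' @importFrom stats predict
NULL

#' Logit transform of methylation levels
#'
#' Maps a methylation fraction `y` in \[0, 1\] to the real line before
#' regression. Two modes:
#' \describe{
#'   \item{`"clip"` (default)}{epsilon-logit: `y` is clipped to
#'     `[alpha, 1 - alpha]` and then logit-transformed. Monotone over the
#'     whole of \[0, 1\] and exactly invertible on the interior.}
#'   \item{`"literal"`}{the piecewise map `-alpha` at `y = 0`,
#'     `log(y) - log(1 - y)` for `0 < y < 1`, `+alpha` at `y = 1`. Kept
#'     for fidelity to the original formulation; note it sends the two
#'     boundary labels to interior values near 0, breaking monotonicity.}
#' }
#'
#' @param y numeric vector of fractions in \[0, 1\].
#' @param alpha small positive fraction (default `1e-3`).
#' @param mode `"clip"` or `"literal"`.
#' @return numeric vector of transformed values.
#' @export
logitTransform <- function(y, alpha = 1e-3, mode = c("clip", "literal")) {
    mode <- match.arg(mode)
    if (any(y < 0 | y > 1))
        mqvStop("methylation levels must lie in [0, 1]", "domainError")
    if (alpha <= 0 || alpha >= 0.5)
        mqvStop("alpha must lie in (0, 0.5)", "domainError")
    if (mode == "clip") {
        cl <- pmin(pmax(y, alpha), 1 - alpha)
        log(cl) - log(1 - cl)
    } else {
        out <- ifelse(y == 0, -alpha,
               ifelse(y == 1, alpha, log(y) - log(1 - y)))
        out
    }
}

#' Inverse of the logit transform
#'
#' Sigmoid back-map `1 / (1 + exp(-yprime))`, clamped to \[0, 1\];
#' applied to model predictions to recover methylation fractions.
#'
#' @param yprime numeric vector of real values.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
inverseTransform <- function(yprime) {
    pmin(pmax(1 / (1 + exp(-yprime)), 0), 1)
}

#' Stack feature vectors into a model input matrix
#'
#' @param features a list of [FeatureVector-class] objects sharing one
#'   layout.
#' @return numeric matrix, one row per feature vector.
#' @export
featureMatrix <- function(features) {
    if (length(features) == 0L)
        return(matrix(numeric(0), nrow = 0L, ncol = 0L))
    lv <- vapply(features, layoutVersion, character(1))
    if (length(unique(lv)) != 1L)
        mqvStop("feature vectors mix layout versions", "layoutError")
    do.call(rbind, lapply(features, featureValues))
}

#' Train the boosted-tree methylation regressor
#'
#' Fits a squared-error gradient-boosted tree ensemble of
#' logit-transformed methylation levels on window feature vectors. The
#' default hyperparameters are a learning rate (`eta`) of 0.1, 1500
#' boosting rounds and a maximal tree depth of 8; tests and small studies
#' override `numRound` downwards. Training is reproducible for a fixed
#' seed and thread count.
#'
#' @param features list of [FeatureVector-class], or a numeric matrix
#'   with one row per locus (assumed to follow the current layout).
#' @param labels numeric vector of methylation fractions in \[0, 1\]
#'   (e.g. `mcols(records)$level` of a filtered loci table), aligned
#'   one-to-one with `features`.
#' @param alpha logit-transform epsilon (default `1e-3`).
#' @param mode transform mode, `"clip"` (default) or `"literal"`.
#' @param eta learning rate (default 0.1).
#' @param numRound number of boosting rounds (default 1500).
#' @param maxDepth maximal tree depth (default 8).
#' @param seed RNG seed recorded in the model and passed to the booster
#'   (default 0).
#' @param nthread booster threads (default 1 for reproducibility).
#' @param flank window half-width the features were computed with.
#' @param featureMask optional character vector of feature segment names;
#'   when given, only those segments' columns are used (ablation runs).
#' @param minLoci minimum number of training loci (default 10).
#' @param provenance free-text tag stored in the model.
#' @return a [MethylModel-class].
#' @export
trainModel <- function(features, labels, alpha = 1e-3,
                       mode = c("clip", "literal"),
                       eta = 0.1, numRound = 1500L, maxDepth = 8L,
                       seed = 0L, nthread = 1L, flank = 10L,
                       featureMask = NULL, minLoci = 10L,
                       provenance = "unspecified") {
    mode <- match.arg(mode)
    X <- if (is.matrix(features)) features else featureMatrix(features)
    if (nrow(X) != length(labels))
        mqvStop(sprintf("%d feature rows but %d labels", nrow(X),
                        length(labels)), "alignmentError")
    if (nrow(X) < minLoci)
        mqvStop(sprintf("only %d training loci; at least %d required",
                        nrow(X), minLoci), "insufficientData")
    seg <- featureSegmentLengths(flank)
    if (ncol(X) != sum(seg))
        mqvStop(sprintf("feature width %d does not match flank %d layout (%d)",
                        ncol(X), flank, sum(seg)), "layoutError")
    mask <- if (is.null(featureMask)) names(seg) else featureMask
    cols <- segmentIndices(seg, mask)
    yprime <- logitTransform(labels, alpha, mode)
    dtrain <- xgb.DMatrix(X[, cols, drop = FALSE], label = yprime,
                          nthread = nthread)
    booster <- xgb.train(
        params = list(eta = eta, max_depth = maxDepth,
                      objective = "reg:squarederror",
                      nthread = nthread, seed = seed),
        data = dtrain, nrounds = numRound, verbose = 0
    )
    new("MethylModel", booster = booster,
        layoutVersion = FEATURE_LAYOUT_VERSION, flank = as.integer(flank),
        transform = list(alpha = alpha, mode = mode),
        hyperparams = list(eta = eta, num_round = as.integer(numRound),
                           max_depth = as.integer(maxDepth),
                           seed = as.integer(seed),
                           nthread = as.integer(nthread)),
        featureMask = mask, provenance = provenance)
}

#' Predict per-locus methylation levels
#'
#' Applies a trained model to window feature vectors: the booster's
#' prediction on the logit scale is mapped back through
#' [inverseTransform()]. The feature layout and flank of the input must
#' match those recorded in the model.
#'
#' @param model a [MethylModel-class].
#' @param features list of [FeatureVector-class] or a numeric matrix.
#' @param loci a `GRanges` of locus identities aligned with `features`
#'   (chrom/position/strand; a `depth` metadata column is carried over).
#' @return a `GRanges` of methylation records with predicted `level`.
#' @export
predictLoci <- function(model, features, loci) {
    X <- if (is.matrix(features)) features else featureMatrix(features)
    if (nrow(X) == 0L)
        return(methylationRecords(character(), integer(), character(),
                                  numeric()))
    if (!is.matrix(features)) {
        lv <- layoutVersion(features[[1]])
        if (!identical(lv, model@layoutVersion))
            mqvStop(sprintf("feature layout '%s' does not match model layout '%s'",
                            lv, model@layoutVersion), "layoutError")
    }
    seg <- featureSegmentLengths(model@flank)
    if (ncol(X) != sum(seg))
        mqvStop(sprintf("feature width %d does not match model flank %d",
                        ncol(X), model@flank), "layoutError")
    if (nrow(X) != length(loci))
        mqvStop("features and loci differ in length", "alignmentError")
    cols <- segmentIndices(seg, model@featureMask)
    yprime <- predict(model@booster, xgb.DMatrix(X[, cols, drop = FALSE],
                                                 nthread = 1L))
    level <- inverseTransform(yprime)
    depth <- if (!is.null(mcols(loci)$depth)) mcols(loci)$depth else 0L
    methylationRecords(as.character(seqnames(loci)), start(loci) - 1L,
                       as.character(strand(loci)), level, depth = depth)
}

#' Average the two strands of each CpG site
#'
#' CpG methylation is symmetric: the forward-strand cytosine at position
#' `i` and the reverse-strand cytosine at `i + 1` report the same site.
#' Pairs matching this geometry are merged into a single record at the
#' forward-strand coordinate with the mean of the two levels and the sum
#' of the two depths; records without a partner pass through unchanged.
#'
#' @param records a `GRanges` of per-strand methylation records.
#' @return a `GRanges` of site-level records.
#' @export
averageStrands <- function(records) {
    if (length(records) == 0L) return(records)
    chrom <- as.character(seqnames(records))
    pos <- start(records)
    str <- as.character(strand(records))
    fwd <- which(str == "+")
    rev <- which(str == "-")
    key <- function(ch, p) paste(ch, p, sep = ":")
    revmap <- structure(rev, names = key(chrom[rev], pos[rev]))
    partner <- revmap[key(chrom[fwd], pos[fwd] + 1L)]
    paired_f <- fwd[!is.na(partner)]
    paired_r <- unname(partner[!is.na(partner)])
    lone <- setdiff(seq_along(records), c(paired_f, paired_r))
    lv <- mcols(records)$level
    dp <- mcols(records)$depth
    out <- c(
        methylationRecords(chrom[paired_f], pos[paired_f] - 1L,
                           rep("+", length(paired_f)),
                           (lv[paired_f] + lv[paired_r]) / 2,
                           depth = dp[paired_f] + dp[paired_r]),
        records[lone]
    )
    sort(out, ignore.strand = TRUE)
}

#' Save a trained model to a directory
#'
#' Persists the booster as a portable JSON dump (`model.json`) and the
#' metadata (layout version, flank, transform, hyperparameters, feature
#' mask, provenance) as a sidecar (`meta.json`).
#'
#' @param model a [MethylModel-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
saveModel <- function(model, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    xgb.save(model@booster, file.path(dir, "model.json"))
    meta <- list(layout_version = model@layoutVersion,
                 flank = model@flank,
                 transform = model@transform,
                 hyperparams = model@hyperparams,
                 feature_mask = as.list(model@featureMask),
                 provenance = model@provenance)
    write_json(meta, file.path(dir, "meta.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(dir)
}

#' Load a trained model from a directory written by [saveModel()]
#'
#' @param dir model directory containing `model.json` and `meta.json`.
#' @return a [MethylModel-class].
#' @export
loadModel <- function(dir) {
    meta <- read_json(file.path(dir, "meta.json"))
    booster <- xgb.load(file.path(dir, "model.json"))
    new("MethylModel", booster = booster,
        layoutVersion = meta$layout_version,
        flank = as.integer(meta$flank),
        transform = list(alpha = meta$transform$alpha,
                         mode = meta$transform$mode),
        hyperparams = lapply(meta$hyperparams, function(x)
            if (is.numeric(x) && x == round(x)) as.integer(x) else x),
        featureMask = unlist(meta$feature_mask),
        provenance = meta$provenance)
}
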