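#' @import methods
#' @importFrom S4Vectors isSingleNumber isSingleString
NULL

BASE_ALPHABET <- c("A", "C", "G", "T")
READ_ALPHABET <- c("A", "C", "G", "T", "D")

#' WindowPileup: rectangular read stack over a candidate-site window
#'
#' Holds the aligned bases and basecall quality values (QVs) of all reads
#' that fully cover the `2*flank + 1` reference positions centred on a
#' candidate cytosine. Rows are reads, columns are window positions ordered
#' from `-flank` to `+flank` relative to the centre. Deleted positions carry
#' the base symbol `"D"` and the configured placeholder QV.
#'
#' @slot Q numeric matrix, `n x (2*flank+1)`, Phred-scaled QVs.
#' @slot R character matrix, same shape, bases over `{A,C,G,T,D}`.
#' @slot context character vector of length `2*flank+1`: the reference
#'   bases of the window (upper case, `{A,C,G,T}` only).
#' @slot chrom single string, contig name.
#' @slot center integer, 0-based reference position of the candidate base.
#' @slot strand `"+"` or `"-"`, strand of the candidate cytosine.
#' @slot flank integer, window half-width (21-position window when 10).
#'
#' @seealso [collectWindowReads()], [windowMoments()], [jointErrorRates()]
#' @export
setClass("WindowPileup",
    representation(
        Q = "matrix",
        R = "matrix",
        context = "character",
        chrom = "character",
        center = "integer",
        strand = "character",
        flank = "integer"
    )
)

setValidity("WindowPileup", function(object) {
    msg <- character()
    w <- 2L * object@flank + 1L
    if (!identical(dim(object@Q), dim(object@R)))
        msg <- c(msg, "Q and R must have identical dimensions")
    if (ncol(object@Q) != w)
        msg <- c(msg, sprintf("Q must have %d columns (2*flank+1)", w))
    if (length(object@context) != w)
        msg <- c(msg, sprintf("context must have length %d", w))
    if (!all(object@context %in% BASE_ALPHABET))
        msg <- c(msg, "context bases must be in {A,C,G,T}")
    if (nrow(object@R) > 0L && !all(object@R %in% READ_ALPHABET))
        msg <- c(msg, "read bases must be in {A,C,G,T,D}")
    if (nrow(object@Q) > 0L && any(object@Q < 0))
        msg <- c(msg, "QVs must be non-negative")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' WindowMoments: high-order QV moment features of one window
#'
#' The four moment families computed from the QV matrix of a
#' [WindowPileup-class]: per-position mean, covariance, coskewness and
#' cokurtosis across reads, plus the per-position spread used to
#' standardize the third and fourth moments.
#'
#' @slot mean numeric vector, length `2*flank+1`.
#' @slot cov numeric matrix (symmetric), sample covariance (divisor n-1).
#' @slot coskew numeric matrix; not symmetric in general.
#' @slot cokurt numeric matrix (symmetric, non-negative entries).
#' @slot sd numeric vector, per-position standard deviation used for
#'   standardization (population divisor by default).
#'
#' @seealso [windowMoments()]
#' @export
setClass("WindowMoments",
    representation(
        mean = "numeric",
        cov = "matrix",
        coskew = "matrix",
        cokurt = "matrix",
        sd = "numeric"
    )
)

setValidity("WindowMoments", function(object) {
    w <- length(object@mean)
    ok <- identical(dim(object@cov), c(w, w)) &&
        identical(dim(object@coskew), c(w, w)) &&
        identical(dim(object@cokurt), c(w, w)) &&
        length(object@sd) == w
    if (!ok) return("moment shapes inconsistent with window width")
    TRUE
})

#' ErrorTensor: pairwise joint sequencing-error rates of one window
#'
#' Four-dimensional array `E[s, t, p, q]` giving the fraction of reads that
#' simultaneously carry non-reference symbol `s` at window position `p` and
#' non-reference symbol `t` at position `q`. Symbols run over the ordered
#' alphabet (A, C, G, T, D) where D is a deletion; positions run over the
#' window. Entries with `s` equal to the reference base at `p` (or `t` at
#' `q`) are structurally zero.
#'
#' @slot E numeric 4-d array, `5 x 5 x (2*flank+1) x (2*flank+1)`.
#' @slot context character vector, the reference bases defining the
#'   structural zeros.
#'
#' @seealso [jointErrorRates()]
#' @export
setClass("ErrorTensor",
    representation(E = "array", context = "character")
)

setValidity("ErrorTensor", function(object) {
    d <- dim(object@E)
    w <- length(object@context)
    if (length(d) != 4L || d[1] != 5L || d[2] != 5L || d[3] != w || d[4] != w)
        return("E must be a 5 x 5 x width x width array matching context")
    if (any(object@E < 0) || any(object@E > 1))
        return("entries must lie in [0, 1]")
    TRUE
})

#' FeatureVector: fixed-layout flattening of the window features
#'
#' Concatenation, in a fixed segment order, of the moment features, the
#' error tensor and the binary context code of one window. The layout
#' (segment order, row-major flattening, total length) is identified by
#' `layoutVersion`; models refuse feature vectors built under a different
#' layout.
#'
#' @slot values numeric vector (length 12411 for the default flank of 10).
#' @slot layoutVersion single string identifying the flattening scheme.
#' @slot segments named integer vector of segment lengths, in layout order.
#'
#' @seealso [assembleFeatureVector()], [extractFeatures()]
#' @export
setClass("FeatureVector",
    representation(
        values = "numeric",
        layoutVersion = "character",
        segments = "integer"
    )
)

setValidity("FeatureVector", function(object) {
    if (length(object@values) != sum(object@segments))
        return("length(values) must equal sum(segments)")
    if (is.null(names(object@segments)))
        return("segments must be named")
    TRUE
})

#' MethylModel: trained boosted-tree methylation regressor
#'
#' A gradient-boosted tree ensemble mapping window feature vectors to
#' logit-transformed methylation levels, together with the metadata needed
#' to apply it safely: the feature layout it was trained on, the window
#' half-width, the label transform, the boosting hyperparameters and a
#' free-text provenance tag (e.g. basecaller/flowcell of the training
#' labels).
#'
#' @slot booster an `xgb.Booster`.
#' @slot layoutVersion feature-layout identifier (must match at prediction).
#' @slot flank window half-width the features were computed with.
#' @slot transform list with elements `alpha` and `mode` describing the
#'   label transform (see [logitTransform()]).
#' @slot hyperparams list with `eta`, `num_round`, `max_depth`, `seed`.
#' @slot featureMask character vector of segment names the model uses
#'   (all segments when unmasked).
#' @slot provenance free-text tag.
#'
#' @seealso [trainModel()], [predictLoci()], [saveModel()], [loadModel()]
#' @export
setClass("MethylModel",
    representation(
        booster = "ANY",
        layoutVersion = "character",
        flank = "integer",
        transform = "list",
        hyperparams = "list",
        featureMask = "character",
        provenance = "character"
    )
)
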