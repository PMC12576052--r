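#' @importFrom stats cov sd median var
NULL

## Layout identifier: bump whenever the segment order, flattening or
## encoding changes, so stale models refuse fresh features.
FEATURE_LAYOUT_VERSION <- "mqv-moments-error-context/1"

featureSegmentLengths <- function(flank = 10L) {
    w <- 2L * flank + 1L
    c(mean = w, cov = w * w, coskew = w * w, cokurt = w * w,
      error = 25L * w * w, context = 2L * w)
}

checkDepth <- function(pileup, min) {
    n <- nrow(pileup@Q)
    if (n == 0L)
        mqvStop("empty pileup: no reads fully cover the window",
                "emptyPileup")
    if (n < min)
        mqvStop(sprintf("pileup has %d reads; at least %d required", n, min),
                "insufficientDepth")
    n
}

#' Per-position mean quality value
#'
#' First-moment feature: the mean QV of each window position across the
#' `n` reads of the pileup, `M_i = (1/n) * sum_j Q_ij`.
#'
#' @param pileup a [WindowPileup-class].
#' @return numeric vector of length `2*flank + 1`.
#' @export
meanQV <- function(pileup) {
    checkDepth(pileup, 1L)
    colMeans(pileup@Q)
}

#' QV covariance matrix
#'
#' Second-moment feature: the sample covariance (divisor `n - 1`) between
#' the QVs of every pair of window positions,
#' `V_pq = 1/(n-1) * sum_j (Q_pj - M_p)(Q_qj - M_q)`.
#'
#' @param pileup a [WindowPileup-class] with at least 2 reads.
#' @return symmetric numeric matrix, `(2*flank+1)` square.
#' @export
qvCovariance <- function(pileup) {
    checkDepth(pileup, 2L)
    stats::cov(pileup@Q)
}

## Population (ddof = 0) or sample (ddof = 1) per-position sd. The
## standardization of the third and fourth moments divides by powers of
## this; positions with zero spread yield zero rows/columns rather than
## NaN so feature vectors stay finite.
positionSd <- function(Q, ddof = 0L) {
    n <- nrow(Q)
    ctr <- sweep(Q, 2L, colMeans(Q))
    sqrt(colSums(ctr^2) / (n - ddof))
}

#' QV coskewness matrix
#'
#' Third-moment feature,
#' `S_pq = sum_j (Q_pj - M_p)^2 (Q_qj - M_q) / (n * sd_p^2 * sd_q)`.
#' Not symmetric in general (position `p` enters squared, `q` linearly).
#' Entries whose `sd_p` or `sd_q` is zero are set to 0.
#'
#' @param pileup a [WindowPileup-class] with at least 2 reads.
#' @param sigmaDdof degrees-of-freedom correction for the standardizing
#'   spread: 0 (population, default) or 1 (sample).
#' @return numeric matrix, `(2*flank+1)` square.
#' @export
qvCoskewness <- function(pileup, sigmaDdof = 0L) {
    n <- checkDepth(pileup, 2L)
    ctr <- sweep(pileup@Q, 2L, colMeans(pileup@Q))
    s <- positionSd(pileup@Q, sigmaDdof)
    S <- crossprod(ctr^2, ctr) / n
    denom <- outer(s^2, s)
    out <- ifelse(denom > 0, S / ifelse(denom > 0, denom, 1), 0)
    out
}

#' QV cokurtosis matrix
#'
#' Fourth-moment feature,
#' `K_pq = sum_j (Q_pj - M_p)^2 (Q_qj - M_q)^2 / (n * sd_p^2 * sd_q^2)`.
#' Symmetric with non-negative entries; zero-spread rows/columns are set
#' to 0.
#'
#' @inheritParams qvCoskewness
#' @return symmetric numeric matrix, `(2*flank+1)` square.
#' @export
qvCokurtosis <- function(pileup, sigmaDdof = 0L) {
    n <- checkDepth(pileup, 2L)
    ctr2 <- sweep(pileup@Q, 2L, colMeans(pileup@Q))^2
    s <- positionSd(pileup@Q, sigmaDdof)
    K <- crossprod(ctr2, ctr2) / n
    denom <- outer(s^2, s^2)
    ifelse(denom > 0, K / ifelse(denom > 0, denom, 1), 0)
}

#' All QV moment features of a window
#'
#' Convenience wrapper computing the mean, covariance, coskewness and
#' cokurtosis features in one pass.
#'
#' @inheritParams qvCoskewness
#' @return a [WindowMoments-class].
#' @export
windowMoments <- function(pileup, sigmaDdof = 0L) {
    new("WindowMoments",
        mean = meanQV(pileup),
        cov = qvCovariance(pileup),
        coskew = qvCoskewness(pileup, sigmaDdof),
        cokurt = qvCokurtosis(pileup, sigmaDdof),
        sd = positionSd(pileup@Q, sigmaDdof))
}

#' Pairwise joint sequencing-error rate tensor
#'
#' For every ordered pair of window positions `(p, q)` and symbols
#' `(s, t)` over (A, C, G, T, D), the fraction of reads carrying
#' non-reference symbol `s` at `p` and non-reference symbol `t` at `q`:
#' `E_stpq = (1/n) * sum_j I(R_pj = s) I(R_qj = t) I(T_p != s) I(T_q != t)`.
#' The two indicator pairs make entries with `s = T_p` or `t = T_q`
#' structurally zero, and the tensor satisfies `E[s,t,p,q] = E[t,s,q,p]`.
#'
#' @param pileup a [WindowPileup-class] with a valid reference context.
#' @return an [ErrorTensor-class].
#' @export
jointErrorRates <- function(pileup) {
    n <- checkDepth(pileup, 1L)
    w <- ncol(pileup@R)
    E <- array(0, dim = c(5L, 5L, w, w))
    Ridx <- matrix(match(pileup@R, READ_ALPHABET), nrow = n)
    Tidx <- match(pileup@context, READ_ALPHABET)
    for (j in seq_len(n)) {
        errAt <- which(Ridx[j, ] != Tidx)        # error positions of read j
        if (length(errAt) == 0L) next
        sym <- Ridx[j, errAt]
        ii <- cbind(
            s = rep(sym, times = length(errAt)),
            t = rep(sym, each = length(errAt)),
            p = rep(errAt, times = length(errAt)),
            q = rep(errAt, each = length(errAt))
        )
        E[ii] <- E[ii] + 1
    }
    new("ErrorTensor", E = E / n, context = pileup@context)
}

#' Binary encoding of the window's reference context
#'
#' Two bits per reference base, high bit first (A = 00, C = 01, G = 10,
#' T = 11), concatenated in window order from `-flank` to `+flank`:
#' 42 bits for the default 21-base window.
#'
#' @param context character vector of reference bases.
#' @return integer vector of 0/1 values, length `2 * length(context)`.
#' @export
encodeContext <- function(context) {
    code <- match(context, BASE_ALPHABET) - 1L
    if (anyNA(code))
        mqvStop("context contains a base outside {A,C,G,T}",
                "contextUnencodable")
    as.integer(rbind(code %/% 2L, code %% 2L))
}

## Row-major flattening: within a matrix, q varies fastest; within the
## error tensor the order is s (slowest), t, p, q (fastest).
flattenRowMajor <- function(M) as.vector(t(M))

flattenTensor <- function(E) as.vector(aperm(E, c(4L, 3L, 2L, 1L)))

#' Assemble the fixed-layout feature vector of one window
#'
#' Concatenates the feature families in the fixed order mean, cov,
#' coskew, cokurt, error, context with row-major flattening of matrices
#' (and s, t, p, q slow-to-fast ordering of the error tensor). For the
#' default flank of 10 the total length is
#' 21 + 441 + 441 + 441 + 11025 + 42 = 12411.
#'
#' @param moments a [WindowMoments-class].
#' @param tensor an [ErrorTensor-class].
#' @param contextBits integer 0/1 vector from [encodeContext()].
#' @return a [FeatureVector-class].
#' @export
assembleFeatureVector <- function(moments, tensor, contextBits) {
    w <- length(moments@mean)
    flank <- (w - 1L) %/% 2L
    seg <- featureSegmentLengths(flank)
    d <- dim(tensor@E)
    if (d[3] != w || d[4] != w || length(contextBits) != seg[["context"]])
        mqvStop("feature shapes do not match a common window width",
                "layoutError")
    vals <- c(moments@mean,
              flattenRowMajor(moments@cov),
              flattenRowMajor(moments@coskew),
              flattenRowMajor(moments@cokurt),
              flattenTensor(tensor@E),
              as.numeric(contextBits))
    new("FeatureVector", values = unname(vals),
        layoutVersion = FEATURE_LAYOUT_VERSION, segments = seg)
}

#' Extract the full feature vector of a window pileup
#'
#' One-call wrapper: moments + error tensor + context encoding,
#' assembled in the fixed layout.
#'
#' @inheritParams qvCoskewness
#' @return a [FeatureVector-class].
#' @export
extractFeatures <- function(pileup, sigmaDdof = 0L) {
    assembleFeatureVector(windowMoments(pileup, sigmaDdof),
                          jointErrorRates(pileup),
                          encodeContext(pileup@context))
}

#' Column indices of a feature segment
#'
#' Maps segment names (`"mean"`, `"cov"`, `"coskew"`, `"cokurt"`,
#' `"error"`, `"context"`) to their 1-based column spans in the assembled
#' feature vector; used for feature-subset (ablation) training.
#'
#' @param segments named integer vector of segment lengths (as stored in
#'   a [FeatureVector-class]).
#' @param names character vector of segment names to select.
#' @return integer vector of column indices.
#' @export
segmentIndices <- function(segments, names) {
    bad <- setdiff(names, names(segments))
    if (length(bad))
        mqvStop(sprintf("unknown feature segment(s): %s",
                        paste(bad, collapse = ", ")), "layoutError")
    ends <- cumsum(segments)
    starts <- ends - segments + 1L
    unlist(lapply(names, function(nm)
        seq.int(starts[[nm]], ends[[nm]])), use.names = FALSE)
}
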