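#' @rdname WindowPileup-class
#' @param object,x a `WindowPileup` (or other class as documented).
#' @export
setGeneric("readCount", function(x) standardGeneric("readCount"))

#' @rdname WindowPileup-class
#' @export
setGeneric("windowWidth", function(x) standardGeneric("windowWidth"))

#' @rdname WindowPileup-class
#' @export
setGeneric("qvMatrix", function(x) standardGeneric("qvMatrix"))

#' @rdname WindowPileup-class
#' @export
setGeneric("baseMatrix", function(x) standardGeneric("baseMatrix"))

#' @rdname WindowPileup-class
#' @export
setGeneric("refContext", function(x) standardGeneric("refContext"))

#' @rdname FeatureVector-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureVector-class
#' @export
setGeneric("layoutVersion", function(x) standardGeneric("layoutVersion"))

#' @rdname FeatureVector-class
#' @export
setGeneric("featureSegments", function(x) standardGeneric("featureSegments"))

setMethod("readCount", "WindowPileup", function(x) nrow(x@Q))
setMethod("windowWidth", "WindowPileup", function(x) 2L * x@flank + 1L)
setMethod("qvMatrix", "WindowPileup", function(x) x@Q)
setMethod("baseMatrix", "WindowPileup", function(x) x@R)
setMethod("refContext", "WindowPileup", function(x) x@context)

setMethod("featureValues", "FeatureVector", function(x) x@values)
setMethod("layoutVersion", "FeatureVector", function(x) x@layoutVersion)
setMethod("layoutVersion", "MethylModel", function(x) x@layoutVersion)
setMethod("featureSegments", "FeatureVector", function(x) x@segments)

setMethod("show", "WindowPileup", function(object) {
    cat(sprintf(
        "WindowPileup at %s:%d (%s): %d reads x %d positions (flank %d)\n",
        object@chrom, object@center, object@strand,
        nrow(object@Q), ncol(object@Q), object@flank
    ))
    invisible(NULL)
})

setMethod("show", "WindowMoments", function(object) {
    w <- length(object@mean)
    cat(sprintf(
        "WindowMoments over %d positions (mean QV %.2f-%.2f)\n",
        w, min(object@mean), max(object@mean)
    ))
    invisible(NULL)
})

setMethod("show", "ErrorTensor", function(object) {
    d <- dim(object@E)
    cat(sprintf(
        "ErrorTensor %dx%dx%dx%d, total error mass %.4f\n",
        d[1], d[2], d[3], d[4], sum(object@E)
    ))
    invisible(NULL)
})

setMethod("show", "FeatureVector", function(object) {
    cat(sprintf(
        "FeatureVector of length %d (layout %s)\n  segments: %s\n",
        length(object@values), object@layoutVersion,
        paste(sprintf("%s(%d)", names(object@segments), object@segments),
              collapse = " ")
    ))
    invisible(NULL)
})

setMethod("show", "MethylModel", function(object) {
    cat(sprintf(
        paste0("MethylModel (layout %s, flank %d)\n",
               "  transform: %s (alpha %g)\n",
               "  boosting: eta %g, %d rounds, max depth %d\n",
               "  features: %s\n  provenance: %s\n"),
        object@layoutVersion, object@flank,
        object@transform$mode, object@transform$alpha,
        object@hyperparams$eta, object@hyperparams$num_round,
        object@hyperparams$max_depth,
        paste(object@featureMask, collapse = ","),
        object@provenance
    ))
    invisible(NULL)
})
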