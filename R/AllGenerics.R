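#' @name accessors
#' @title Accessors for weighted-ensemble objects
#'
#' @description Small accessor generics used across the package instead of
#' direct slot access.
#'
#' @param object,x An object of the documented class.
#' @param ... Unused.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("states", function(x, ...) standardGeneric("states"))

#' @rdname accessors
#' @export
setMethod("states", "WalkerEnsemble", function(x, ...) x@states)

#' @rdname accessors
#' @export
setGeneric("cycleIndex", function(x, ...) standardGeneric("cycleIndex"))

#' @rdname accessors
#' @export
setMethod("cycleIndex", "WalkerEnsemble", function(x, ...) x@cycleIndex)

#' @rdname accessors
#' @export
setMethod("cycleIndex", "ResamplingRecord", function(x, ...) x@cycleIndex)

#' @rdname accessors
#' @export
setGeneric("nWalkers", function(x, ...) standardGeneric("nWalkers"))

#' @rdname accessors
#' @export
setMethod("nWalkers", "WalkerEnsemble", function(x, ...) length(x@states))

#' @rdname accessors
#' @importFrom stats weights
#' @export
setMethod("weights", "WalkerEnsemble", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("weights", "Walker", function(object, ...) object@weight)

#' @rdname accessors
#' @export
setMethod("states", "Walker", function(x, ...) x@state)

#' @rdname accessors
#' @export
setGeneric("operations", function(x, ...) standardGeneric("operations"))

#' @rdname accessors
#' @export
setMethod("operations", "ResamplingRecord", function(x, ...) x@operations)

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x, ...) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setMethod("nRegions", "RegionHierarchy",
          function(x, ...) length(x@images))

#' @rdname accessors
#' @export
setGeneric("nLevels", function(x, ...) standardGeneric("nLevels"))

#' @rdname accessors
#' @export
setMethod("nLevels", "RegionHierarchy",
          function(x, ...) length(x@thresholds))

#' @rdname accessors
#' @export
setGeneric("profileTable", function(x, ...) standardGeneric("profileTable"))

#' @rdname accessors
#' @export
setMethod("profileTable", "ProbabilityProfile", function(x, ...) x@profile)

#' @rdname accessors
#' @export
setGeneric("warpEvents", function(x, ...) standardGeneric("warpEvents"))

#' @rdname accessors
#' @export
setMethod("warpEvents", "RunRecord", function(x, ...) x@warps)

#' @rdname accessors
#' @export
setGeneric("runConfigOf", function(x, ...) standardGeneric("runConfigOf"))

#' @rdname accessors
#' @export
setMethod("runConfigOf", "RunRecord", function(x, ...) x@config)

setMethod("show", "Walker", function(object) {
    cat("Walker of weight", format(object@weight), "\n")
})

setMethod("show", "WalkerEnsemble", function(object) {
    cat(sprintf("WalkerEnsemble: %d walkers at cycle %d\n",
                nWalkers(object), cycleIndex(object)))
    w <- weights(object)
    if (length(w))
        cat(sprintf("  weights: min %.3g / max %.3g / sum %.15g\n",
                    min(w), max(w), sum(w)))
})

setMethod("show", "ResamplingRecord", function(object) {
    ops <- object@operations
    cat(sprintf("ResamplingRecord (cycle %d): %d clones, %d merges\n",
                object@cycleIndex, sum(ops$op == "clone"),
                sum(ops$op == "merge")))
})

setMethod("show", "REVOParams", function(object) {
    cat(sprintf(
        "REVOParams: alpha=%g d0=%s pMin=%g pMax=%g mergeDistance=%g (%s)\n",
        object@alpha, ifelse(is.na(object@d0), "<estimate>",
                             format(object@d0)),
        object@pMin, object@pMax, object@mergeDistance, object@noveltyMode))
})

setMethod("show", "RegionHierarchy", function(object) {
    cat(sprintf(
        "RegionHierarchy: %d levels (thresholds %s), %d nodes, <=%d children\n",
        nLevels(object), paste(object@thresholds, collapse = "/"),
        nRegions(object), object@maxChildren))
})

setMethod("show", "RunRecord", function(object) {
    cfg <- object@config
    cat(sprintf("RunRecord: %s resampler, %d walkers, %d cycles, N=%d\n",
                cfg$resampler, cfg$nWalkers, length(object@positions),
                cfg$system$nDims))
    if (nrow(object@warps))
        cat(sprintf("  %d warp events, total warped weight %.3g\n",
                    nrow(object@warps), sum(object@warps$weight)))
})

setMethod("show", "ProbabilityProfile", function(object) {
    cat(sprintf(
        "ProbabilityProfile: %d positions, %d run(s), N=%s\n",
        nrow(object@profile), object@metadata$nRuns,
        format(object@metadata$nDims)))
})
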