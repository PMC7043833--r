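#' @import methods
#' @importFrom stats runif rnorm sd setNames
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))

#' Walker: a conformation with a statistical weight
#'
#' The atom of weighted-ensemble sampling: an opaque system state (for the
#' random-walk benchmark, a non-negative integer vector) carrying a
#' statistical weight in (0, 1].
#'
#' @slot state Opaque conformation; interpretation is system-specific.
#' @slot weight Statistical weight, a probability mass in (0, 1].
#'
#' @seealso [cloneWalker()], [mergeWalkers()], [WalkerEnsemble]
#' @export
setClass("Walker", representation(state = "ANY", weight = "numeric"))

setValidity("Walker", function(object) {
    if (length(object@weight) != 1L || !is.finite(object@weight))
        return("'weight' must be a single finite number")
    if (object@weight <= 0 || object@weight > 1)
        return("'weight' must be in (0, 1]")
    TRUE
})

#' An ordered ensemble of walkers
#'
#' Holds the ordered walker set operated on by the resamplers. Walkers are
#' addressed by position; all resampling records refer to these indices.
#' Total weight must be 1 (within 1e-12) and is never silently renormalized:
#' a violation is a correctness signal and raises at validity checking.
#'
#' @slot states List of conformations, one per walker.
#' @slot weights Numeric vector of statistical weights summing to 1.
#' @slot cycleIndex Non-negative integer, the cycle this snapshot belongs to.
#'
#' @seealso [walkerEnsemble()], [runCycle()]
#' @export
setClass("WalkerEnsemble", representation(
    states = "list", weights = "numeric", cycleIndex = "integer"))

setValidity("WalkerEnsemble", function(object) {
    n <- length(object@states)
    if (length(object@weights) != n)
        return("'states' and 'weights' must have equal length")
    if (n > 0 && any(object@weights <= 0 | object@weights > 1))
        return("all weights must be in (0, 1]")
    if (n > 0 && abs(sum(object@weights) - 1) >= 1e-12)
        return(sprintf("weights must sum to 1 (got %.17g)",
                       sum(object@weights)))
    if (length(object@cycleIndex) != 1L || object@cycleIndex < 0L)
        return("'cycleIndex' must be a single non-negative integer")
    TRUE
})

#' Per-cycle log of clone/merge operations
#'
#' An audit trail of one resampling call. Replaying the operations on the
#' pre-resampling ensemble reproduces the post-resampling ensemble exactly
#' (see [replayRecord()]). Operations are stored as a data frame with
#' columns \code{op} ("merge" or "clone"), \code{src1}, \code{src2},
#' \code{tgt1}, \code{tgt2}, \code{kept} (slot whose conformation survives a
#' merge) and \code{wNew1}, \code{wNew2} (weights after the operation).
#' An empty data frame means every walker was kept unchanged.
#'
#' @slot cycleIndex Cycle the record belongs to.
#' @slot operations Data frame of operations, applied in row order.
#'
#' @seealso [replayRecord()]
#' @export
setClass("ResamplingRecord", representation(
    cycleIndex = "integer", operations = "data.frame"))

setValidity("ResamplingRecord", function(object) {
    need <- c("op", "src1", "src2", "tgt1", "tgt2", "kept", "wNew1", "wNew2")
    if (nrow(object@operations) > 0 &&
        !all(need %in% names(object@operations)))
        return(paste("operations must have columns:",
                     paste(need, collapse = ", ")))
    TRUE
})

#' Boundary condition with warping
#'
#' A predicate on walker states together with the reset state. A walker
#' whose state satisfies the predicate after dynamics is "warped": its state
#' is set back to \code{warpState} while its (unchanged) weight is logged as
#' reactive flux. The warp state itself must not satisfy the predicate.
#'
#' @slot predicate Function of one state returning TRUE/FALSE.
#' @slot warpState The state walkers are reset to.
#'
#' @seealso [applyBoundary()], [fluxAndResidence()]
#' @export
setClass("BoundaryCondition", representation(
    predicate = "function", warpState = "ANY"))

setValidity("BoundaryCondition", function(object) {
    hit <- isTRUE(object@predicate(object@warpState))
    if (hit) return("'warpState' must not itself satisfy 'predicate'")
    TRUE
})

#' Parameters of the REVO resampler
#'
#' @slot alpha Distance exponent of the variation function (unitless,
#'   >= 0); larger values emphasize large pairwise distances.
#' @slot d0 Characteristic distance making the variation unit-free, in the
#'   units of the system's distance metric; \code{NA} means "estimate from
#'   one dynamics cycle" (see [estimateD0()]).
#' @slot pMin Minimum walker weight; walkers are never cloned if a child
#'   would fall below it.
#' @slot pMax Maximum walker weight; merges may not create a heavier walker.
#' @slot mergeDistance Maximum pairwise distance at which two walkers may be
#'   merged, limiting information loss.
#' @slot noveltyMode "weight_based" (logarithmic weight novelty) or
#'   "constant" (novelty 1 for every walker).
#'
#' @seealso [revoParams()], [calcVariation()], [revoResample()]
#' @export
setClass("REVOParams", representation(
    alpha = "numeric", d0 = "numeric", pMin = "numeric", pMax = "numeric",
    mergeDistance = "numeric", noveltyMode = "character"))

setValidity("REVOParams", function(object) {
    if (object@alpha < 0) return("'alpha' must be >= 0")
    if (!is.na(object@d0) && object@d0 <= 0) return("'d0' must be > 0")
    if (!(object@pMin > 0 && object@pMin < object@pMax && object@pMax <= 1))
        return("need 0 < pMin < pMax <= 1")
    if (object@mergeDistance <= 0) return("'mergeDistance' must be > 0")
    if (!object@noveltyMode %in% c("weight_based", "constant"))
        return("'noveltyMode' must be 'weight_based' or 'constant'")
    TRUE
})

#' Parameters of the N-dimensional biased random walk
#'
#' @slot nDims Number of dimensions N (>= 1).
#' @slot pUp Forward-step probability per dimension per step (default 0.25;
#'   the walk is biased back toward the origin).
#' @slot stepsPerCycle Dynamics steps per WE cycle (default 10).
#'
#' @seealso [rwParams()], [rwStep()], [rwTargetProb()]
#' @export
setClass("RWParams", representation(
    nDims = "integer", pUp = "numeric", stepsPerCycle = "integer"))

setValidity("RWParams", function(object) {
    if (object@nDims < 1L) return("'nDims' must be >= 1")
    if (!(object@pUp > 0 && object@pUp < 1))
        return("'pUp' must be in (0, 1)")
    if (object@stepsPerCycle < 1L) return("'stepsPerCycle' must be >= 1")
    TRUE
})

#' Hierarchy of Voronoi regions for WExplore
#'
#' A leveled tree of Voronoi "images" (stored conformations). The top level
#' uses the coarsest (largest) distance threshold; thresholds strictly
#' decrease down the hierarchy. Nodes are stored in creation order and are
#' immutable once created: images never move or disappear. Each parent may
#' hold at most \code{maxChildren} children.
#'
#' Internally the tree is flat: \code{parent[i]} is the node id of node i's
#' parent (0 for top-level nodes), \code{level[i]} its depth (1 = top) and
#' \code{images[[i]]} its image conformation.
#'
#' @slot thresholds Numeric vector of per-level distance thresholds,
#'   strictly decreasing, length = number of levels.
#' @slot maxChildren Maximum child regions per parent node.
#' @slot parent Integer vector of parent node ids (0 = virtual root).
#' @slot level Integer vector of node depths, 1-based.
#' @slot images List of image conformations.
#'
#' @seealso [regionHierarchy()], [assignWalker()], [updateRegions()]
#' @export
setClass("RegionHierarchy", representation(
    thresholds = "numeric", maxChildren = "integer",
    parent = "integer", level = "integer", images = "list"))

setValidity("RegionHierarchy", function(object) {
    L <- length(object@thresholds)
    if (L < 1L) return("need at least one level")
    if (L > 1L && any(diff(object@thresholds) >= 0))
        return("'thresholds' must be strictly decreasing (coarsest first)")
    if (object@maxChildren < 1L) return("'maxChildren' must be >= 1")
    n <- length(object@parent)
    if (length(object@level) != n || length(object@images) != n)
        return("'parent', 'level' and 'images' must have equal length")
    if (n > 0 && any(object@level < 1L | object@level > L))
        return("node levels out of range")
    TRUE
})

#' A self-contained record of one weighted-ensemble run
#'
#' Everything needed for post-hoc analysis: the configuration snapshot,
#' per-cycle walker positions and weights (post-resampling), the per-cycle
#' resampling records, warp events, the per-cycle per-dimension maximum
#' position visited (post-dynamics, i.e. before any warping), and resampler
#' traces (total variation for REVO, region counts for WExplore).
#'
#' @slot config Configuration list (see [runConfig()]).
#' @slot positions List of integer matrices (walkers x dimensions), one per
#'   cycle, taken after resampling.
#' @slot weights List of numeric weight vectors, one per cycle.
#' @slot maxVisited Numeric matrix (cycles x dimensions): per-cycle maximum
#'   position reached in each dimension during dynamics.
#' @slot resampling List of [ResamplingRecord] objects, one per cycle.
#' @slot warps Data frame of warp events: cycle, walker, weight.
#' @slot vTrace Numeric per-cycle total variation (REVO; NA otherwise).
#' @slot regionCounts Integer per-cycle region count (WExplore; NA
#'   otherwise).
#' @slot d0 Characteristic distance used (NA unless REVO).
#' @slot hierarchy Final [RegionHierarchy] (WExplore) or NULL.
#'
#' @seealso [runSimulation()], [writeRunRecord()], [readRunRecord()]
#' @export
setClass("RunRecord", representation(
    config = "list", positions = "list", weights = "list",
    maxVisited = "matrix", resampling = "list", warps = "data.frame",
    vTrace = "numeric", regionCounts = "integer", d0 = "numeric",
    hierarchy = "ANY"))

#' Averaged positional probability profile
#'
#' The estimated probability of finding sampled probability mass at each
#' integer position, averaged over dimensions, sampled cycles and runs, plus
#' the per-run profiles needed for run-to-run standard errors.
#'
#' @slot profile Data frame with columns \code{x} and \code{P}; P sums to 1.
#' @slot perRun Numeric matrix (positions x runs) of per-run profiles.
#' @slot metadata List: nDims, nRuns, cycles averaged, burn-in used.
#'
#' @seealso [predictedProbability()], [accuracy()], [runStandardError()]
#' @export
setClass("ProbabilityProfile", representation(
    profile = "data.frame", perRun = "matrix", metadata = "list"))

setValidity("ProbabilityProfile", function(object) {
    if (!all(c("x", "P") %in% names(object@profile)))
        return("'profile' must have columns 'x' and 'P'")
    if (any(object@profile$P < 0)) return("probabilities must be >= 0")
    if (abs(sum(object@profile$P) - 1) > 1e-9)
        return("profile must sum to 1 (within 1e-9)")
    TRUE
})
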