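## Generic weighted-ensemble machinery: walkers, clone/merge primitives,
## boundary-condition warping and the cycle loop. Resampler-agnostic.

#' Construct a Walker
#'
#' @param state Opaque conformation.
#' @param weight Statistical weight in (0, 1].
#' @return A [Walker-class] object.
#' @examples
#' walker(c(0L, 0L), 0.5)
#' @export
walker <- function(state, weight) {
    new("Walker", state = state, weight = as.numeric(weight))
}

#' Construct a WalkerEnsemble
#'
#' @param states List of conformations (or a matrix, rows = walkers).
#' @param weights Numeric weights summing to 1; default uniform.
#' @param cycleIndex Cycle index of the snapshot (default 0).
#' @return A [WalkerEnsemble-class] object.
#' @examples
#' walkerEnsemble(list(c(0L, 0L), c(1L, 2L)))
#' @export
walkerEnsemble <- function(states, weights = NULL, cycleIndex = 0L) {
    if (is.matrix(states))
        states <- lapply(seq_len(nrow(states)), function(i) states[i, ])
    if (is.null(weights))
        weights <- rep(1 / length(states), length(states))
    new("WalkerEnsemble", states = states, weights = as.numeric(weights),
        cycleIndex = as.integer(cycleIndex))
}

#' Construct a boundary condition
#'
#' @param predicate Function of a state returning TRUE when the walker has
#'   crossed the boundary (e.g. reached the unbound state).
#' @param warpState State to reset crossing walkers to (must not itself
#'   satisfy the predicate).
#' @return A [BoundaryCondition-class] object.
#' @export
boundaryCondition <- function(predicate, warpState) {
    new("BoundaryCondition", predicate = predicate, warpState = warpState)
}

#' Clone a walker
#'
#' Cloning replaces a walker by two independent walkers that share its
#' conformation and each carry exactly half of its weight, so the children's
#' weights sum to the parent weight bit-exactly. Eligibility rules (weight
#' floors) belong to the resamplers, not to this primitive.
#'
#' @param w A [Walker-class].
#' @return List of two [Walker-class] children.
#' @examples
#' ch <- cloneWalker(walker("s", 0.5))
#' weights(ch[[1]]) + weights(ch[[2]])  # 0.5
#' @export
cloneWalker <- function(w) {
    stopifnot(is(w, "Walker"), w@weight > 0)
    half <- w@weight / 2
    list(walker(w@state, half), walker(w@state, half))
}

#' Merge two walkers
#'
#' The merged walker carries the summed weight and inherits the conformation
#' of one parent, chosen with probability proportional to the parents'
#' weights. The draw consumes one uniform variate from the current RNG
#' stream.
#'
#' @param a,b [Walker-class] objects with combined weight <= 1.
#' @return List with elements \code{walker} (the merged [Walker-class]) and
#'   \code{kept} (1 if \code{a}'s conformation survived, 2 if \code{b}'s).
#' @examples
#' set.seed(1)
#' mergeWalkers(walker("A", 0.3), walker("B", 0.1))$walker
#' @export
mergeWalkers <- function(a, b) {
    stopifnot(is(a, "Walker"), is(b, "Walker"))
    wsum <- a@weight + b@weight
    if (wsum > 1)
        stop("invalid merge: combined weight ", format(wsum), " exceeds 1")
    kept <- if (runif(1) < a@weight / wsum) 1L else 2L
    st <- if (kept == 1L) a@state else b@state
    list(walker = walker(st, wsum), kept = kept)
}

#' Apply a boundary condition, warping crossing walkers
#'
#' Every walker whose state satisfies the predicate has its state replaced
#' by the warp state; its (unchanged) weight is logged as a warp event. Each
#' walker is checked once per call (a freshly warped walker is not
#' re-checked), and total weight is conserved exactly.
#'
#' @param ens A [WalkerEnsemble-class].
#' @param bc A [BoundaryCondition-class].
#' @return List with \code{ensemble} (possibly warped) and \code{warps}, a
#'   data frame with columns cycle, walker, weight (zero rows if nothing
#'   crossed).
#' @export
applyBoundary <- function(ens, bc) {
    stopifnot(is(ens, "WalkerEnsemble"), is(bc, "BoundaryCondition"))
    hit <- vapply(ens@states, function(s) isTRUE(bc@predicate(s)), logical(1))
    idx <- which(hit)
    if (length(idx)) {
        for (i in idx) ens@states[[i]] <- bc@warpState
    }
    warps <- data.frame(cycle = rep(ens@cycleIndex, length(idx)),
                        walker = idx, weight = ens@weights[idx])
    list(ensemble = ens, warps = warps)
}

## Apply one recorded operation row to (states, weights); used by both the
## resamplers' bookkeeping and replayRecord().
.applyOp <- function(states, weightsv, row) {
    if (row$op == "merge") {
        ## merged walker sits at the kept slot; the vacated slot is left for
        ## a subsequent clone row to overwrite
        weightsv[row$tgt1] <- row$wNew1
    } else if (row$op == "clone") {
        states[[row$tgt2]] <- states[[row$src1]]
        weightsv[row$tgt1] <- row$wNew1
        weightsv[row$tgt2] <- row$wNew2
    } else stop("unknown operation kind: ", row$op)
    list(states = states, weights = weightsv)
}

#' Replay a resampling record
#'
#' Applies the logged clone/merge operations, in order, to a pre-resampling
#' ensemble. By construction this reproduces the post-resampling ensemble
#' exactly (merge conformation choices are recorded, so no randomness is
#' involved in a replay).
#'
#' @param ens The pre-resampling [WalkerEnsemble-class].
#' @param record A [ResamplingRecord-class].
#' @return The reconstructed post-resampling [WalkerEnsemble-class].
#' @export
replayRecord <- function(ens, record) {
    stopifnot(is(ens, "WalkerEnsemble"), is(record, "ResamplingRecord"))
    st <- ens@states
    wt <- ens@weights
    ops <- record@operations
    for (r in seq_len(nrow(ops))) {
        upd <- .applyOp(st, wt, ops[r, ])
        st <- upd$states
        wt <- upd$weights
    }
    walkerEnsemble(st, wt, cycleIndex = ens@cycleIndex)
}

## empty operations table with the canonical columns
.emptyOps <- function() {
    data.frame(op = character(), src1 = integer(), src2 = integer(),
               tgt1 = integer(), tgt2 = integer(), kept = integer(),
               wNew1 = numeric(), wNew2 = numeric())
}

.opRow <- function(op, src1, src2 = NA_integer_, tgt1, tgt2 = NA_integer_,
                   kept = NA_integer_, wNew1, wNew2 = NA_real_) {
    data.frame(op = op, src1 = as.integer(src1), src2 = as.integer(src2),
               tgt1 = as.integer(tgt1), tgt2 = as.integer(tgt2),
               kept = as.integer(kept), wNew1 = wNew1, wNew2 = wNew2)
}

## fast path for the resampler loops: operations accumulated as parallel
## lists and assembled into the canonical data frame once per cycle
.buildOps <- function(kind, rows) {
    if (!length(kind)) return(.emptyOps())
    m <- do.call(rbind, rows)
    data.frame(op = kind,
               src1 = as.integer(m[, 1]), src2 = as.integer(m[, 2]),
               tgt1 = as.integer(m[, 3]), tgt2 = as.integer(m[, 4]),
               kept = as.integer(m[, 5]), wNew1 = m[, 6], wNew2 = m[, 7])
}

#' The identity ("conventional") resampler
#'
#' Returns the ensemble unchanged with an empty record; running with it
#' reproduces conventional, unresampled simulation (CONV).
#'
#' @param ens A [WalkerEnsemble-class].
#' @return List with \code{ensemble} and \code{record}.
#' @export
convResample <- function(ens) {
    list(ensemble = ens,
         record = new("ResamplingRecord", cycleIndex = ens@cycleIndex,
                      operations = .emptyOps()))
}

#' Run one weighted-ensemble cycle
#'
#' Executes the cycle contract in fixed order: dynamics, then the boundary
#' check (warping), then resampling. Walker count and total weight are
#' conserved end-to-end; the returned ensemble's cycle index is advanced by
#' one.
#'
#' @param ens A [WalkerEnsemble-class].
#' @param dynamics Function taking the list of states and returning the
#'   propagated list of states (draws from the current RNG stream).
#' @param resampler Function taking an ensemble and returning a list with
#'   \code{ensemble} and \code{record} (e.g. [convResample()], or closures
#'   over [revoResample()] / [wexploreResample()]).
#' @param bc Optional [BoundaryCondition-class] (default NULL: no boundary).
#' @return List with \code{ensemble}, \code{record}, \code{warps} and
#'   \code{postDynamics} (the state list after dynamics, before warping;
#'   used for range bookkeeping).
#' @export
runCycle <- function(ens, dynamics, resampler, bc = NULL) {
    stopifnot(is(ens, "WalkerEnsemble"))
    n0 <- nWalkers(ens)
    st <- dynamics(ens@states)
    ens2 <- walkerEnsemble(st, ens@weights,
                           cycleIndex = ens@cycleIndex + 1L)
    postDynamics <- st
    warps <- data.frame(cycle = integer(), walker = integer(),
                        weight = numeric())
    if (!is.null(bc)) {
        bres <- applyBoundary(ens2, bc)
        ens2 <- bres$ensemble
        warps <- bres$warps
    }
    rres <- resampler(ens2)
    out <- rres$ensemble
    if (nWalkers(out) != n0)
        stop("resampler changed the walker count")
    if (abs(sum(weights(out)) - sum(weights(ens))) >= 1e-12)
        stop("resampler failed to conserve total weight")
    list(ensemble = out, record = rres$record, warps = warps,
         postDynamics = postDynamics)
}
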