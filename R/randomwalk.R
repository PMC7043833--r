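## N-dimensional biased random walk benchmark: lattice dynamics biased
## toward the origin, the scaled Manhattan metric, and the analytic target
## distribution the benchmark is scored against.

#' Construct random-walk parameters
#'
#' @param nDims Number of dimensions N.
#' @param pUp Forward-step probability per dimension per step. The default
#'   0.25 biases the walk toward the origin (backward probability 0.75).
#' @param stepsPerCycle Dynamics steps per WE cycle.
#' @return An [RWParams-class] object.
#' @examples
#' rwParams(nDims = 5)
#' @export
rwParams <- function(nDims = 2L, pUp = 0.25, stepsPerCycle = 10L) {
    new("RWParams", nDims = as.integer(nDims), pUp = pUp,
        stepsPerCycle = as.integer(stepsPerCycle))
}

#' Propagate random-walk states
#'
#' Each dimension independently moves +1 with probability \code{pUp} and -1
#' otherwise, at each step; a backward move from 0 is rejected (the
#' component stays at 0), which confines the walk to non-negative positions
#' and yields the stationary law (2/3)(1/3)^x at pUp = 0.25. One Bernoulli
#' variate is consumed per walker per dimension per step, in dimension-major
#' order, from the current RNG stream.
#'
#' @param pos Integer matrix (walkers x dimensions) of current positions,
#'   or a single position vector.
#' @param params An [RWParams-class]; \code{stepsPerCycle} steps are taken.
#' @param steps Number of steps to take (default \code{params@stepsPerCycle}).
#' @return Propagated positions, same shape as the input.
#' @export
rwStep <- function(pos, params, steps = params@stepsPerCycle) {
    vec <- is.vector(pos)
    if (vec) pos <- matrix(as.integer(pos), nrow = 1)
    stopifnot(ncol(pos) == params@nDims, all(pos >= 0))
    n <- nrow(pos)
    N <- ncol(pos)
    for (s in seq_len(steps)) {
        up <- runif(n * N) < params@pUp
        move <- matrix(ifelse(up, 1L, -1L), n, N)
        pos <- pmax(pos + move, 0L)
    }
    if (vec) pos[1, ] else pos
}

#' Scaled Manhattan distance between random-walk states
#'
#' The distance between two lattice states is the Manhattan (L1) norm of
#' their difference divided by the dimensionality N, making distances
#' comparable across N.
#'
#' @param a,b Non-negative position vectors of equal length.
#' @return Non-negative scalar distance.
#' @examples
#' rwDistance(c(0, 0), c(2, 4))  # 3
#' @export
rwDistance <- function(a, b) {
    if (length(a) != length(b))
        stop("dimension mismatch: ", length(a), " vs ", length(b))
    mean(abs(a - b))
}

#' All-to-all scaled Manhattan distance matrix
#'
#' @param pos Integer matrix (walkers x dimensions).
#' @return Symmetric zero-diagonal matrix of pairwise scaled Manhattan
#'   distances.
#' @importFrom stats dist
#' @export
rwDistanceMatrix <- function(pos) {
    as.matrix(dist(pos, method = "manhattan")) / ncol(pos)
}

#' Analytic target distribution of the biased walk
#'
#' With forward probability 1/4 and reflection at 0, each dimension's
#' stationary distribution is the geometric law P(x) = (2/3)(1/3)^x over
#' non-negative integers.
#'
#' @param x Non-negative integer position(s).
#' @return Target probability P(x).
#' @examples
#' rwTargetProb(0)  # 2/3
#' @export
rwTargetProb <- function(x) {
    if (any(x < 0)) stop("positions must be non-negative")
    (2 / 3) * (1 / 3)^x
}

#' Bundle the random-walk system for the simulation driver
#'
#' @param params An [RWParams-class].
#' @return List with \code{dynamics} (state-list propagator),
#'   \code{metric} (pairwise distance), \code{distanceMatrix} (ensemble
#'   distance matrix from a state list) and \code{initialState}.
#' @export
rwSystem <- function(params) {
    N <- params@nDims
    list(
        dynamics = function(states) {
            pos <- do.call(rbind, states)
            pos <- rwStep(pos, params)
            lapply(seq_len(nrow(pos)), function(i) pos[i, ])
        },
        metric = rwDistance,
        distanceMatrix = function(states)
            rwDistanceMatrix(do.call(rbind, states)),
        initialState = rep(0L, N)
    )
}
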