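## The REVO resampler: trajectory-variation objective, weight novelty, the
## greedy clone/merge optimization loop, characteristic-distance estimation
## and the distance-exponent calibration scan.

#' Construct REVO parameters
#'
#' @param alpha Distance exponent of the variation function. Larger alpha
#'   emphasizes widely separated walkers; 4 is the value selected by the
#'   early/late calibration procedure (see [alphaScan()]).
#' @param d0 Characteristic distance (same units as the distance metric);
#'   \code{NA} requests estimation from one dynamics cycle.
#' @param pMin,pMax Minimum and maximum walker weights.
#' @param mergeDistance Maximum pairwise distance permitting a merge.
#' @param noveltyMode "weight_based" or "constant".
#' @return A [REVOParams-class] object.
#' @examples
#' revoParams(alpha = 4, d0 = 1, pMin = 1e-12, pMax = 0.1,
#'            mergeDistance = 2.5)
#' @export
revoParams <- function(alpha = 4, d0 = NA_real_, pMin = 1e-12, pMax = 0.1,
                       mergeDistance = 2.5,
                       noveltyMode = c("weight_based", "constant")) {
    new("REVOParams", alpha = alpha, d0 = as.numeric(d0), pMin = pMin,
        pMax = pMax, mergeDistance = mergeDistance,
        noveltyMode = match.arg(noveltyMode))
}

#' Weight novelty of a walker
#'
#' The novelty phi(w) = ln(w) - ln(pMin/100) measures the relative
#' importance of a walker through its weight, prioritizing high-weight
#' walkers. With pMin = 1e-12 it ranges from about 32 for w near 1 down to
#' ln(100) = 4.6 at w = pMin. It is strictly increasing in w and
#' non-negative for w >= pMin/100.
#'
#' @param weight Walker weight(s), each in [pMin, 1].
#' @param pMin Minimum walker weight.
#' @return Novelty value(s).
#' @examples
#' novelty(1, 1e-12)      # ~32.24
#' novelty(1e-12, 1e-12)  # ln(100) = 4.605
#' @export
novelty <- function(weight, pMin) {
    if (any(weight < pMin))
        stop("weight below pMin: the resampler must never produce such ",
             "a walker")
    if (any(weight > 1)) stop("weights must be <= 1")
    log(weight) - log(pMin / 100)
}

.phiOf <- function(weightsv, params) {
    if (params@noveltyMode == "constant") rep(1, length(weightsv))
    else novelty(weightsv, params@pMin)
}

#' Trajectory variation of a walker ensemble
#'
#' The variation V = sum_i V_i with V_i = sum_j (d_ij/d0)^alpha phi_i phi_j
#' is the objective REVO maximizes: a novelty-weighted sum over walker
#' pairs of their distance raised to the exponent alpha, normalized by the
#' characteristic distance d0 so that V is unit-free.
#'
#' @param weightsv Numeric walker weights.
#' @param dmat Symmetric non-negative distance matrix with zero diagonal.
#' @param params A [REVOParams-class] with finite \code{d0}.
#' @return List with \code{vTotal}, per-walker \code{vI} and the novelties
#'   \code{phi}.
#' @export
calcVariation <- function(weightsv, dmat, params) {
    stopifnot(is(params, "REVOParams"))
    if (is.na(params@d0) || params@d0 <= 0)
        stop("'d0' must be a positive number (estimate it first)")
    n <- length(weightsv)
    if (!is.matrix(dmat) || nrow(dmat) != n || ncol(dmat) != n)
        stop("distance matrix dimension does not match the weight count")
    phi <- .phiOf(weightsv, params)
    M <- (dmat / params@d0)^params@alpha
    diag(M) <- 0   # d_ii = 0; keep 0 even when alpha = 0
    vI <- phi * as.vector(M %*% phi)
    list(vTotal = sum(vI), vI = vI, phi = phi)
}

#' Characteristic distance from a single dynamics cycle
#'
#' The characteristic distance d0 is the mean pairwise walker distance
#' after one dynamics cycle from the initial ensemble; it makes the
#' variation unit-free without affecting clone/merge behavior.
#'
#' @param dmat Pairwise distance matrix of the post-cycle ensemble (or a
#'   state matrix if \code{metricMatrix} is supplied).
#' @param metricMatrix Optional function turning states into a distance
#'   matrix (e.g. [rwDistanceMatrix()]).
#' @return Mean distance over all unordered pairs.
#' @export
estimateD0 <- function(dmat, metricMatrix = NULL) {
    if (!is.null(metricMatrix)) dmat <- metricMatrix(dmat)
    n <- nrow(dmat)
    if (is.null(n) || n < 2) stop("need at least 2 walkers")
    d0 <- mean(dmat[upper.tri(dmat)])
    if (d0 == 0)
        stop("all walkers identical after one cycle: d0 = 0 leaves the ",
             "variation undefined")
    d0
}

## One greedy REVO decision: candidate selection on current weights/V_i.
## Returns NULL when no legal (c, m1, m2) triple exists.
.revoCandidates <- function(w, vI, D, params) {
    ## m1: lowest-V_i walker that can still absorb weight
    elig1 <- which(w < params@pMax)
    if (!length(elig1)) return(NULL)
    m1 <- elig1[which.min(vI[elig1])]
    ## m2: walker closest to m1 among legal merge partners
    cand <- which(w + w[m1] < params@pMax & D[m1, ] < params@mergeDistance)
    cand <- setdiff(cand, m1)
    if (!length(cand)) return(NULL)
    m2 <- cand[which.min(D[m1, cand])]
    ## c: highest-V_i walker whose children stay above pMin, distinct from
    ## the merge pair
    eligc <- which(w / 2 >= params@pMin)
    eligc <- setdiff(eligc, c(m1, m2))
    if (!length(eligc)) return(NULL)
    cc <- eligc[which.max(vI[eligc])]
    list(c = cc, m1 = m1, m2 = m2)
}

#' REVO resampling of a walker ensemble
#'
#' Greedy maximization of the trajectory variation: at each iteration the
#' highest-variation eligible walker is cloned while the lowest-variation
#' walker below the weight cap is merged with its nearest legal partner
#' (combined weight below \code{pMax}, distance below
#' \code{mergeDistance}). The move is kept only if it strictly increases
#' the total variation; otherwise it is undone and the loop stops. The
#' distance matrix is updated incrementally — clones inherit the parent's
#' distances (zero between the pair) and a merge keeps the surviving
#' walker's row — which is exact because conformations are copies.
#'
#' Walker count and total weight are conserved; given an input ensemble
#' whose weights lie within [pMin, pMax], no output weight leaves that
#' band.
#'
#' @param ens A [WalkerEnsemble-class].
#' @param dmat All-to-all distance matrix of the input ensemble.
#' @param params A [REVOParams-class] with finite \code{d0}.
#' @return List with \code{ensemble}, \code{record}
#'   ([ResamplingRecord-class]), \code{vTotal} (accepted final variation),
#'   \code{vTotalInitial} and \code{dmat} (incrementally updated matrix for
#'   the output ensemble).
#' @export
revoResample <- function(ens, dmat, params) {
    stopifnot(is(ens, "WalkerEnsemble"), is(params, "REVOParams"))
    n <- nWalkers(ens)
    w <- ens@weights
    D <- dmat
    stateIdx <- seq_len(n)            # slot -> input conformation index
    vr <- calcVariation(w, D, params)
    vOld <- vr$vTotal
    vInit <- vOld
    opKind <- character(0)
    opRows <- list()
    maxIter <- 10L * n + 100L         # safety guard; never binds in practice
    for (it in seq_len(maxIter)) {
        cand <- .revoCandidates(w, vr$vI, D, params)
        if (is.null(cand)) break
        m1 <- cand$m1; m2 <- cand$m2; cc <- cand$c
        ## merge keep-choice: drawn now; an undo restores the ensemble
        ## exactly (the consumed variate is part of the run's RNG stream)
        keepFirst <- runif(1) < w[m1] / (w[m1] + w[m2])
        kept <- if (keepFirst) m1 else m2
        vac <- if (keepFirst) m2 else m1
        wNew <- w
        wNew[kept] <- w[m1] + w[m2]
        wNew[cc] <- w[cc] / 2
        wNew[vac] <- w[cc] / 2
        Dnew <- D
        Dnew[vac, ] <- D[cc, ]
        Dnew[, vac] <- D[, cc]
        Dnew[vac, cc] <- 0
        Dnew[cc, vac] <- 0
        Dnew[vac, vac] <- 0
        vrNew <- calcVariation(wNew, Dnew, params)
        if (vrNew$vTotal > vOld) {
            w <- wNew; D <- Dnew; vr <- vrNew; vOld <- vrNew$vTotal
            stateIdx[vac] <- stateIdx[cc]
            opKind <- c(opKind, "merge", "clone")
            opRows[[length(opRows) + 1L]] <-
                c(m1, m2, kept, NA, kept, wNew[kept], NA)
            opRows[[length(opRows) + 1L]] <-
                c(cc, NA, cc, vac, NA, wNew[cc], wNew[vac])
        } else break                  # undo: discard the proposal
    }
    outStates <- ens@states[stateIdx]
    out <- walkerEnsemble(outStates, w, cycleIndex = ens@cycleIndex)
    rec <- new("ResamplingRecord", cycleIndex = ens@cycleIndex,
               operations = .buildOps(opKind, opRows))
    list(ensemble = out, record = rec, vTotal = vOld, vTotalInitial = vInit,
         dmat = D)
}

#' Distance-exponent calibration scan
#'
#' Evaluates the mean trajectory variation of labeled walker ensembles
#' (typically "early": compact, high-weight; "late": containing far,
#' low-weight walkers) over a set of alpha values, using one shared d0. An
#' exponent that clearly separates late from early ensembles is suitable
#' for driving rare-event sampling.
#'
#' @param ensembles List of entries, each a list with \code{label}
#'   (character), \code{weights} and \code{dmat}.
#' @param alphas Numeric vector of exponents to scan (default 1:4).
#' @param params A [REVOParams-class]; its \code{d0} is shared across all
#'   ensembles and alphas (estimated from the pooled early ensembles when
#'   \code{NA}).
#' @return Data frame with columns label, alpha, meanV, semV.
#' @export
alphaScan <- function(ensembles, alphas = 1:4, params = revoParams()) {
    labs <- vapply(ensembles, function(e) e$label, character(1))
    if (!length(ensembles) || any(!nzchar(labs)))
        stop("every ensemble needs a non-empty label")
    d0 <- params@d0
    if (is.na(d0)) {
        early <- ensembles[labs == "early"]
        if (!length(early))
            stop("no 'early' ensembles to estimate d0 from; supply d0")
        d0 <- mean(vapply(early, function(e)
            mean(e$dmat[upper.tri(e$dmat)]), numeric(1)))
    }
    out <- expand.grid(label = unique(labs), alpha = alphas,
                       stringsAsFactors = FALSE)
    out$meanV <- NA_real_
    out$semV <- NA_real_
    for (r in seq_len(nrow(out))) {
        p <- revoParams(alpha = out$alpha[r], d0 = d0, pMin = params@pMin,
                        pMax = params@pMax,
                        mergeDistance = params@mergeDistance,
                        noveltyMode = params@noveltyMode)
        grp <- ensembles[labs == out$label[r]]
        if (!length(grp)) stop("empty label group: ", out$label[r])
        vs <- vapply(grp, function(e)
            calcVariation(e$weights, e$dmat, p)$vTotal, numeric(1))
        out$meanV[r] <- mean(vs)
        out$semV[r] <- if (length(vs) > 1) sd(vs) / sqrt(length(vs)) else 0
    }
    out
}
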