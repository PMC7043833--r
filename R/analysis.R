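## Post-run metrics: positional probability profiles, accuracy against the
## analytic target, sampling range, run-to-run standard error, unbinding
## flux / residence time, and origin-distance statistics.

#' Averaged positional probability profile
#'
#' For each sampled cycle the walker weights are histogrammed over integer
#' positions separately in every dimension; the histograms are averaged
#' over dimensions, sampled cycles and runs into one normalized profile.
#' Per-run profiles are kept for run-to-run standard errors.
#'
#' @param records List of [RunRecord-class] objects sharing N and cycle
#'   count.
#' @param burnIn Fraction of initial cycles discarded (default 0.1).
#' @param every Sample every this-many cycles after burn-in (default 1).
#' @return A [ProbabilityProfile-class].
#' @export
predictedProbability <- function(records, burnIn = 0.1, every = 1L) {
    if (!length(records)) stop("need at least one run record")
    nC <- length(records[[1]]@positions)
    N <- ncol(records[[1]]@positions[[1]])
    use <- seq.int(floor(burnIn * nC) + 1L, nC, by = every)
    maxX <- 0L
    acc <- vector("list", length(records))
    for (r in seq_along(records)) {
        rec <- records[[r]]
        if (length(rec@positions) != nC ||
            ncol(rec@positions[[1]]) != N)
            stop("run records must share N and cycle count")
        tot <- numeric(256)
        for (cy in use) {
            pos <- rec@positions[[cy]]
            w <- rec@weights[[cy]]
            p <- as.vector(pos) + 1L        # 1-based bins
            if (max(p) > length(tot)) tot <- c(tot, numeric(max(p)))
            agg <- rowsum(rep(w, N), p)
            tot[as.integer(rownames(agg))] <-
                tot[as.integer(rownames(agg))] + agg[, 1]
        }
        tot <- tot / (length(use) * N)
        acc[[r]] <- tot
        maxX <- max(maxX, max(which(tot > 0)))
    }
    perRun <- vapply(acc, function(v) {
        length(v) <- maxX
        v[is.na(v)] <- 0
        v
    }, numeric(maxX))
    perRun <- matrix(perRun, nrow = maxX,
                     dimnames = list(0:(maxX - 1L), NULL))
    P <- rowMeans(perRun)
    new("ProbabilityProfile",
        profile = data.frame(x = 0:(maxX - 1L), P = unname(P)),
        perRun = perRun,
        metadata = list(nDims = N, nRuns = length(records),
                        cycles = use, burnIn = burnIn))
}

#' Accuracy of a probability profile against the target
#'
#' Per position, the accuracy contribution is
#' \deqn{a(x) = 1 + |\log P^t(x) - \log P(x)| / \log P^t(x)}
#' when \eqn{\log P(x) > 2 \log P^t(x)} (i.e. the estimate is within a
#' factor of the squared target on the log scale), and 0 otherwise, so a
#' position never estimated contributes nothing. The contribution peaks at
#' 1 exactly when P(x) equals the target, and the total accuracy A is the
#' sum of contributions over positions up to the largest with P(x) > 0.
#'
#' @param profile A [ProbabilityProfile-class], or a data frame with
#'   columns x and P.
#' @param target Vectorized target distribution (default [rwTargetProb()]).
#' @return List with \code{total} (A) and \code{table} (x, a).
#' @export
accuracy <- function(profile, target = rwTargetProb) {
    tab <- if (is(profile, "ProbabilityProfile")) profile@profile
           else as.data.frame(profile)
    sup <- tab$x[tab$P > 0]
    xs <- if (length(sup)) 0:max(sup) else integer(0)
    a <- vapply(xs, function(x) {
        P <- tab$P[match(x, tab$x)]
        if (is.na(P) || P <= 0) return(0)
        Pt <- target(x)
        if (log(P) > 2 * log(Pt))
            1 + abs(log(Pt) - log(P)) / log(Pt)
        else 0
    }, numeric(1))
    list(total = sum(a), table = data.frame(x = xs, a = a))
}

#' Sampling range of a set of runs
#'
#' The range of one run is the largest position ever visited along each
#' dimension (during dynamics, before any warping), averaged over
#' dimensions. Ranges are then averaged over runs with a standard error.
#'
#' @param records List of [RunRecord-class] objects.
#' @param upToCycle Only count cycles up to this index (default all).
#' @return List with \code{mean}, \code{se} and per-run \code{ranges}.
#' @export
samplingRange <- function(records, upToCycle = Inf) {
    if (!length(records)) stop("need at least one run record")
    rg <- vapply(records, function(rec) {
        mv <- rec@maxVisited
        k <- min(nrow(mv), upToCycle)
        mean(apply(mv[seq_len(k), , drop = FALSE], 2, max))
    }, numeric(1))
    list(mean = mean(rg),
         se = if (length(rg) > 1) sd(rg) / sqrt(length(rg)) else 0,
         ranges = rg)
}

#' Run-to-run averaged standard error of the predicted probability
#'
#' For each position in [xLo, xHi] the standard error of P(x) across runs
#' is computed (absent positions count as probability 0), then averaged
#' over positions.
#'
#' @param profile A [ProbabilityProfile-class] holding >= 2 per-run
#'   profiles.
#' @param xLo,xHi Position window (defaults 0 and 22).
#' @return List with \code{average} (the averaged SE) and \code{perX}
#'   (data frame x, se).
#' @export
runStandardError <- function(profile, xLo = 0L, xHi = 22L) {
    stopifnot(is(profile, "ProbabilityProfile"))
    pr <- profile@perRun
    if (ncol(pr) < 2) stop("need at least 2 runs")
    xs <- xLo:xHi
    se <- vapply(xs, function(x) {
        row <- x + 1L
        v <- if (row <= nrow(pr)) pr[row, ] else numeric(ncol(pr))
        sd(v) / sqrt(length(v))
    }, numeric(1))
    list(average = mean(se), perX = data.frame(x = xs, se = se))
}

#' Unbinding flux and residence time from warp logs
#'
#' The cumulative flux of a run is the running sum of warped walker
#' weights over time; the mean flux rate of a run is its total warped
#' weight divided by its simulated time. Rates are averaged over runs with
#' a standard error, and the residence time (mean first-passage time of
#' the warped transition) is the reciprocal of the average rate — infinite
#' when no warp ever occurred.
#'
#' @param records List of [RunRecord-class] objects, or a list of warp
#'   data frames (cycle, walker, weight) paired with \code{nCycles}.
#' @param cycleDuration Simulated time per cycle (default 1, arbitrary
#'   units).
#' @param nCycles Run length in cycles; taken from the records when they
#'   are [RunRecord-class] objects.
#' @return List with \code{series} (per-run data frames t, flux),
#'   \code{meanRate}, \code{seRate}, \code{residenceTime} and
#'   \code{residenceBounds} (reciprocals of rate +/- one SE).
#' @export
fluxAndResidence <- function(records, cycleDuration = 1, nCycles = NULL) {
    if (!length(records)) stop("need at least one run")
    asRec <- is(records[[1]], "RunRecord")
    series <- vector("list", length(records))
    rates <- numeric(length(records))
    for (r in seq_along(records)) {
        warps <- if (asRec) records[[r]]@warps else records[[r]]
        len <- if (asRec) length(records[[r]]@positions) else nCycles
        if (is.null(len) || len <= 0) stop("zero or unknown run length")
        tEnd <- len * cycleDuration
        warps <- warps[order(warps$cycle), , drop = FALSE]
        series[[r]] <- data.frame(t = warps$cycle * cycleDuration,
                                  flux = cumsum(warps$weight))
        rates[r] <- sum(warps$weight) / tEnd
    }
    meanRate <- mean(rates)
    seRate <- if (length(rates) > 1) sd(rates) / sqrt(length(rates)) else 0
    list(series = series, rates = rates, meanRate = meanRate,
         seRate = seRate,
         residenceTime = if (meanRate > 0) 1 / meanRate else Inf,
         residenceBounds = c(
             lower = if (meanRate + seRate > 0) 1 / (meanRate + seRate)
                     else Inf,
             upper = if (meanRate - seRate > 0) 1 / (meanRate - seRate)
                     else Inf))
}

#' Distribution of walker distances to the origin
#'
#' Pools walkers over the requested cycles and runs and reports the
#' distribution (and expectation) of their scaled-Manhattan distance to
#' the origin. By default walkers are pooled uniformly — the statistic
#' describes walker positions, not probability mass — with weight-weighted
#' pooling available as an option.
#'
#' @param records List of [RunRecord-class] objects.
#' @param nCyclesSample Number of cycles, evenly spaced over the run, to
#'   pool (default 10).
#' @param weighted Pool by statistical weight instead of uniformly
#'   (default FALSE).
#' @return List with \code{expectation}, \code{distances} (pooled values)
#'   and \code{histogram} (data frame d, p).
#' @export
originDistanceStats <- function(records, nCyclesSample = 10L,
                                weighted = FALSE) {
    if (!length(records)) stop("need at least one run record")
    dall <- numeric(0)
    wall <- numeric(0)
    for (rec in records) {
        nC <- length(rec@positions)
        cys <- unique(round(seq(1, nC, length.out = min(nCyclesSample, nC))))
        for (cy in cys) {
            pos <- rec@positions[[cy]]
            dall <- c(dall, rowMeans(abs(pos)))
            wall <- c(wall, rec@weights[[cy]])
        }
    }
    pw <- if (weighted) wall / sum(wall) else rep(1 / length(dall),
                                                  length(dall))
    agg <- rowsum(pw, dall)
    list(expectation = sum(dall * pw),
         distances = dall,
         histogram = data.frame(d = as.numeric(rownames(agg)),
                                p = agg[, 1]))
}
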