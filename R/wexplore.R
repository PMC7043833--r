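## WExplore reference resampler: hierarchical Voronoi regions with dynamic
## image creation under per-level distance thresholds, a branching cap, and
## top-down balancing of walker counts via clone/merge.

#' Construct a region hierarchy
#'
#' Initializes the hierarchy with a single chain of regions — one node per
#' level — all imaged on the initial conformation. Thresholds are stored
#' coarsest (largest) first; for the random-walk benchmark the four-level
#' hierarchy uses 16, 4, 1, 0.25.
#'
#' @param thresholds Strictly decreasing per-level distance thresholds.
#' @param initialImage Conformation imaging the initial region at every
#'   level.
#' @param maxChildren Maximum child regions per parent (default 10).
#' @return A [RegionHierarchy-class].
#' @examples
#' regionHierarchy(c(16, 4, 1, 0.25), rep(0L, 2))
#' @export
regionHierarchy <- function(thresholds, initialImage, maxChildren = 10L) {
    L <- length(thresholds)
    new("RegionHierarchy", thresholds = as.numeric(thresholds),
        maxChildren = as.integer(maxChildren),
        parent = c(0L, seq_len(L - 1L)), level = seq_len(L),
        images = rep(list(initialImage), L))
}

## children node ids of `parentId` at level `lvl` (parentId 0 = root)
.childrenOf <- function(h, parentId, lvl) {
    which(h@parent == parentId & h@level == lvl)
}

#' Assign a walker to a region path
#'
#' Greedy top-down descent: at each level the walker goes to the child
#' region whose image is nearest (ties broken toward the earliest-created
#' node). Returns the root-to-leaf path of node ids.
#'
#' @param state Walker conformation.
#' @param h A [RegionHierarchy-class].
#' @param metric Distance function between two conformations.
#' @return Integer vector of node ids, one per level.
#' @export
assignWalker <- function(state, h, metric) {
    L <- nLevels(h)
    if (!nRegions(h)) stop("empty hierarchy")
    path <- integer(L)
    parent <- 0L
    for (lvl in seq_len(L)) {
        kids <- .childrenOf(h, parent, lvl)
        if (!length(kids))
            stop("hierarchy has no node at level ", lvl, " under node ",
                 parent)
        d <- vapply(kids, function(k) metric(state, h@images[[k]]),
                    numeric(1))
        parent <- kids[which.min(d)]
        path[lvl] <- parent
    }
    path
}

## create a chain of new nodes from level `lvl` down to the bottom, all
## imaged on `image`, hanging under `parentId`; returns list(h, leafPath)
.growChain <- function(h, parentId, lvl, image) {
    L <- nLevels(h)
    ids <- integer(L - lvl + 1L)
    for (l in lvl:L) {
        h@parent <- c(h@parent, parentId)
        h@level <- c(h@level, l)
        h@images <- c(h@images, list(image))
        parentId <- length(h@images)
        ids[l - lvl + 1L] <- parentId
    }
    list(h = h, ids = ids)
}

#' Create new regions for out-of-threshold walkers
#'
#' Walkers are processed in ensemble order. Each descends the hierarchy; at
#' any level where its distance to every sibling image exceeds that level's
#' threshold and the parent is not saturated (fewer than \code{maxChildren}
#' children), a new region is founded with the walker's conformation as its
#' image, together with the chain of child regions below it. At the
#' branching cap no region is created and the walker is assigned to the
#' nearest existing image. Images are never moved once created.
#'
#' @param ens A [WalkerEnsemble-class].
#' @param h A [RegionHierarchy-class].
#' @param metric Distance function between two conformations.
#' @return The (possibly extended) [RegionHierarchy-class].
#' @export
updateRegions <- function(ens, h, metric) {
    L <- nLevels(h)
    for (i in seq_len(nWalkers(ens))) {
        s <- ens@states[[i]]
        parent <- 0L
        for (lvl in seq_len(L)) {
            kids <- .childrenOf(h, parent, lvl)
            d <- vapply(kids, function(k) metric(s, h@images[[k]]),
                        numeric(1))
            if (all(d > h@thresholds[lvl]) &&
                length(kids) < h@maxChildren) {
                h <- .growChain(h, parent, lvl, s)$h
                break
            }
            parent <- kids[which.min(d)]
        }
    }
    h
}

## deterministic merge-pair search within a most-populated group: the two
## lowest-weight walkers sharing a full leaf path whose combined weight
## stays below pMax; among leaves, the pair with the smallest combined
## weight wins
.mergePairIn <- function(idx, leafKeyAll, w, pMax) {
    leafKey <- leafKeyAll[idx]
    best <- NULL
    bestW <- Inf
    for (key in unique(leafKey)) {
        grp <- idx[leafKey == key]
        if (length(grp) < 2) next
        ord <- grp[order(w[grp], grp)]
        pair <- ord[1:2]
        ws <- sum(w[pair])
        if (ws < pMax && ws < bestW) {
            best <- pair
            bestW <- ws
        }
    }
    best
}

#' WExplore resampling of a walker ensemble
#'
#' Balances walker counts across sibling regions from the top of the
#' hierarchy down: within each sibling group, while the most- and
#' least-populated occupied regions differ by more than one walker and a
#' legal move exists, the two lowest-weight same-leaf walkers of the
#' most-populated region are merged (freeing one slot) and the
#' highest-weight clonable walker of the least-populated region is cloned
#' into it. Merges only ever pair walkers sharing the same region at every
#' level; \code{pMin}/\code{pMax} are respected throughout, and walker
#' count and total weight are conserved.
#'
#' @param ens A [WalkerEnsemble-class].
#' @param h A [RegionHierarchy-class] already updated for this cycle (see
#'   [updateRegions()]).
#' @param metric Distance function between two conformations.
#' @param pMin,pMax Minimum and maximum walker weights.
#' @return List with \code{ensemble}, \code{record}
#'   ([ResamplingRecord-class]) and \code{assignments} (final region paths,
#'   walkers x levels).
#' @export
wexploreResample <- function(ens, h, metric, pMin = 1e-12, pMax = 0.1) {
    stopifnot(is(ens, "WalkerEnsemble"), is(h, "RegionHierarchy"))
    n <- nWalkers(ens)
    st <- ens@states
    w <- ens@weights
    paths <- t(vapply(st, function(s) assignWalker(s, h, metric),
                      integer(nLevels(h))))
    opKind <- character(0)
    opRows <- list()
    leafKey <- apply(paths, 1, paste, collapse = "/")

    balance <- function(idx, lvl) {
        if (lvl > nLevels(h) || length(idx) < 2) return(invisible(NULL))
        repeat {
            groups <- split(idx, paths[idx, lvl])
            if (length(groups) > 1) {
                counts <- lengths(groups)
                moved <- FALSE
                mx <- which.max(counts)
                mn <- which.min(counts)
                if (counts[mx] - counts[mn] > 1) {
                    pair <- .mergePairIn(groups[[mx]], leafKey, w, pMax)
                    donors <- groups[[mn]]
                    elig <- donors[w[donors] / 2 >= pMin]
                    if (!is.null(pair) && length(elig)) {
                        cc <- elig[order(-w[elig], elig)][1]
                        m1 <- pair[1]; m2 <- pair[2]
                        keepFirst <- runif(1) < w[m1] / (w[m1] + w[m2])
                        kept <- if (keepFirst) m1 else m2
                        vac <- if (keepFirst) m2 else m1
                        w[kept] <<- w[m1] + w[m2]
                        half <- w[cc] / 2
                        w[cc] <<- half
                        w[vac] <<- half
                        st[[vac]] <<- st[[cc]]
                        paths[vac, ] <<- paths[cc, ]
                        leafKey[vac] <<- leafKey[cc]
                        opKind <<- c(opKind, "merge", "clone")
                        opRows[[length(opRows) + 1L]] <<-
                            c(m1, m2, kept, NA, kept, w[kept], NA)
                        opRows[[length(opRows) + 1L]] <<-
                            c(cc, NA, cc, vac, NA, half, half)
                        moved <- TRUE
                    }
                }
                if (!moved) break
            } else break
        }
        for (g in split(idx, paths[idx, lvl])) balance(g, lvl + 1L)
        invisible(NULL)
    }
    balance(seq_len(n), 1L)
    out <- walkerEnsemble(st, w, cycleIndex = ens@cycleIndex)
    rec <- new("ResamplingRecord", cycleIndex = ens@cycleIndex,
               operations = .buildOps(opKind, opRows))
    list(ensemble = out, record = rec, assignments = paths)
}
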