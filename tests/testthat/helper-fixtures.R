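## Shared fixtures and independent oracles used across the test files.

## Brute-force evaluation of the variation objective, written independently
## of calcVariation(): explicit double loop over ordered pairs.
bruteVariation <- function(w, dmat, alpha, d0, pMin,
                           constantNovelty = FALSE) {
    n <- length(w)
    phi <- if (constantNovelty) rep(1, n) else log(w) - log(pMin / 100)
    vI <- numeric(n)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i != j)
                vI[i] <- vI[i] + (dmat[i, j] / d0)^alpha * phi[i] * phi[j]
        }
    }
    list(vTotal = sum(vI), vI = vI)
}

## Brute-force mean over unordered pairs.
brutePairMean <- function(dmat) {
    n <- nrow(dmat)
    tot <- 0
    k <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        tot <- tot + dmat[i, j]
        k <- k + 1
    }
    tot / k
}

## Enumeration oracle for hierarchical region assignment: evaluates the
## greedy descent level by level without using assignWalker's code path.
enumAssign <- function(state, h, metric) {
    L <- length(h@thresholds)
    parent <- 0L
    path <- integer(L)
    for (lvl in seq_len(L)) {
        kids <- which(h@parent == parent & h@level == lvl)
        dd <- sapply(kids, function(k) metric(state, h@images[[k]]))
        parent <- kids[which.min(dd)]
        path[lvl] <- parent
    }
    path
}

## A small deterministic ensemble on the 2-D lattice.
smallEnsemble <- function(positions, weights = NULL) {
    walkerEnsemble(positions, weights)
}

## A 3-walker variation instance with stated weights and distances, used
## against the brute-force oracle.
threeWalkerInstance <- function() {
    dmat <- matrix(c(0, 1, 3,
                     1, 0, 2,
                     3, 2, 0), 3, 3, byrow = TRUE)
    list(weights = c(0.5, 0.3, 0.2), dmat = dmat, alpha = 4, d0 = 2,
         pMin = 1e-12)
}
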