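## Hand-built run records keep the analysis oracles independent of the
## simulation driver.
fakeRecord <- function(positionsList, weightsList, maxVisited = NULL,
                       warps = NULL, config = list()) {
    nC <- length(positionsList)
    N <- ncol(positionsList[[1]])
    if (is.null(maxVisited))
        maxVisited <- do.call(rbind, lapply(positionsList, function(p)
            apply(p, 2, max)))
    if (is.null(warps))
        warps <- data.frame(cycle = integer(), walker = integer(),
                            weight = numeric())
    new("RunRecord", config = config, positions = positionsList,
        weights = weightsList, maxVisited = maxVisited,
        resampling = list(), warps = warps, vTrace = rep(NA_real_, nC),
        regionCounts = rep(NA_integer_, nC), d0 = NA_real_,
        hierarchy = NULL)
}

test_that("probability profiles are normalized weighted histograms", {
    ## one walker, weight 1, at x = 3 in every dimension -> point mass
    rec <- fakeRecord(list(matrix(3L, 1, 2)), list(1))
    pp <- predictedProbability(list(rec), burnIn = 0)
    tab <- profileTable(pp)
    expect_equal(tab$P[tab$x == 3], 1)
    expect_equal(sum(tab$P), 1)

    ## two walkers, unequal weights, different dimensions contribute
    rec2 <- fakeRecord(list(rbind(c(0L, 2L), c(1L, 1L))),
                       list(c(0.75, 0.25)))
    pp2 <- predictedProbability(list(rec2), burnIn = 0)
    tab2 <- profileTable(pp2)
    ## dim 1: 0.75 at 0, 0.25 at 1; dim 2: 0.75 at 2, 0.25 at 1; averaged
    expect_equal(tab2$P, c(0.375, 0.25, 0.375))
    expect_equal(sum(tab2$P), 1)
})

test_that("profiles over runs are the arithmetic mean of run profiles", {
    recA <- fakeRecord(list(matrix(0L, 1, 1)), list(1))
    recB <- fakeRecord(list(matrix(2L, 1, 1)), list(1))
    pp <- predictedProbability(list(recA, recB), burnIn = 0)
    expect_equal(profileTable(pp)$P, c(0.5, 0, 0.5))
    expect_equal(dim(pp@perRun), c(3L, 2L))
    expect_equal(pp@perRun[, 1], c(1, 0, 0), ignore_attr = TRUE)
})

test_that("accuracy contributions follow the two-branch formula", {
    ## exact agreement with the target on x = 0..9: every a(x) = 1, A = 10
    prof <- data.frame(x = 0:9, P = rwTargetProb(0:9))
    prof$P <- prof$P / sum(prof$P) * sum(rwTargetProb(0:9)) # unchanged
    acc <- accuracy(prof)
    expect_equal(acc$table$a, rep(1, 10))
    expect_equal(acc$total, 10)

    ## a zero-probability position contributes 0
    prof2 <- data.frame(x = 0:2, P = c(2 / 3, 0, 1 - 2 / 3 - 0))
    acc2 <- accuracy(prof2)
    expect_equal(acc2$table$a[acc2$table$x == 1], 0)

    ## the condition is strict: P = (P^t)^2 exactly falls to the 0 branch
    x <- 2
    prof3 <- data.frame(x = x, P = rwTargetProb(x)^2)
    acc3 <- accuracy(prof3)
    expect_equal(acc3$table$a[acc3$table$x == x], 0)

    ## slightly above the boundary re-enters the positive branch
    prof4 <- data.frame(x = x, P = rwTargetProb(x)^2 * 1.01)
    acc4 <- accuracy(prof4)
    expect_gt(acc4$table$a[acc4$table$x == x], 0)
})

test_that("accuracy is maximized exactly at the target distribution", {
    xs <- 0:6
    atTarget <- accuracy(data.frame(x = xs, P = rwTargetProb(xs)))$total
    set.seed(19)
    for (i in 1:20) {
        P <- rwTargetProb(xs) * exp(runif(length(xs), -1, 1))
        expect_lte(accuracy(data.frame(x = xs, P = P))$total, atTarget)
    }
})

test_that("sampling range averages per-dimension maxima over runs", {
    ## one N = 2 run with per-dimension maxima 5 and 7 -> 6.0
    rec <- fakeRecord(list(matrix(0L, 1, 2)), list(1),
                      maxVisited = rbind(c(2, 7), c(5, 3)))
    rg <- samplingRange(list(rec))
    expect_equal(rg$mean, 6.0)
    expect_equal(rg$se, 0)

    ## walkers that never leave the origin give range 0
    rec0 <- fakeRecord(list(matrix(0L, 3, 2)), list(rep(1 / 3, 3)))
    expect_equal(samplingRange(list(rec0))$mean, 0)

    ## the range is non-decreasing in the number of cycles included
    rec2 <- fakeRecord(list(matrix(0L, 1, 1), matrix(0L, 1, 1),
                            matrix(0L, 1, 1)), rep(list(1), 3),
                       maxVisited = rbind(1, 4, 2))
    r1 <- samplingRange(list(rec2), upToCycle = 1)$mean
    r2 <- samplingRange(list(rec2), upToCycle = 2)$mean
    r3 <- samplingRange(list(rec2), upToCycle = 3)$mean
    expect_true(r1 <= r2 && r2 <= r3)
    expect_equal(c(r1, r2, r3), c(1, 4, 4))
})

test_that("run-to-run standard errors match hand calculations", {
    ## two runs with P(0) = 0.6 and 0.7: SE = 0.05
    recA <- fakeRecord(list(rbind(0L, 1L)), list(c(0.6, 0.4)))
    recB <- fakeRecord(list(rbind(0L, 1L)), list(c(0.7, 0.3)))
    pp <- predictedProbability(list(recA, recB), burnIn = 0)
    se <- runStandardError(pp, 0, 1)
    expect_equal(se$perX$se[se$perX$x == 0], 0.05)
    expect_equal(se$perX$se[se$perX$x == 1], 0.05)
    expect_equal(se$average, 0.05)

    ## identical runs: zero SE everywhere
    pp2 <- predictedProbability(list(recA, recA), burnIn = 0)
    expect_equal(runStandardError(pp2, 0, 5)$average, 0)

    ## the average equals a brute-force recomputation over the window
    set.seed(23)
    recs <- lapply(1:4, function(s) {
        w <- runif(3)
        w <- w / sum(w)
        fakeRecord(list(matrix(sample(0:5, 6, replace = TRUE), 3, 2)),
                   list(w))
    })
    pp3 <- predictedProbability(recs, burnIn = 0)
    got <- runStandardError(pp3, 0, 8)
    brute <- sapply(0:8, function(x) {
        v <- sapply(seq_along(recs), function(r) {
            if (x + 1 <= nrow(pp3@perRun)) pp3@perRun[x + 1, r] else 0
        })
        sd(v) / 2
    })
    expect_equal(got$average, mean(brute), tolerance = 1e-12)

    expect_error(runStandardError(
        predictedProbability(list(recA), burnIn = 0)), "at least 2")
})

test_that("flux series and residence times follow the warp logs", {
    ## no warps: zero flux, infinite residence time
    rec0 <- fakeRecord(rep(list(matrix(0L, 1, 1)), 5), rep(list(1), 5))
    fl0 <- fluxAndResidence(list(rec0))
    expect_equal(nrow(fl0$series[[1]]), 0)
    expect_equal(fl0$meanRate, 0)
    expect_equal(fl0$residenceTime, Inf)

    ## single warp of weight 1e-6 in a run of length 100 time units:
    ## rate 1e-8 per unit, residence 1e8
    warps <- data.frame(cycle = 40L, walker = 1L, weight = 1e-6)
    rec1 <- fakeRecord(rep(list(matrix(0L, 1, 1)), 100),
                       rep(list(1), 100), warps = warps)
    fl1 <- fluxAndResidence(list(rec1), cycleDuration = 1)
    expect_equal(fl1$meanRate, 1e-8)
    expect_equal(fl1$residenceTime, 1e8)
    expect_equal(fl1$series[[1]]$flux, 1e-6)

    ## two runs: mean of per-run rates, SE propagated to bounds
    warps2 <- data.frame(cycle = c(10L, 20L), walker = c(1L, 1L),
                         weight = c(2e-6, 1e-6))
    rec2 <- fakeRecord(rep(list(matrix(0L, 1, 1)), 100),
                       rep(list(1), 100), warps = warps2)
    fl <- fluxAndResidence(list(rec1, rec2), cycleDuration = 1)
    expect_equal(fl$rates, c(1e-8, 3e-8))
    expect_equal(fl$meanRate, 2e-8)
    expect_equal(fl$seRate, sd(c(1e-8, 3e-8)) / sqrt(2))
    expect_equal(fl$residenceTime, 5e7)
    expect_equal(unname(fl$residenceBounds["lower"]),
                 1 / (2e-8 + fl$seRate))
    ## cumulative flux is non-decreasing and equals the summed weights
    expect_equal(max(fl$series[[2]]$flux), 3e-6)
    expect_true(all(diff(fl$series[[2]]$flux) >= 0))
})

test_that("origin-distance statistics pool walkers over cycles and runs", {
    ## all walkers at the origin: point mass at 0
    rec0 <- fakeRecord(list(matrix(0L, 4, 2)), list(rep(0.25, 4)))
    os0 <- originDistanceStats(list(rec0))
    expect_equal(os0$expectation, 0)
    expect_equal(os0$histogram$d, 0)
    expect_equal(os0$histogram$p, 1)

    ## two walkers at distances 1 and 3: expectation 2 under uniform
    ## pooling, weight-dependent otherwise
    pos <- rbind(c(2L, 0L), c(3L, 3L))
    rec <- fakeRecord(list(pos), list(c(0.9, 0.1)))
    os <- originDistanceStats(list(rec))
    expect_equal(sort(os$distances), c(1, 3))
    expect_equal(os$expectation, 2)
    osw <- originDistanceStats(list(rec), weighted = TRUE)
    expect_equal(osw$expectation, 0.9 * 1 + 0.1 * 3)

    ## pooling over cycles equals concatenation then histogram
    rec2 <- fakeRecord(list(pos, pos), list(c(0.9, 0.1), c(0.5, 0.5)))
    os2 <- originDistanceStats(list(rec2), nCyclesSample = 2)
    expect_equal(length(os2$distances), 4L)
    expect_equal(os2$expectation, 2)
})
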