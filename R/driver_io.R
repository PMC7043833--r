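## Simulation driver, configuration handling, JSON-lines run-record
## persistence, the synthetic early/late calibration-ensemble generator
## and the command-line interface.

#' Build and validate a run configuration
#'
#' @param resampler One of "revo", "wexplore", "conv".
#' @param nWalkers Number of walkers (held constant through the run).
#' @param nCycles Number of WE cycles.
#' @param seed Integer seed for the run's single RNG stream.
#' @param system List of random-walk parameters: nDims, pUp, stepsPerCycle.
#' @param revo List of REVO parameters: alpha, d0 (NA = estimate), pMin,
#'   pMax, mergeDistance, noveltyMode. Ignored unless resampler = "revo".
#' @param wexplore List of WExplore parameters: thresholds (coarsest
#'   first), maxChildren, pMin, pMax. Ignored unless resampler =
#'   "wexplore".
#' @param boundary NULL, or a list with \code{distance}: walkers whose
#'   scaled-Manhattan distance to the origin reaches it are warped back to
#'   the origin.
#' @param cycleDuration Simulated time per cycle (flux units; default 1).
#' @return Validated configuration list (class "weRunConfig").
#' @examples
#' runConfig("conv", nWalkers = 10, nCycles = 5, seed = 1)
#' @export
runConfig <- function(resampler = c("revo", "wexplore", "conv"),
                      nWalkers = 200L, nCycles = 1000L, seed = 1L,
                      system = list(), revo = list(), wexplore = list(),
                      boundary = NULL, cycleDuration = 1) {
    resampler <- match.arg(resampler)
    sys <- utils::modifyList(
        list(nDims = 2L, pUp = 0.25, stepsPerCycle = 10L), system)
    rv <- utils::modifyList(
        list(alpha = 4, d0 = NA_real_, pMin = 1e-100, pMax = 0.1,
             mergeDistance = 2.5, noveltyMode = "weight_based"), revo)
    wx <- utils::modifyList(
        list(thresholds = c(16, 4, 1, 0.25), maxChildren = 10L,
             pMin = 1e-100, pMax = 0.1), wexplore)
    cfg <- list(resampler = resampler, nWalkers = as.integer(nWalkers),
                nCycles = as.integer(nCycles), seed = as.integer(seed),
                system = sys, revo = rv, wexplore = wx,
                boundary = boundary, cycleDuration = cycleDuration)
    .validateConfig(cfg)
    class(cfg) <- c("weRunConfig", "list")
    cfg
}

.validateConfig <- function(cfg) {
    fail <- function(...) stop("invalid configuration: ", ...,
                               call. = FALSE)
    if (!cfg$resampler %in% c("revo", "wexplore", "conv"))
        fail("unknown resampler '", cfg$resampler, "'")
    if (cfg$nWalkers < 2) fail("need at least 2 walkers")
    if (cfg$nCycles < 1) fail("need at least 1 cycle")
    ## constructors run the class validity checks
    rwParams(cfg$system$nDims, cfg$system$pUp, cfg$system$stepsPerCycle)
    if (cfg$resampler == "revo")
        do.call(revoParams, cfg$revo)
    if (cfg$resampler == "wexplore") {
        if (any(diff(cfg$wexplore$thresholds) >= 0))
            fail("wexplore thresholds must be strictly decreasing")
        if (!(cfg$wexplore$pMin > 0 && cfg$wexplore$pMin <
              cfg$wexplore$pMax && cfg$wexplore$pMax <= 1))
            fail("need 0 < pMin < pMax <= 1")
    }
    if (!is.null(cfg$boundary) &&
        (is.null(cfg$boundary$distance) || cfg$boundary$distance <= 0))
        fail("boundary$distance must be a positive number")
    if (1 / cfg$nWalkers > if (cfg$resampler == "revo") cfg$revo$pMax
        else if (cfg$resampler == "wexplore") cfg$wexplore$pMax else 1)
        fail("initial uniform weight exceeds pMax")
    invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with any subset of the [runConfig()] arguments.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    known <- c("resampler", "nWalkers", "nCycles", "seed", "system",
               "revo", "wexplore", "boundary", "cycleDuration")
    bad <- setdiff(names(y), known)
    if (length(bad)) stop("unknown config fields: ",
                          paste(bad, collapse = ", "))
    do.call(runConfig, y)
}

#' Run a weighted-ensemble simulation
#'
#' Executes the full cycle loop (dynamics, optional boundary warping,
#' resampling) on the N-dimensional biased random walk with the configured
#' resampler. All randomness is drawn from one stream seeded with
#' \code{config$seed}, so identical configurations reproduce bit-identical
#' records. For REVO with \code{d0 = NA}, the characteristic distance is
#' first estimated as the mean pairwise walker distance after a single
#' dynamics cycle.
#'
#' @param config A configuration from [runConfig()] / [readRunConfig()].
#' @return A [RunRecord-class].
#' @export
runSimulation <- function(config) {
    .validateConfig(config)
    set.seed(config$seed)
    sysp <- rwParams(config$system$nDims, config$system$pUp,
                     config$system$stepsPerCycle)
    sys <- rwSystem(sysp)
    n <- config$nWalkers
    N <- sysp@nDims
    ens <- walkerEnsemble(matrix(0L, n, N))

    bc <- NULL
    if (!is.null(config$boundary)) {
        bd <- config$boundary$distance
        bc <- boundaryCondition(
            predicate = function(s) mean(abs(s)) >= bd,
            warpState = rep(0L, N))
    }

    d0 <- NA_real_
    params <- NULL
    hier <- NULL
    if (config$resampler == "revo") {
        params <- do.call(revoParams, config$revo)
        if (is.na(params@d0)) {
            probe <- sys$dynamics(ens@states)
            d0 <- estimateD0(sys$distanceMatrix(probe))
            params@d0 <- d0
        } else d0 <- params@d0
    } else if (config$resampler == "wexplore") {
        hier <- regionHierarchy(config$wexplore$thresholds,
                                sys$initialState,
                                config$wexplore$maxChildren)
    }

    nC <- config$nCycles
    positions <- vector("list", nC)
    weightsL <- vector("list", nC)
    resampling <- vector("list", nC)
    maxVisited <- matrix(0, nC, N)
    warps <- data.frame(cycle = integer(), walker = integer(),
                        weight = numeric())
    vTrace <- rep(NA_real_, nC)
    regionCounts <- rep(NA_integer_, nC)

    resampler <- switch(config$resampler,
        conv = function(e) convResample(e),
        revo = function(e) {
            res <- revoResample(e, sys$distanceMatrix(e@states), params)
            vTrace[e@cycleIndex] <<- res$vTotal
            res
        },
        wexplore = function(e) {
            hier <<- updateRegions(e, hier, sys$metric)
            res <- wexploreResample(e, hier, sys$metric,
                                    pMin = config$wexplore$pMin,
                                    pMax = config$wexplore$pMax)
            regionCounts[e@cycleIndex] <<- nRegions(hier)
            res
        })

    for (cy in seq_len(nC)) {
        out <- runCycle(ens, sys$dynamics, resampler, bc)
        ens <- out$ensemble
        pd <- do.call(rbind, out$postDynamics)
        maxVisited[cy, ] <- apply(pd, 2, max)
        positions[[cy]] <- do.call(rbind, ens@states)
        weightsL[[cy]] <- ens@weights
        resampling[[cy]] <- out$record
        if (nrow(out$warps)) warps <- rbind(warps, out$warps)
    }

    new("RunRecord", config = unclass(config), positions = positions,
        weights = weightsL, maxVisited = maxVisited,
        resampling = resampling, warps = warps, vTrace = vTrace,
        regionCounts = regionCounts, d0 = d0, hierarchy = hier)
}

#' Write a run record as JSON lines
#'
#' One JSON object per line: a config header, a meta line (d0, region
#' hierarchy snapshot when present), one line per cycle (positions,
#' weights, resampling operations, variation), and one line per warp
#' event. Weights are serialized at full precision, so a read-back is
#' bit-exact.
#'
#' @param record A [RunRecord-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeRunRecord <- function(record, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    emit <- function(x) writeLines(jsonlite::toJSON(
        x, digits = NA, auto_unbox = TRUE, null = "null", na = "null"),
        con)
    emit(list(type = "config", config = record@config))
    hier <- NULL
    if (!is.null(record@hierarchy) && is(record@hierarchy,
                                         "RegionHierarchy")) {
        h <- record@hierarchy
        hier <- list(thresholds = h@thresholds,
                     maxChildren = h@maxChildren, parent = h@parent,
                     level = h@level, images = h@images)
    }
    emit(list(type = "meta", d0 = record@d0, hierarchy = hier))
    for (cy in seq_along(record@positions)) {
        rec <- record@resampling[[cy]]
        emit(list(type = "cycle", cycle = cy,
                  positions = record@positions[[cy]],
                  weights = record@weights[[cy]],
                  maxVisited = record@maxVisited[cy, ],
                  ops = record@resampling[[cy]]@operations,
                  v = record@vTrace[cy],
                  nRegions = record@regionCounts[cy]))
    }
    for (r in seq_len(nrow(record@warps)))
        emit(c(type = "warp", as.list(record@warps[r, ])))
    invisible(path)
}

#' Read a run record written by [writeRunRecord()]
#'
#' @param path JSON-lines file.
#' @return A [RunRecord-class]; weights round-trip bit-exactly.
#' @export
readRunRecord <- function(path) {
    if (!file.exists(path)) stop("run record not found: ", path)
    lines <- readLines(path)
    objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    types <- vapply(objs, function(o) o$type, character(1))
    cfg <- objs[[which(types == "config")[1]]]$config
    meta <- objs[[which(types == "meta")[1]]]
    cyc <- objs[types == "cycle"]
    cyc <- cyc[order(vapply(cyc, function(o) o$cycle, numeric(1)))]
    nC <- length(cyc)
    N <- cfg$system$nDims
    toOps <- function(o) {
        if (is.null(o$ops) || length(o$ops) == 0 ||
            (is.data.frame(o$ops) && !nrow(o$ops))) return(.emptyOps())
        ops <- as.data.frame(o$ops)
        for (cl in c("src1", "src2", "tgt1", "tgt2", "kept"))
            ops[[cl]] <- as.integer(ops[[cl]])
        ops
    }
    positions <- lapply(cyc, function(o)
        matrix(as.integer(o$positions), ncol = N))
    weightsL <- lapply(cyc, function(o) as.numeric(o$weights))
    resampling <- lapply(cyc, function(o)
        new("ResamplingRecord", cycleIndex = as.integer(o$cycle),
            operations = toOps(o)))
    maxVisited <- do.call(rbind, lapply(cyc, function(o)
        as.numeric(o$maxVisited)))
    vTrace <- vapply(cyc, function(o)
        if (is.null(o$v)) NA_real_ else as.numeric(o$v), numeric(1))
    regionCounts <- vapply(cyc, function(o)
        if (is.null(o$nRegions)) NA_integer_
        else as.integer(o$nRegions), integer(1))
    wl <- objs[types == "warp"]
    warps <- if (length(wl))
        data.frame(cycle = vapply(wl, function(o) as.integer(o$cycle),
                                  integer(1)),
                   walker = vapply(wl, function(o) as.integer(o$walker),
                                   integer(1)),
                   weight = vapply(wl, function(o) as.numeric(o$weight),
                                   numeric(1)))
    else data.frame(cycle = integer(), walker = integer(),
                    weight = numeric())
    hier <- NULL
    if (!is.null(meta$hierarchy)) {
        hh <- meta$hierarchy
        imgs <- hh$images
        if (is.matrix(imgs))    # equal-length images simplify to a matrix
            imgs <- lapply(seq_len(nrow(imgs)), function(i)
                as.integer(imgs[i, ]))
        else imgs <- lapply(imgs, as.integer)
        hier <- new("RegionHierarchy",
                    thresholds = as.numeric(hh$thresholds),
                    maxChildren = as.integer(hh$maxChildren),
                    parent = as.integer(hh$parent),
                    level = as.integer(hh$level),
                    images = imgs)
    }
    new("RunRecord", config = cfg, positions = positions,
        weights = weightsL, maxVisited = maxVisited,
        resampling = resampling, warps = warps, vTrace = vTrace,
        regionCounts = regionCounts,
        d0 = if (is.null(meta$d0)) NA_real_ else as.numeric(meta$d0),
        hierarchy = hier)
}

#' Synthetic early/late calibration ensembles
#'
#' Generates walker ensembles emulating the two stages of an unbinding
#' simulation used to calibrate the distance exponent. "Early" ensembles
#' are compact — every pairwise distance below the characteristic distance
#' d0 and all weights close to uniform. "Late" ensembles are bimodal: a
#' small cluster of "unbound" walkers sits far from the main cluster
#' (pairs beyond 5 d0) carrying weights within a few orders of magnitude
#' of pMin. Distances come from points embedded in 3-D space, so the
#' matrix is symmetric, zero-diagonal and satisfies the triangle
#' inequality.
#'
#' @param kind "early" or "late".
#' @param nWalkers Ensemble size (default 48).
#' @param seed Integer seed.
#' @param d0 Characteristic distance of the emulated system (default 1).
#' @param pMin Minimum walker weight (default 1e-12).
#' @return List with \code{label}, \code{weights}, \code{dmat} and
#'   \code{d0}.
#' @export
generateCalibrationEnsembles <- function(kind = c("early", "late"),
                                         nWalkers = 48L, seed = 1L,
                                         d0 = 1, pMin = 1e-12) {
    kind <- match.arg(kind)
    set.seed(seed)
    n <- nWalkers
    if (kind == "early") {
        pts <- matrix(rnorm(n * 3, sd = 0.15 * d0), n, 3)
        dmat <- as.matrix(dist(pts))
        ## compact by construction: rescale so the widest pair sits at
        ## 0.9 d0
        dmat <- dmat * (0.9 * d0 / max(dmat))
        w <- runif(n, 0.8, 1.2)
        w <- w / sum(w)               # near-uniform, all > 1e-3 for n = 48
    } else {
        nFar <- max(2L, round(n / 6))
        near <- matrix(rnorm((n - nFar) * 3, sd = 0.3 * d0), n - nFar, 3)
        far <- matrix(rnorm(nFar * 3, sd = 0.5 * d0), nFar, 3)
        far[, 1] <- far[, 1] + 8 * d0
        dmat <- as.matrix(dist(rbind(near, far)))
        ## unbound walkers carry weights a few orders above pMin
        wFar <- 10^runif(nFar, log10(pMin) + 1, log10(pMin) + 3)
        wNear <- runif(n - nFar, 0.8, 1.2)
        wNear <- wNear * (1 - sum(wFar)) / sum(wNear)
        w <- c(wNear, wFar)
    }
    list(label = kind, weights = w, dmat = dmat, d0 = d0)
}

#' Command-line interface
#'
#' Subcommands: \code{run} (simulate from a YAML config and write a
#' JSON-lines record), \code{analyze} (compute a metric table from
#' records), \code{calibrate-alpha} (alpha scan on synthetic fixtures) and
#' \code{replay} (verify that every cycle's resampling record replays).
#' Invoked by the installed script \code{inst/scripts/we-cli.R}.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
weCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
    usage <- paste(
        "usage: we-cli.R <subcommand> [options]",
        "  run             --config cfg.yaml --out record.jsonl [--seed n]",
        "  analyze         --metric accuracy|range|profile|se|flux|origin",
        "                  [--out table.tsv] record.jsonl [...]",
        "  calibrate-alpha --fixtures [--alphas 1,2,3,4] [--seed n]",
        "                  [--out table.tsv]",
        "  replay          record.jsonl", sep = "\n")
    fail <- function(...) {
        message(...)
        message(usage)
        invisible(1L)
    }
    if (!length(args)) return(fail("no subcommand given"))
    sub <- args[1]
    rest <- args[-1]
    opt <- list()
    pos <- character(0)
    i <- 1L
    while (i <= length(rest)) {
        a <- rest[i]
        if (startsWith(a, "--")) {
            key <- substring(a, 3)
            if (key == "fixtures") {
                opt[[key]] <- TRUE
                i <- i + 1L
            } else {
                if (i == length(rest))
                    return(fail("missing value for --", key))
                opt[[key]] <- rest[i + 1L]
                i <- i + 2L
            }
        } else {
            pos <- c(pos, a)
            i <- i + 1L
        }
    }
    known <- c("config", "out", "seed", "metric", "alphas", "fixtures")
    if (length(bad <- setdiff(names(opt), known)))
        return(fail("unknown flag(s): ", paste(bad, collapse = ", ")))
    writeTSV <- function(df, out) {
        if (is.null(out)) {
            utils::write.table(df, stdout(), sep = "\t", quote = FALSE,
                               row.names = FALSE)
        } else {
            utils::write.table(df, out, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        }
    }
    res <- tryCatch({
        switch(sub,
        run = {
            if (is.null(opt$config)) return(fail("run: --config required"))
            if (is.null(opt$out)) return(fail("run: --out required"))
            cfg <- readRunConfig(opt$config)
            if (!is.null(opt$seed)) {
                cfg$seed <- as.integer(opt$seed)
                class(cfg) <- c("weRunConfig", "list")
            }
            rec <- runSimulation(cfg)
            writeRunRecord(rec, opt$out)
            message("wrote ", opt$out)
            0L
        },
        analyze = {
            if (is.null(opt$metric))
                return(fail("analyze: --metric required"))
            if (!length(pos))
                return(fail("analyze: at least one record required"))
            recs <- lapply(pos, readRunRecord)
            out <- switch(opt$metric,
                accuracy = {
                    acc <- accuracy(predictedProbability(recs))
                    tab <- acc$table
                    names(tab) <- c("x", "a_x")
                    attr(tab, "footer") <- sprintf("# total_A\t%.10g",
                                                   acc$total)
                    tab
                },
                range = {
                    rg <- samplingRange(recs)
                    data.frame(run = seq_along(rg$ranges),
                               range = rg$ranges,
                               mean = rg$mean, se = rg$se)
                },
                profile = {
                    pp <- predictedProbability(recs)
                    tab <- pp@profile
                    if (ncol(pp@perRun) > 1)
                        tab$se <- apply(pp@perRun, 1, sd) /
                            sqrt(ncol(pp@perRun))
                    tab
                },
                se = {
                    se <- runStandardError(predictedProbability(recs))
                    tab <- se$perX
                    attr(tab, "footer") <- sprintf("# average_se\t%.10g",
                                                   se$average)
                    tab
                },
                flux = {
                    fl <- fluxAndResidence(recs)
                    do.call(rbind, lapply(seq_along(fl$series),
                        function(r) if (nrow(fl$series[[r]]))
                            cbind(run = r, fl$series[[r]]) else NULL))
                },
                origin = {
                    os <- originDistanceStats(recs)
                    tab <- os$histogram
                    attr(tab, "footer") <- sprintf("# expectation\t%.10g",
                                                   os$expectation)
                    tab
                },
                return(fail("unknown metric: ", opt$metric)))
            writeTSV(out, opt$out)
            if (!is.null(attr(out, "footer"))) {
                if (is.null(opt$out)) cat(attr(out, "footer"), "\n")
                else cat(attr(out, "footer"), "\n", file = opt$out,
                         append = TRUE)
            }
            0L
        },
        `calibrate-alpha` = {
            if (!isTRUE(opt$fixtures))
                return(fail(
                    "calibrate-alpha: only --fixtures mode is available"))
            alphas <- if (is.null(opt$alphas)) 1:4
                      else as.numeric(strsplit(opt$alphas, ",")[[1]])
            seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
            ens <- c(
                lapply(seed + 0:4, function(s)
                    generateCalibrationEnsembles("early", seed = s)),
                lapply(seed + 5:9, function(s)
                    generateCalibrationEnsembles("late", seed = s)))
            tab <- alphaScan(ens, alphas = alphas,
                             params = revoParams(pMin = 1e-12))
            names(tab) <- c("label", "alpha", "mean_V", "sem_V")
            writeTSV(tab, opt$out)
            0L
        },
        replay = {
            if (length(pos) != 1)
                return(fail("replay: exactly one record required"))
            rec <- readRunRecord(pos[1])
            cfg <- rec@config
            class(cfg) <- c("weRunConfig", "list")
            fresh <- runSimulation(cfg)
            same <- identical(fresh@weights, rec@weights) &&
                identical(lapply(fresh@positions, as.integer),
                          lapply(rec@positions, as.integer))
            if (same) {
                message("record verified: ", length(rec@positions),
                        " cycles replay bit-identically from seed ",
                        cfg$seed)
                0L
            } else {
                message("record FAILED replay verification")
                1L
            }
        },
        return(fail("unknown subcommand: ", sub)))
    }, error = function(e) {
        message("error: ", conditionMessage(e))
        1L
    })
    invisible(as.integer(res))
}
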