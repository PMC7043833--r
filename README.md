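# revo

Weighted-ensemble (WE) enhanced sampling with the region-free **REVO**
resampler (resampling of ensembles by variation optimization), a reference
**WExplore** resampler built on hierarchical Voronoi regions, an
N-dimensional biased random-walk benchmark with an analytic target
distribution, and the analysis suite needed to score them: predicted
probability profiles, accuracy, sampling range, run-to-run standard error,
and unbinding flux / residence-time estimation via boundary-condition
warping.

It is aimed at people studying rare events — ligand unbinding, barrier
crossings — who want a tested, deterministic, pure-R implementation of the
WE resampling layer itself: the dynamics engine is pluggable and the
built-in lattice benchmark makes every algorithmic claim checkable against
closed forms.

## The method in brief

A WE simulation alternates dynamics and resampling over an ensemble of
walkers, each a conformation plus a statistical weight. Cloning replaces a
walker by two half-weight copies; merging replaces two walkers by one with
the summed weight whose conformation is kept with probability proportional
to weight. Neither operation biases ensemble averages.

REVO chooses what to clone and merge by greedily maximizing the trajectory
variation

    V = Σ_i Σ_j (d_ij / d0)^α  φ_i φ_j,      φ_i = ln(w_i) − ln(p_min/100)

where `d_ij` is the pairwise walker distance, `d0` the characteristic
distance (mean pairwise distance after one dynamics cycle), `α` the
distance exponent, and `φ_i` a logarithmic weight novelty. Each iteration
clones the highest-variation eligible walker and merges the
lowest-variation walker with its nearest legal partner, keeping the move
only if `V` strictly increases. Weights are confined to `[p_min, p_max]`
and total weight is conserved exactly.

The package also implements the distance-exponent calibration: evaluating
mean variation of "early" (compact, high-weight) versus "late" (containing
far, low-weight walkers) ensembles across `α = 1..4`, the exponent that
cleanly separates the two is suitable for rare-event work.

## Worked example

```r
library(revo)

cfg <- runConfig("revo",
                 nWalkers = 48, nCycles = 500, seed = 1,
                 system = list(nDims = 2))
rec <- runSimulation(cfg)

rec@d0
#> [1] 0.8807624

pp <- predictedProbability(list(rec))
head(profileTable(pp), 5)
#>   x       P
#> 1 0 0.66677
#> 2 1 0.22205
#> 3 2 0.07281
#> 4 3 0.02418
#> 5 4 0.00979

accuracy(pp)$total
#> [1] 12.95682
samplingRange(list(rec))$mean
#> [1] 22.5
```

The characteristic distance 0.88 was estimated from one dynamics cycle of
the 48-walker ensemble. The estimated positional distribution tracks the
analytic target `P(x) = (2/3)(1/3)^x` closely near the origin (target
values 0.6667, 0.2222, 0.0741, ...), the accuracy sums per-position
contributions that peak at 1 where the estimate equals the target (12.96
here across the estimated support), and the walk reached an average
largest position of 22.5 per dimension — far beyond what the biased,
unresampled walk visits in the same number of steps.

The exponent calibration on synthetic early/late fixtures:

```r
early <- lapply(1:3, function(s) generateCalibrationEnsembles("early", seed = s))
late  <- lapply(4:6, function(s) generateCalibrationEnsembles("late",  seed = s))
alphaScan(c(early, late), params = revoParams(pMin = 1e-12))
#>   label alpha     meanV      semV
#> 1 early     1 1.814e+06 3.790e+04
#> 2  late     1 5.610e+06 1.350e+05
#> 3 early     2 2.117e+06 9.400e+04
#> 4  late     2 7.584e+07 2.543e+06
#> 5 early     3 2.762e+06 1.828e+05
#> 6  late     3 1.505e+09 6.582e+07
#> 7 early     4 3.929e+06 3.373e+05
#> 8  late     4 3.145e+10 1.718e+09
```

The late/early separation grows with `α`, which is what makes the higher
exponent the right choice for driving unbinding-style transitions.

A command-line driver wrapping the same functions is installed at
`inst/scripts/we-cli.R` with subcommands `run`, `analyze`,
`calibrate-alpha` and `replay`; see `?weCLI`.

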