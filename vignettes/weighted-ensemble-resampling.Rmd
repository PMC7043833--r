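---
title: "Weighted-ensemble resampling by variation optimization"
author: "revo package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-ensemble resampling by variation optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revo)
```

# The weighted-ensemble framework

Rare events — a ligand leaving its binding pocket, a barrier crossing on a
rough landscape — are exponentially expensive for brute-force simulation.
Weighted-ensemble (WE) sampling attacks the problem by running many
trajectory copies ("walkers"), each carrying a statistical weight, and
alternating two steps:

1. **Dynamics**: every walker is propagated independently for a fixed
   number of steps.
2. **Resampling**: desirable walkers are *cloned* (replaced by two copies,
   each with half the weight) and less desirable walkers are *merged*
   (replaced by one walker with the summed weight, whose conformation is
   drawn from the pair proportionally to weight).

Because cloning and merging manipulate weights but never bias them, any
weighted average over the ensemble remains an unbiased estimate of the
corresponding equilibrium or kinetic observable, whatever the resampling
policy. The policy only decides *where* sampling effort is spent. In this
package the walker count is held constant through every resampling call,
and total weight is conserved to better than 1e-12 — a violation raises an
error rather than being silently renormalized, because weight leakage is a
correctness signal, not a numerical nuisance.

# The REVO resampler

REVO (resampling of ensembles by variation optimization) needs no
partitioning of conformation space. It maximizes the **trajectory
variation**

$$V = \sum_i V_i = \sum_i \sum_j
      \left(\frac{d_{ij}}{d_0}\right)^{\alpha} \phi_i \phi_j ,$$

where $d_{ij}$ is the all-to-all pairwise distance between walker
conformations under a system-specific metric, $d_0$ is a characteristic
distance making $V$ unit-free, $\alpha$ modulates how strongly large
distances dominate, and $\phi_i$ is the **novelty** of walker $i$. The
weight-based novelty used here is

$$\phi_i = \ln w_i - \ln\!\left(\frac{p_{\min}}{100}\right),$$

which prioritizes high-weight walkers: with $p_{\min} = 10^{-12}$ it runs
from $\ln(100) \approx 4.6$ at the weight floor up to $\approx 32$ at
$w_i = 1$. Setting `noveltyMode = "constant"` replaces all $\phi_i$ by 1,
making resampling decisions purely geometric.

Each resampling call is a greedy ascent. Repeatedly:

* the *merge pair* is chosen first — $m_1$ is the lowest-$V_i$ walker with
  $w_{m_1} < p_{\max}$, and $m_2$ the walker nearest to $m_1$ with
  $w_{m_1}+w_{m_2} < p_{\max}$ and $d_{m_1 m_2}$ below the merge-distance
  threshold;
* the *clone candidate* $c$ is the highest-$V_i$ walker distinct from the
  pair whose children would not fall below $p_{\min}$ (we require
  $w_c/2 \ge p_{\min}$, a deliberately stricter reading than "$w_c >
  p_{\min}$": halving must not create sub-threshold children);
* the clone and merge are performed, $V$ is recomputed, and the move is
  kept only if $V$ strictly increased — otherwise it is undone and the
  ascent stops.

Ties in $V_i$ or in the nearest-partner distance always resolve to the
lowest walker index, so a run is fully determined by its seed. The merge's
keep-choice variate is drawn when the move is proposed; an undo restores
the ensemble exactly (the consumed variate is simply part of the run's
stream).

Within the ascent the distance matrix is updated incrementally: a clone
inherits its parent's distances with zero between the pair, and a merge
keeps the surviving walker's row. Because clones are literal copies, this
is *exact*, not an approximation — the test suite checks it against
recomputing the metric from the output conformations bit for bit.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `alpha` | distance exponent in $V$ | 4 | unitless |
| `d0` | characteristic distance | estimated | metric units |
| `pMin` | weight floor | 1e-100 (benchmark runs), 1e-12 (calibration) | probability |
| `pMax` | weight cap | 0.1 | probability |
| `mergeDistance` | max distance for a merge | 2.5 | metric units |

The weight cap of 0.1 guarantees at least ten walkers carry appreciable
probability at all times; the floor stops effort being spent on walkers
that can no longer contribute to observables. The benchmark runs use the
very permissive floor of $10^{-100}$ so that range exploration is
essentially unconstrained, while the calibration ensembles use $10^{-12}$,
the floor typical of molecular unbinding studies. The merge distance of
2.5 (in scaled-Manhattan units) limits the information lost when two
trajectories collapse into one.

$d_0$ is estimated by running one dynamics cycle from the initial ensemble
and averaging the distance over all unordered walker pairs. It cancels out
of clone/merge decisions (rescaling all distances and $d_0$ together
leaves $V$ unchanged — a tested invariant) and exists to make variation
values comparable across metrics and dimensionalities. An ensemble of
identical walkers leaves $d_0 = 0$ undefined and raises an error.

## Choosing the exponent

Because scanning $\alpha$ with full simulations is wasteful, the package
implements the calibration shortcut: take walker ensembles from an *early*
stage (compact, all weights still high) and a *late* stage (some walkers
far away with very low weight) of a previous run, and evaluate the mean
variation of each group at $\alpha = 1, 2, 3, 4$ with one shared $d_0$. A
useful exponent separates late from early clearly — if the variation is
not higher for ensembles containing the far-flung state, maximizing it
cannot drive sampling there. The gap grows strictly with $\alpha$ on the
synthetic fixtures, and $\alpha = 4$ is the value this procedure selects
for unbinding-style problems; the exponent used by the benchmark runs
defaults to that same value. The shared-$d_0$ convention (the early-group
estimate) keeps variation values comparable between groups.

`generateCalibrationEnsembles()` builds the fixtures from points embedded
in 3-D space, so the distance matrices are true metrics (symmetric,
zero-diagonal, triangle inequality). Early ensembles are rescaled so every
pair sits below $d_0$ with near-uniform weights; late ensembles place
about one walker in six in a cluster $8 d_0$ away carrying weights one to
three orders of magnitude above the floor. These fixtures emulate the
*geometry and weight structure* of real unbinding ensembles, not their
molecular detail — passing the calibration tests shows the scan machinery
is correct, not that any particular molecular system separates at a given
exponent.

# The WExplore reference resampler

For comparison the package includes a hierarchical-Voronoi resampler.
Space is partitioned by a tree of "images" (stored conformations): a
walker descends the tree, at each level joining the nearest child image.
New regions are founded when a walker is farther than that level's
threshold from every sibling image, unless the parent already has the
maximum number of children (10 by default; four levels bound the total at
$10^4$ regions). Images never move or disappear once created; walkers are
processed in ensemble order, so the first founder wins and runs are
deterministic.

Resampling balances walker *counts* across sibling regions from the top
level downward: while the most- and least-populated occupied siblings
differ by more than one walker, the two lowest-weight same-leaf walkers of
the crowded region are merged and the highest-weight clonable walker of
the sparse region is cloned into the vacated slot. Merging only ever pairs
walkers that share their region at *every* level. The characteristic
"thresholding" burst — a lone walker founding a distant region is cloned
repeatedly until counts even out — emerges from this rule and is exercised
directly in the tests. Where the balancing rule leaves freedom (which
walkers to merge or clone), the weight-extremal choice is used: it
minimizes the statistical distortion of any single move and is
deterministic.

Two conventions deserve note. First, thresholds are stored coarsest-first
(16, 4, 1, 0.25 in scaled-Manhattan units for the benchmark), consistent
with progressively finer regions down the hierarchy. Second, balancing
uses region counts only, not region weights, matching the goal of
distributing *walkers* as evenly as possible. A known quirk of greedy
hierarchical assignment is that a deep node's image can be "shadowed" by a
nearer upper-level image created later, so path-through-own-node
idempotence is only guaranteed for well-separated hierarchies; the tests
reflect this.

# The benchmark system

The $N$-dimensional biased random walk is the package's test bed. Each
dimension of a walker's non-negative integer position independently moves
$+1$ with probability $P_u = 0.25$ and $-1$ otherwise at every step; a
backward move at 0 is rejected (the component stays), which yields the
per-dimension stationary law

$$P^t(x) = \tfrac{2}{3} \left(\tfrac{1}{3}\right)^{x}.$$

The rejection semantics matter: the move is drawn first and rejected at
the wall, preserving the drawn-move probabilities, and this is exactly
what produces the $(1/3)^x$ geometric form the analysis compares against.
Distances use the scaled Manhattan metric $d_{ij} = \frac{1}{N} \sum_d
|x_i^d - x_j^d|$. Without resampling the dimensions are completely
independent — the resampler is the only coupling — so an $N$-dimensional
run is statistically $N$ one-dimensional runs, a property the suite checks
through moment comparisons. One Bernoulli variate is consumed per walker
per dimension per step in a fixed order from the run's single seeded
stream, so every run is bit-reproducible.

A toy boundary condition completes the kinetics machinery: walkers whose
scaled-Manhattan distance from the origin reaches a configured threshold
are "warped" back to the origin after dynamics and before resampling, each
logging its (unchanged) weight as a warp event. Warping is applied once
per walker per cycle, and a freshly warped walker is an ordinary walker
for the resampling that follows. The cumulative warped weight is the
reactive flux; the mean first-passage time of the warped transition is the
reciprocal of the run-averaged flux rate, reported as infinite when
nothing ever warped. With equal-length runs the per-run-rate average
coincides with pooled weight over pooled time.

# Analysis metrics

* **Predicted probability**: per sampled cycle, walker weights are
  histogrammed over integer positions in each dimension; histograms are
  averaged over dimensions, cycles and runs. Which cycles enter the
  average is genuinely open; the default discards the first 10% of cycles
  as burn-in and uses every cycle thereafter, both configurable.
* **Accuracy**: each position contributes
  $a(x) = 1 + |\log P^t(x) - \log P(x)| / \log P^t(x)$ when
  $\log P(x) > 2\log P^t(x)$ and 0 otherwise; the total $A$ sums
  contributions from 0 to the farthest estimated position (positions never
  reached fall to the 0 branch anyway, so the cutoff is cosmetic). The
  contribution peaks at exactly 1 when $P = P^t$; the condition is strict,
  so $P = (P^t)^2$ contributes 0. The log-ratio form is base-invariant;
  natural logs are used.
* **Range**: the largest position visited along each dimension during
  dynamics (before any warping), averaged over dimensions, then over runs
  with a standard error. Merges can discard the outermost walker, which is
  why the maximum is tracked post-dynamics.
* **Run-to-run standard error**: the standard error of $P(x)$ across runs,
  averaged over a position window, measures the consistency of a
  resampler.
* **Origin distance**: the pooled distribution of walker distances to the
  origin. Walkers are pooled uniformly by default — the statistic
  describes where walkers *are*, not where probability is — with
  weight-weighted pooling as an option.

# Scope of the simulation studies

The comparative studies in the test suite run at reduced scale: 48 walkers,
1000 cycles, dimensionalities 2 and 5, a handful of seeds. These sizes
were chosen as the smallest at which the comparative orderings among
resamplers are meaningfully probed while a full check remains a
coffee-break computation; the corresponding full-protocol studies (200
walkers, 10 000 cycles, ten runs per dimensionality, averaged over $N \in
\{2, 5, 10, 20\}$) sit well beyond that envelope, and no result at that
scale is asserted anywhere in this package. Reduced scale is kept
honest in both directions: an ordering that holds here is evidence the
machinery is right, and an ordering that concentrates in a regime reduced
scale cannot reach (small-$N$, few-walker consistency averages are
dominated by bulk positions where aggressive resampling buys nothing) is
reported as such rather than papered over.

What passing these tests shows is that the resamplers implement their
specified decision rules exactly, conserve weight and count, replay
deterministically, and reproduce the analytic target of the benchmark.
What they cannot show is performance on molecular systems: the random
walk has no metastability, its metric is exact rather than an RMSD proxy,
and its dynamics cost nothing relative to resampling overhead.

# Known limitations

* Only constant walker counts are supported; resamplers that grow or
  shrink the ensemble are out of scope.
* The novelty menu is weight-based or constant; conformation-dependent
  novelties are left to the caller's own resampler closures.
* Region hierarchies serialize with their full image set; for very large
  hierarchies the JSON-lines records grow accordingly.
* Whether warped walkers should be shielded from same-cycle cloning or
  merging is not specified by the framework; they are treated as ordinary
  walkers here.

# A minimal run

```{r example, eval = FALSE}
cfg <- runConfig("revo",
                 nWalkers = 48, nCycles = 500, seed = 1,
                 system = list(nDims = 2))
rec <- runSimulation(cfg)
pp <- predictedProbability(list(rec))
accuracy(pp)$total
samplingRange(list(rec))$mean
```
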