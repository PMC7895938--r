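---
title: "Tempo and mode of thermal-limit evolution: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tempo and mode of thermal-limit evolution: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(thermevol)
```

## The scientific question

Upper and lower thermal tolerance limits (CTmax/CTmin in ectotherms, lethal
limits in plants and algae, thermoneutral-zone edges in endotherms) need not
evolve at the same pace or under the same regime. `thermevol` packages the
comparative machinery for asking, on a time-calibrated phylogeny:

* **Tempo** — how fast does each limit evolve? Measured by the Brownian rate
  `sigma2` in degC^2 per Mya.
* **Mode** — under what regime? Compared across Brownian motion (BM, an
  unconstrained random walk), Ornstein-Uhlenbeck (OU, a walk with an
  attractor of strength `alpha`, summarized as `-log alpha`), and white
  noise (WN, phylogeny-free variation about a global mean).
* **Deep-time climate legacies** — do species from orders that originated
  under glaciated palaeoclimates tolerate colder temperatures today?
* **Predictor importance** — how much do current climate, clade age and
  palaeoclimate origin each explain of present-day limits, via a
  random-forest regressor?

## The trait models and their likelihoods

For a rooted tree with branch lengths in Mya, tip depths `d_i` and shared
root-to-MRCA times `t_a(i,j)`, the three models are Gaussian:

* **BM** — mean `z0` (root state), covariance `sigma2 * C` with
  `C[i,j] = t_a(i,j)`. The tips' variance grows linearly with time.
* **OU** (fixed root, single stationary peak) — mean `z0`, Hansen
  covariance
  `V[i,j] = sigma2/(2 alpha) (1 - e^{-2 alpha t_a}) e^{-alpha (d_i + d_j - 2 t_a)}`.
  As `alpha -> 0` this tends to the BM covariance; as `alpha` grows the
  phylogenetic correlation decays and the tip variance saturates at the
  stationary value `sigma2 / (2 alpha)`.
* **WN** — iid `Normal(mu, sigma2)`; the null model in which phylogeny
  carries no signal.

The BM log-likelihood is evaluated by two mutually checking paths — a dense
multivariate-normal path and a Felsenstein pruning (contrasts) recursion —
which the test-suite holds to within 1e-8 of each other on random trees.

### Maximum likelihood

WN and BM have closed-form MLEs via generalized least squares:
`z0 = (1'C^{-1}x)/(1'C^{-1}1)` and `sigma2 = r'C^{-1}r / n`. The variance
MLE uses denominator `n` (not `n-1`): likelihoods must be comparable across
models, so all three are maximized, not REML-estimated. For OU, `(z0,
sigma2)` are profiled in closed form at each candidate `alpha` and the
profile is optimized over `log(alpha)` with bounded L-BFGS-B from five
jittered equally spaced starts; both interval endpoints are always
evaluated as additional candidates. Fits are deterministic given the
options seed.

### The OU optimum

The optimum `theta` is constrained equal to the root state `z0` (the
single-stationary-peak model, `k = 3` parameters). On ultrametric trees
`theta` and `z0` are only weakly jointly identifiable, and the analyses
this package supports report only `alpha`; freeing `theta` would add an
ill-constrained parameter without changing the reported quantities.

### Numerical choices

* `alpha` is searched in `[1e-9/T, 100/T]`, where `T` is tree depth. The
  shared-time factor `(1 - e^{-2 alpha t})/(2 alpha)` is evaluated with
  `expm1`, so the lower end of the interval reproduces the BM covariance
  to near machine precision. The lower bound is deliberately small enough
  that the nesting guarantee `lnL(OU) >= lnL(BM) - 1e-6` holds: at a looser
  bound such as `1e-6/T` the covariance truncation error (relative size
  about `alpha * T`) can exceed that tolerance on a few hundred tips.
* `-log alpha` uses the natural logarithm; this choice is recorded in every
  fit (`logBase`).
* `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` is reported alongside raw `lnL`.
  Models are ranked by both; the likelihood ranking is the headline, AICc
  the parsimony check (they can disagree, since OU spends one more
  parameter).
* Non-ultrametric trees are accepted by all three models (the fixed-root
  Hansen covariance is valid generally); ultrametricity is reported by
  `checkUltrametric()` (relative tip-depth deviation, default tolerance
  1e-3), not enforced.
* Coincident zero-distance tips make the covariance singular; this is
  raised as an explicit error, not smoothed over.
* Within-species measurement variance is not modelled; duplicate records
  for a species are averaged (and logged) before fitting.

### Identifiability window for `alpha`

`alpha` is well estimated only when `alpha * T` is roughly in `[0.5, 5]`.
Below that window the data cannot distinguish OU from BM (the estimate runs
to the lower search bound, and `-log alpha` reflects the bound, flagged via
`atLowerBound`); far above it, only the stationary variance
`sigma2/(2 alpha)` is identified. The multi-tree summaries make this
visible: across posterior trees the spread of `-log alpha` is small when
the data are informative and explodes at the bounds.

### Tempo across tree variants, and multi-tree summaries

Chronograms for the same taxa differ with the rate-smoothing used to date
them. `tempoSigma2()` therefore reports the arithmetic mean of the BM
`sigma2` MLEs across the supplied tree variants (typically a smoothed and
an unsmoothed chronogram). `summarizeOverTrees()` refits one model across a
tree set (e.g. 100 posterior chronograms) and reports per-parameter mean
and standard deviation (denominator `nTrees - 1`; zero for a single tree).

## Ancestral states and traitgrams

`reconstructBM()` computes, for every internal node, the conditional
expectation and variance of its state given the tip values under the
*fitted* BM model (plug-in `sigma2`), from the partitioned joint Gaussian
over tips and internal nodes. The root's conditional mean is exactly the
GLS `z0`. Uncertainty is this analytic conditional variance, not a
resampling band: it is deterministic and directly testable against the
partitioned-Gaussian formula. Traitgram geometry (`traitgramSegments()`)
is one segment per edge on a Mya-before-present axis. OU ancestral states
are not provided: the traitgram convention in comparative work is BM, and
under the fitted OU regimes the reconstruction would be dominated by the
attractor rather than the data.

## Palaeoclimate origin

Orders are assigned one of four categories — full glaciation, partial
glaciation, partial warm, warm — by where their origination age falls in an
era table, then collapsed to cold-origin (the two glaciation categories)
versus warm-origin (the two warm ones). Intervals are half-open on the
young side: an age exactly on a boundary belongs to the older interval.

The era boundary dates are **configuration, not science shipped by the
package**: `defaultEraTable()` is an illustrative coarse sketch of the
icehouse/greenhouse alternation over the last 541 Mya and is documented as
user-supplied; any analysis tied to a specific palaeoclimate
reconstruction must provide its own table.

The cold-versus-warm contrast reports R-convention boxplot statistics
(type-7 interpolated quartiles; whiskers to the most extreme values within
1.5 IQR *of the quartiles* — the standard `boxplot` rule, which we follow
even though it is occasionally described informally as "from the median")
and a two-sided permutation test of the difference in class medians,
`p = (1 + #{|d_perm| >= |d_obs|}) / (nPerm + 1)`. The permutation test is
this package's explicit, documented choice of distribution comparison; it
is calibrated (type-I error at 0.05 within [0.035, 0.065] in the test
suite) and deterministic given its seed.

## Random-forest importance

The importance model is a *regression* forest — thermal limits are
continuous — with 500 trees by default, `ceiling(p/3)` candidate predictors
per split and bootstrap samples of size `n`. Importance is node purity
(total split-wise variance reduction credited to each predictor),
normalized to percent of the total so the three predictors sum to 100%.
Accuracy is out-of-bag R^2. Confidence intervals come from repeated refits
under derived seeds (percentile 2.5/97.5 across >= 30 refits) — a
documented choice, since no single convention exists for forest-importance
uncertainty. Predictors are exactly three: current temperature (tmax for
upper limits, tmin for lower — the pairing rule), order age, and the
palaeoclimate category encoded ordinally by warmth (one-hot available via
`encoding = "onehot"`). Realm, metric type and latitude are deliberately
not predictors in the default model.

## What the synthetic generator emulates — and what it does not

`simulateGlobtherm()` produces a dataset with the statistical structure the
analyses assume, with every ground-truth parameter stored:

* a Yule (pure-birth) chronogram — `birthRate = 0.015`/Mya at `nTips =
  200` gives depths of a few hundred Mya, the scale of order-level
  chronograms. Pure birth is the simplest ultrametric generator; real
  trees' extinction-driven branch-length structure is not emulated.
* taxonomic orders as the monophyletic clades crossing the time slice at
  which exactly `nOrders` lineages exist (default 25 at 200 tips, about
  one order per eight species, the granularity of curated thermal-limit
  compilations), dated by their crown node (stem for singletons).
* latent upper and lower limits evolving under configurable BM/OU/WN.
  Defaults: BM with `sigma2 = 0.5`, root 40 degC (upper) and `sigma2 =
  2.0`, root -10 degC (lower) — lower limits evolving faster, with
  CTmax/CTmin-like root states.
* a latitudinal climate gradient (`tmax = 38 - 0.35|lat|`, `tmin = 22 -
  0.7|lat|`, plus noise) coupled additively into the limits (0.3 degC per
  degC of centred environment), so the "current climate" signal in the
  importance analysis is tunable.
* `upper > lower` enforced by redrawing the whole trait stage from a fresh
  substream (per-species resampling would break the tree-wide trait
  correlation); the attempt count is part of the stored ground truth.

Passing tests on these data show that the estimators recover the
generating process **under the model's own assumptions**. They do not show
robustness to what real thermal-limit compilations add: measurement error
and protocol heterogeneity, taxonomic misassignment, spatially structured
sampling gaps, correlated upper/lower measurement pairs, or trees whose
branch lengths are themselves estimates.

## Problem sizes used in the shipped checks

The package's statistical checks run at sizes chosen to make the
properties sharp while staying desk-scale: likelihood-path equivalence on
100 random trees of up to 12 tips; rate recovery on 100 replicates of
200-tip Yule trees (median `sigma2` error well under 15%); OU-vs-BM model
selection on 100 replicates at `alpha * T = 2` (inside the identifiability
window); the tempo asymmetry on 20 generator replicates; permutation-test
calibration over 1000 null contrasts; forest-importance ranking over 100
seeded refits. The pipeline determinism check re-runs a full analysis from
its manifest and requires bit-identical outputs.

## Known limitations

* Single-optimum OU only; no multi-peak OU, early-burst, or branch-length
  transforms, and no Bayesian fitting.
* No measurement-error term in the likelihoods.
* Name matching is exact after case-folding and underscore/space
  normalization; synonym resolution belongs upstream.
* The default era table is illustrative; conclusions about palaeoclimate
  origin are only as good as the supplied dating.
* `-log alpha` at the search bounds means "no attraction detectable", not
  an estimate; check `atLowerBound`/`atUpperBound` in the fit diagnostics.
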