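---
title: "Filtered, stability-regularized symbolic regression for QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtered, stability-regularized symbolic regression for QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Matched molecular series — sets of analogues sharing a core scaffold and
differing at one substituent site — are a natural unit for local QSAR
modelling: the potency change within a series is driven by the substituent
alone, so a handful of substituent descriptors (aromatic ring count, logP,
rotatable bonds, TPSA, van der Waals volume, molecular weight, H-bond
donor/acceptor counts, heavy atoms, ring count) can explain pKi. Such
series are small (tens of compounds), which rules out flexible black-box
models and puts a premium on simple, *interpretable* equations. Symbolic
regression by genetic programming (GP) searches the space of closed-form
expressions directly, but plain GP on small potency sets has two chronic
failure modes:

* **divergence** — expressions that fit the observed compounds but blow up
  (a pole, an exploding exponential) somewhere inside the chemically
  accessible descriptor range;
* **overfitting** — expressions whose output moves violently under tiny
  changes of descriptors or coefficients.

`figp2` implements a GP in which both failure modes are attacked
explicitly, plus the benchmarking protocol used to judge it.

## The search

An individual is an expression tree over the operators
`+ − × ÷ sqrt square cube exp ln`, descriptor variables, and real
constants. A single terminal has depth 0; trees are capped at depth 4.
The loop is generational: tournament selection (size 5), subtree
crossover (p = 0.7), subtree mutation with fresh subtrees of depth 0–2
(p = 0.2), reproduction otherwise; population 200 for 200 generations in
the standard configuration. Elitism of one — the all-time best
filter-passing individual survives — makes the best fitness
non-increasing, which the tests exploit as an invariant. Given a seed,
a run is fully deterministic.

**Constants are not searched by evolution.** At every fitness
evaluation the tree's constants are refined by damped least squares
(Levenberg–Marquardt via `minpack.lm`) against the training data,
started from the tree's current constants. Rows where the candidate
evaluates invalidly contribute a large finite penalty residual (10^6)
so the optimizer is steered out of invalid regions. If that first fit
ends no better than predicting the training mean — which happens for
roughly half of random starts on division structures such as
`c1*logp + c2/(tpsa + c3)`, whose loss surface has a pole-crossing
barrier — one deterministic extra fit is started from all constants
equal to 1 (scale-neutral, pole-avoiding at typical non-negative
descriptor values) and the better result is kept. The fit never
worsens a tree: on failure the incoming constants stand.

## The filters

* **V-filter**: every variable may appear at most once anywhere in the
  tree. This is the strict whole-tree reading; a weaker per-term reading
  exists but is not implemented.
* **F-filter**: no operator may be nested under another operator of the
  same group, with groups `{sqrt}`, `{square, cube}`, `{ln, exp}`;
  `sqrt(sqrt(x))` and `ln(1 + exp(x))` fail, `x^2 + y^3` passes.
* **D-filter** (sample-based): outputs on a large probe set (by default
  10,000 uniform points in a box 1.5× the training span) must be valid
  and inside the target range. A pole between probes slips through.
* **D2-filter** (optimization-based): the expression's minimum and
  maximum over the descriptor box are estimated by five bounded
  L-BFGS-B searches per direction, started from training rows (clipped
  into the box, uniform in the box when no data are supplied), and the
  whole estimated range must lie inside the target range. An invalid
  operation encountered at any in-box query point makes the expression
  uncertifiable and rejects it. This closes the D-filter's gap at the
  cost of local (not certified-global) optimization, mirroring the
  multi-start scheme of the method; interval arithmetic is a non-goal.

The domain box and target range default to per-column min/max of the
training split (`domain_spec_from_data`). Deriving them from training
*plus test* data is supported but flagged as information leakage in the
spec's `source` field; user-supplied, chemically motivated boxes (e.g.
logp in [−1, 5]) are the recommended practice for production models.
Containment is checked with a symmetric slack of 5% of the target-range
width (`d2_slack`): with noisy y, the observed range *underestimates*
the generating function's range, and exact containment would reject the
true model for a discrepancy of the order of the noise. The slack is a
fixed package default, not a tuning knob.

During evolution, offspring failing a structural filter are re-bred
from the same parents (up to 50 attempts, then a parent is copied
through); offspring failing an active domain filter after constant
fitting are discarded and bred anew, and after the attempt budget the
slot takes a fresh random structurally valid tree, kept at
worst-possible fitness if it still fails. Filters also act at
initialization: every founding individual must pass the active filters
(the domain filters are applied to the *fitted* tree, so the certified
range is that of the expression that actually enters the population).

## The stability penalty

For a fitted expression `f(x; c)`, the descriptor-perturbation metric
`STBL_x` is the root-mean-square displacement between `f(x; c)` and
`f(x + δx; c)` over training rows, with every feature perturbed
simultaneously by `δx = 0.1 × std(x)` (training standard deviation,
denominator n−1; a zero-variance feature gets δ = 0). The
coefficient-perturbation metric `STBL_c` perturbs every constant by
`δc = 0.1 × |c|`. The magnitudes come from the method's standard
settings; since magnitudes do not fix signs, the package uses the
deterministic symmetric realization — the mean of the +δ and −δ
displacements — so that fitness, and hence selection, is reproducible.
A seeded stochastic variant (random sign vectors) is available through
`n_random_signs` for sensitivity checks. If a perturbed evaluation is
invalid at a row, that row's displacement is charged as the
target-range width: an expression that cannot leave the sample is
exactly what the penalty exists to punish.

Closed forms anchor the implementation: for `f = c1·x`,
`STBL_x = 0.1·|c1|·std(x)` and `STBL_c = 0.1·|c1|·sqrt(mean(x²))`;
both metrics scale linearly with the tree's output. Note that a lone
constant tree has `STBL_x = 0` but `STBL_c = 0.1·|c|` — its only
coefficient is perturbed like any other.

The four fitness metrics are `FITNESS_0 = RMSE`,
`FITNESS_X = RMSE + λx·STBL_x`, `FITNESS_C = RMSE + λc·STBL_c`, and
`FITNESS_XC = RMSE + λx·STBL_x + λc·STBL_c`, with weights (1, 1) for
the single-penalty metrics and (0.5, 0.5) for `FITNESS_XC`; lower is
better, and a λ-sweep grid (0.01–1) is supported in the configuration.
The method presets are `GP` (no filters, RMSE), `FIGP` (V, F, D, RMSE),
`FIGP2_D2` (V, F, D2, RMSE) and `FIGP2` (V, F, D2, `FITNESS_XC`).

## The synthetic-data generator

`generate_synthetic()` draws descriptors uniformly over a per-feature
box and adds Gaussian noise to a known ground-truth expression. Three
built-in truths exercise the operator groups: linear
(`0.5*logp + 6.9` over logp ∈ [−1, 5]), rational
(`0.5*logp + 2/(tpsa + 1)` over logp ∈ [−1, 5], tpsa ∈ [0, 60] — a
typical substituent TPSA span, chosen so the rational term is a
detectable part of the signal), and saturating exponential
(`9 − 2*exp(−0.5*acc)` over acc ∈ [0, 8]). What the generator emulates
is the *shape* of substituent-descriptor tables: bounded numeric
descriptors and a pKi-scale response with additive noise. What it does
not emulate: correlated descriptors, discrete count distributions,
activity cliffs, assay heteroscedasticity. Recovery tests passing on
this generator show the engine can find generating structure at small
n; they do not certify performance on real series.

One behavior the synthetic experiments expose is intrinsic to the
method: when the generating formula's extremum over the box sits at a
descriptor *corner* that no training compound occupies (high logp with
tpsa near zero, say), the observed y-range is narrower than the true
function's range and the D2-filter rejects the generating formula
itself. The search then settles on a flattened certified surrogate.
This is the documented trade-off of data-derived domains, and the
reason user-supplied, logically accessible domains are preferable.

## Benchmarking protocol

`run_matrix()` crosses feature sets (FEAT4 ⊂ FEAT7 ⊂ FEAT10) with
training ratios {0.2, 0.5, 0.8} and five random splits — 45 executions
per method per dataset in the default grid — running every method on
byte-identical splits. Scores are test RMSE and RMSE relative to the
mean predictor on the same split (computed per execution, then
aggregated); the summary reports the median with 40th/60th percentile
bands. Baselines: the mean predictor, ordinary least squares on raw
descriptor scales (coefficients are then in descriptor units, as
printed equations require), and ε-SVR with an RBF kernel tuned by
5-fold cross-validated grid search (C ∈ 0.1…1000, ε ∈ 0.01…1,
γ ∈ 10⁻³…10) with features standardized internally from training
statistics. A GP cell whose initialization fails scores as the mean
predictor and is flagged. Statistical testing between methods and
figure generation are out of scope.

## Numerical choices and degenerate inputs

* Invalid operations (zero division, `ln`/`sqrt` out of domain,
  overflow past 10^300) flag the row instead of raising, and the flag
  propagates: `exp(ln(0))` stays invalid rather than becoming 0.
* Range search treats invalid objective values as a large finite
  penalty; finite-difference steps marginally outside the box do not
  count against certification.
* Tournament ties break by lower node count, then randomly.
* Commutative operands are ordered canonically (operators before
  variables before constants in sums, the reverse in products, keyed
  at rendering precision), so structurally equal trees render
  identically and `render → parse → render` is a fixed point; rendered
  constants carry 3 significant digits, the prefix serialization is
  exact.
* Crossover offspring exceeding the depth cap are re-drawn, then the
  parents pass through unchanged; a mutation site's subtree depth is
  clipped to the remaining room.

## Problem sizes used in the tests

The test suite runs the engine at reduced scale — populations of
20–50 for 20–30 generations, datasets of 60–100 synthetic compounds —
which a single CPU completes in a few minutes while still exercising
every code path at the method's standard operator vocabulary and
probabilities. The exhaustive filter checks enumerate all ~3,300
variable-only trees of depth ≤ 2 over two features; range estimation
is validated against 200×200 dense grids. `scripts/acceptance.R`
re-runs the recovery, divergence-elimination and benchmark experiments
from scratch at the same scale.

## Known limitations

* The D2 certificate is only as good as multi-start local search; a
  needle-like spike between starts can escape it (certified global
  optimization is a non-goal).
* Data-derived domains reject generating formulas with unvisited
  extrema (see above).
* The stability penalty biases selection toward smoother surrogates;
  with `FITNESS_XC` a true steep term may lose to a flatter
  approximation — by design.
* Descriptor computation from SMILES depends on toolkit versions
  (logP/TPSA implementations drift); tests pin structural counts and
  toolkit self-consistency, not absolute values.
* Spreadsheet input is not supported; use CSV/TSV.
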