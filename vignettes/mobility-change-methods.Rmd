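---
title: "Coverage-normalised mobility change and its socioeconomic stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-normalised mobility change and its socioeconomic stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobishift)
```

## The measurement problem

Panel-based GPS mobility data counts *pass-through visits*: one visit per
device per calendar day for every destination zone a trajectory enters.
Two properties make raw counts incomparable across time. First, the
device panel fluctuates — user churn, multiple devices, app upgrades —
so a drop in counts may be a drop in panel size, not in movement.
Second, a visit of any duration counts with full weight, so pairs of
origin regions and destination zones that touch or overlap are dominated
by GPS jitter and movement inside the origin itself.

`mobishift` addresses both with two geometric rules and one statistic:

* **Exclusion rule.** An (origin, destination) pair is dropped from
  aggregation iff the two polygons share *any* point — overlapping
  interiors or touching boundaries, corner contact included
  (`find_excluded_pairs()`). The share-any-point reading is deliberately
  conservative: it removes every pair in which jitter across a shared
  boundary could register as a visit. Whether corner-touching should
  count is genuinely open; we adopt the conservative answer and note
  that for census-style partitions the affected pairs are a handful per
  city.
* **Coverage rule.** An origin's sample coverage is the visit count
  recorded in the destination zone that *completely contains* it
  (`coverage_container()`). Full containment is required; partial
  overlap yields undefined coverage and the origin is omitted rather
  than pro-rated. Note the container is itself always an excluded pair
  for visit aggregation — containment implies intersection — which is
  exactly why it can serve as a panel-size proxy: it records local
  presence, not travel.
* **The statistic.** Per origin,
  `lambda_mob = ln[(V_test / C_test) / (V_base / C_base)]`, natural log,
  with `V` the mean daily outflow over non-excluded destinations and `C`
  the coverage in the same period. Mean-per-day versus period-total is
  immaterial: the durations cancel in the ratio; we store per-day means.
  The statistic is antisymmetric under swapping the periods, invariant
  under any per-period joint rescaling of visits and coverage (a panel
  twice the size changes nothing), and invariant under per-origin
  rescaling applied to both periods.

Origins with undefined coverage, zero coverage, or zero outflow in
either period are omitted with reason codes
(`no_coverage`, `zero_coverage`, `zero_outflow_test`,
`zero_outflow_base`). We chose omission over pseudocounts: a pseudocount
scale would be arbitrary, and the affected regions are reported rather
than silently shifted toward zero.

### Assumptions inherited by any user of the statistic

`lambda_mob` compares *frequencies* of movement. It assumes the rate at
which journeys are double-counted (one person crossing several zones per
day) depends on the origin but not on the period, and that coverage is a
faithful panel-size proxy for the origin. If spatial travel patterns —
not just travel frequency — changed between periods, the ratio absorbs
that change and the interpretation weakens.

## Socioeconomic stratification

Two index scores per origin emulate the SEIFA indices of economic
resources (ER: income, rent, home ownership) and education–occupation
(EO: qualifications, occupational skill). Within each city, scores are
ranked (average rank for ties) and cut at the 10%, …, 90% empirical
quantiles of the ranks into **local decile bands**, decile 1 = lowest.
Ranks-then-quantiles is deterministic, invariant under strictly
increasing transforms of the scores (the indices are ordinal), and
balanced up to the remainder forced by `n mod 10`. All scores equal is a
degenerate stratification and an error, not a silent one-decile
assignment. Published decile conventions do not pin down boundary-tie
handling; ours is documented above and frozen.

Decile medians of `lambda_mob` are tested for monotonicity with the
**Mann–Kendall test**: `S = sum_{j>i} sign(x_j - x_i)`, tie-corrected
null variance `[n(n-1)(2n+5) - sum_t t(t-1)(2t+5)]/18`, and a two-sided
p-value from the continuity-corrected normal approximation
`z = (|S|-1)/sqrt(var_S)` (the default, which reproduces the reported
decile-trend tables) or from the exact tie-free null distribution
computed by the inversion-count recurrence (`n <= 12`; identical to full
permutation enumeration, which the tests verify exhaustively for
`n <= 7`). At `n = 10` the normal approximation and the exact tail agree
within a factor of two for `|S| <= 25`, and the exact test is
conservative at the 5% level by construction of its discrete null.

Joint ER×EO stratification produces a 10×10 grid of cell medians plus a
count grid; empty cells are reported missing, never interpolated.
Letter-value summaries use the halved-depth recursion
`d_{k+1} = (floor(d_k)+1)/2` from the median downward, interpolating
half-depths as the mean of adjacent order statistics; levels deeper than
the fourths are added only while the expected tail group at that level
(`n / 2^{k-1}`) holds at least 5 observations, so no letter value rests
on a handful of extremes.

### Marginal decile trends versus conditional effects

Because ER and EO are strongly correlated, a *marginal* decile trend in
one index inherits any true effect of the other, attenuated by their
correlation: with a pure EO effect `beta_eo` and score correlation `r`,
the ER-decile medians trend at roughly `beta_eo * r` per s.d. — easily
significant whenever the EO trend is. A flat marginal ER trend alongside
a falling EO trend therefore implies a *countervailing positive* ER
effect, not a null one. This is precisely why the package carries the
joint grid and the regression suite: the conditional (regression)
coefficients separate the two indices where the marginal decile plots
cannot. The acceptance suite computes both and shows the mechanism: with
`beta_er = 0` and `rho_er_eo = 0.9`, regressions recover `beta_er ≈ 0`
while the marginal ER-decile Mann–Kendall test is significant in every
synthetic city.

## The regression suite

Predictors are z-scored in-sample so coefficients are per-s.d. effects
on `lambda_mob`. Four models, all maximum likelihood, AIC = `2k − 2·ll`
with `k` counting intercept, slopes, the residual variance, and the
spatial parameter where present:

1. **OLS** on ER and EO (via `stats::lm`; log-likelihood and AIC agree
   with `stats::logLik`/`stats::AIC` exactly).
2. **OLS + distance to CBD** (planar Euclidean centroid distance, km).
3. **Spatial lag**: `y = rho W y + X beta + eps`.
4. **Spatial error**: `y = X beta + u`, `u = lambda W u + eps`.

The weights matrix is not dictated by the data, so we fix a
deterministic scheme: k-nearest-neighbour on centroids (k = 8, about the
rook+bishop neighbourhood of a grid), symmetrised by union, then
row-standardised; distance ties and duplicate centroids resolve by
region-id order. `W = D^{-1}A` with `A` symmetric is similar to a
symmetric matrix, so its spectrum is real; `log|I - aW| =
sum(log(1 - a*ev))`, and both spatial likelihoods are concentrated on
the spatial parameter and maximised by golden-section search
(`stats::optimize`, tolerance 1e-10) on the admissible interval
`(1/min(ev), 1)`, shrunk by 1e-8 at the ends. At parameter 0 both reduce
*exactly* to the OLS likelihood — the tests assert this identity, not
approximate agreement. Standard errors are asymptotic, from the
analytical information matrix; computing them involves a dense
`n x n` solve, so simulation loops disable them (`se = FALSE`). The
dense spectrum bounds the supported problem size at `n = 10^4` regions,
ample for city-scale partitions; beyond that the fit refuses rather than
silently approximating.

## The synthetic city

The generator exists so every stage is testable with known truth; its
defaults are the study conditions of the test suite.

* **Geometry**: a `grid_n x grid_n` tiling of square origin cells
  (default 50×50 = 2500 origins, 1 km cells) with destination zones of
  `dzn_block`² cells (default 2, i.e. 625 zones). Squares keep every
  containment and adjacency relation exact; real, irregular geometries
  enter only through the GeoJSON reader, which applies the same
  predicates.
* **Straddlers**: a seeded 4% of origins adjacent to an internal zone
  boundary are deformed — extended half a cell across the boundary, the
  neighbour shrunk to keep origins disjoint and tiling — so no zone
  contains them and the undefined-coverage path is exercised by
  construction, mirroring the regions a real analysis must drop.
* **Scores**: ER and EO from a bivariate Gaussian, `rho_er_eo = 0.9`;
  EO tilted against distance-to-centre with `gamma_eo_dist = -0.5`
  (high-EO areas central, high-ER-low-EO areas peripheral), which
  attenuates the realised ER–EO correlation by `sqrt(1-gamma²)` to
  ≈ 0.78. Scores map affinely to the familiar mean-1000, s.d.-100 scale.
* **Ground truth**: `lambda_true = beta_eo·zEO + beta_er·zER +
  beta_dist·zdist + N(0, sigma_noise)` with defaults
  `(-0.1, 0, 0, 0.2)` — a one-s.d. EO increase multiplies mobility by
  `exp(-0.1) ≈ 0.90`, comparable to the per-s.d. effects such analyses
  report, against region noise twice that size.
* **Visits**: gravity kernel `pop · exp(-d/decay_km)` (decay 8 km)
  truncated at a 50 km horizon, normalised so an origin's expected daily
  outflow is `trip_rate · population` (2 visits/resident/day of
  pass-through counting; populations uniform on 200–800). Counts are
  Poisson per day, reported as mean daily counts; the Poisson total over
  the period divided by its duration is distributionally identical to
  averaging daily draws, so one draw per pair suffices.
* **Coverage and panels**: coverage counts are Poisson with a per-period
  panel rate (defaults 500/day baseline, 400/day test — the panel
  shrinks between periods), and expected visit counts carry the same
  `panel_rate/panel_rate_base` factor, because visits are observed
  *through* the panel. Coverage is otherwise independent of
  `lambda_true`, so the normalisation is exercised by panel fluctuation
  yet unbiased; a period's panel fluctuation scale is a free parameter,
  since no empirical characterisation of panel churn was available to
  fit.
* **Seeds**: one master seed expands by fixed offsets (+11 partitions
  and populations, +23 scores, +37 ground truth, +41, +43, … per
  period) so stages are independently reproducible; identical config and
  seed give byte-identical output, which the pipeline manifest digests
  verify.

What the generator does *not* emulate: real SA1/DZN geometries and their
size gradient toward the urban fringe, SEIFA score distributions beyond
the first two moments, demographic panel bias, overdispersed counts, or
behaviour that changes trip *destinations* rather than frequencies.
Passing tests therefore certify the pipeline's arithmetic, its
invariances, and its ability to recover effects under the stated
generating model — not robustness to panel bias or spatial behaviour
change in real data.

## Numerical choices and degenerate inputs

* Geometry uses planar km with an absolute tolerance of 1e-9; predicates
  are closed-set (boundary points count). Axis-aligned rectangles take
  an exact interval fast path; general simple polygons use vertex and
  edge-midpoint membership plus proper-crossing tests, which is exact
  for convex cells and documented as the supported class.
* Histogram bins for `lambda_mob` default to width 0.1 on the log scale.
* Zero-count edges are legal and dropped from edge lists; an origin
  whose every edge is excluded aggregates to outflow 0 and is then
  omitted with a reason code.
* `mk_pvalue` validates the score's bound and (tie-free) parity;
  impossible scores are input errors, not silent NAs. The exact method
  refuses tied sequences and `n > 12`.
* CSV readers report 1-based offending row numbers; GeoJSON errors name
  the feature.

## Problem sizes in the test suite

The suite exercises the full default city (2500 origins, 625 zones, two
periods, ≈ 3×10⁶ Poisson draws per city) across 20 seeds for trend
recovery and 20 seeds for regression recovery on a fixed-geometry city,
exhaustive permutation checks to `n = 7` (5040 orderings), and a 10⁵-rep
Monte-Carlo calibration of the exact Mann–Kendall test; the whole suite
completes in a couple of minutes on one core. Geometric predicates are
verified against a package-independent closed-interval oracle on full
10×10 grids.

## Known limitations

* The exclusion and containment rules assume effectively convex,
  valid, pairwise-disjoint partition polygons; pathological concave
  geometries may need a dedicated geometry library upstream.
* Spatial model inference uses asymptotic information-matrix standard
  errors; no bootstrap.
* The weights scheme (k-NN, union-symmetrised, row-standardised) is a
  fixed design choice; results with very different schemes (contiguity,
  kernel weights) are not explored.
* No temporal sub-aggregation (weekday/weekend) and no seasonal variant
  of the trend test: periods are compared whole.
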