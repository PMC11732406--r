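# mobishift

Quantify how urban mobility changed between a test period (a lockdown, a
reopening wave) and a pre-pandemic baseline, and how that change varies
with area-level socioeconomic status — from nothing more than aggregated
origin–destination visit counts, per-origin device-panel coverage, and
two SES index scores per origin region.

The package is written for quantitative epidemiologists and urban-mobility
researchers working with panel-based GPS visit counts aggregated to small
census regions (SA1-like origins, destination-zone-like workplaces). Such
counts are *pass-through* counts (one visit per device per calendar day
per zone entered), and the device panel fluctuates between periods, so
raw counts are not comparable across time. The core statistic normalises
both away.

## The statistic

For each origin region, with visits summed over all destination zones
that neither touch nor overlap the origin (to discard GPS jitter and
purely local movement):

```
lambda_mob = ln(A / B)

A = sum_z V(origin -> z, test)  / C(origin, test)
B = sum_z V(origin -> z, base)  / C(origin, base)
```

where `V` are mean daily visit counts and `C` is the sample coverage —
the visit count recorded in the destination zone that *completely
contains* the origin, a proxy for that origin's device-panel size.
`lambda_mob = -0.69` means outbound mobility halved; `0` means no change.
Origins with no containing zone, zero coverage, or zero outflow are
omitted with reason codes, never imputed.

Downstream, origins are stratified into local decile bands of two
SEIFA-style indices — economic resources (ER) and education–occupation
(EO) — and decile-median trends are tested for monotonicity with the
Mann–Kendall test (exact and continuity-corrected normal p-values),
summarised by joint ER×EO median grids and letter values, and modelled
with a four-model regression suite (OLS; OLS + distance to the city
centre; spatial lag; spatial error — the spatial fits by concentrated
maximum likelihood with an eigenvalue log-determinant) compared by AIC.

A synthetic-city generator with a known ground-truth mobility-change
field (`lambda_true = beta_eo*zEO + beta_er*zER + beta_dist*zdist +
noise`) makes every stage testable end to end without proprietary
mobility data.

## Worked example

```r
library(mobishift)

cfg  <- city_config(grid_n = 20L, beta_eo = -0.1, beta_er = 0, seed = 42L)
city <- simulate_city(cfg)
excl <- find_excluded_pairs(city$origins, city$destinations)
mob  <- compute_lambda(
  aggregate_outflow(city$visits, excl, "test"),
  aggregate_outflow(city$visits, excl, "baseline"),
  city$coverage)
mob
#> <mobility_change> 384 origins, 16 omitted
#>   median lambda_mob: 0.0163
#>   omissions: no_coverage=16

dec <- seifa_deciles(city$seifa)
med <- decile_medians(mob, dec, "EO")
round(med, 3)
#>  [1]  0.170  0.116  0.091  0.044  0.051  0.081 -0.056 -0.017 -0.062 -0.251
mk_test(med)
#> Mann-Kendall trend test (normal_approx)
#>   n = 10, S = -37, var_S = 125.000, z = -3.220, p = 0.00128
```

The 16 omitted origins are the generated "straddling" regions that no
destination zone fully contains, so their coverage is undefined. The
EO-decile medians fall from +0.17 to −0.25 — regions with higher
education–occupation scores reduced mobility more — and the Mann–Kendall
score of −37 over the 10 medians rejects a flat trend at p ≈ 1.3×10⁻³.
The regression suite on the same city recovers the generating EO effect
(≈ −0.08 per s.d. after attenuation by count noise) with no ER effect,
and AIC differences between the spatial and non-spatial fits stay within
a point when no spatial process was generated.

A configured end-to-end run (simulate → exclusion rules → lambda →
deciles → trends → joint grids → regressions, with a manifest and log):

```r
run_pipeline(system.file("extdata", "demo-config.yaml", package = "mobishift"),
             out = "demo-run", seed = 1)
```

or from a shell via the thin CLI: `inst/exec/mobishift run --config
inst/extdata/demo-config.yaml --out demo-run --seed 1`.

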