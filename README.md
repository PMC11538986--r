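# nightshare

Night/day analysis of simultaneously GPS- and accelerometer-tracked
groups of social animals. The package asks what sharing a sleeping site
does to a population of group-living animals: whether neighbouring groups
attract or avoid one another, at what distance they start responding to
each other, whether their nightly refuge choices are coordinated, how
days after a shared night differ from ordinary days, and what co-sleeping
costs in sleep quality.

It is aimed at movement ecologists with multi-group collar deployments:
GPS fixes at regular (nominally 15-min) intervals plus per-minute
tri-axial accelerometer bursts.

## What it computes

* **Sleeping sites** — nightly 20:00–04:00 GPS centroids, hierarchical
  agglomerative clustering (complete linkage, 500 m cut), per-night site
  assignments and shared-night flags.
* **Home ranges** — kernel utilization distributions on aligned 50 m
  grids, 95% home ranges, directed overlap, and Bhattacharyya's affinity
  `BA = Σ√(p₁p₂) ∈ [0, 1]`.
* **Day-shift permutation nulls** — one track of a dyad is circularly
  rotated by whole days, preserving each group's space use and daily
  routine while destroying concurrency. Empirical values are scored
  against the 90% inter-quantile band of the null and with add-one
  permutation p-values `(1+k)/(n+1)`. Built-in metrics: mean dyadic
  distance, association time, and within-radius distance, heading
  difference and step-length difference; plus a sleeping-site sharing
  null (site use re-derived from the permuted coordinates) and a
  site-specific post-sharing null that abstains below 20 permuted
  sharing instances.
* **Response radius** — all dyad timestamps pooled into 100 m distance
  bins; the radius is the lower edge of the first bin whose coordination
  metric (default: mean heading difference) falls inside the null band,
  ascending from zero.
* **Interactions** — daytime (08:30–17:30) runs within the response
  radius, merged below 75-min gaps, split at night boundaries, flagged by
  preceding-night sharing, classified for cohesive movement (within the
  80% quantile of within-group spread while travelling ≥ 100 m) and
  scored for front/behind positioning.
* **Sleep** — per-minute sleep/wake from posture-angle stability (runs of
  ≥ 5 min with successive angle changes < 5°), then per-night total sleep
  time, efficiency, fragmentation (wake bouts ≥ 2 min per hour of sleep),
  onset/offset, dyadic synchronization, model-ready effect tables and
  block-bootstrap sharing contrasts.
* **Simulator** — a multi-group movement + accelerometry generator with
  full ground truth (site assignments, shared nights, attraction days,
  minute-level sleep labels) that drives every validation experiment.

## Worked example

Simulate a two-group scenario in which sharing a sleeping site triggers
movement coupling strictly inside a true 600 m response radius, then run
the full pipeline:

```r
library(nightshare)

sc  <- make_scenario("radius_600", n_days = 90)
sim <- simulate_gps(sc$config, seed = 42)
labels <- simulate_sleep_labels(sim$truth$individual_nights, sc$config, seed = 43)
bursts <- simulate_accel(labels, sc$config, seed = 44)

res <- run_pipeline(sim$fixes, bursts, "demo_run",
                    analysis_config(n_permutations = 200), seed = 7)
res$response_radius
#> <response_radius> heading_diff: 600 m (200 permutations, band 5-95%)
res$null_tests[, c("metric", "empirical", "null_lo", "null_hi", "significant")]
#>   metric               empirical   null_lo  null_hi significant
#> 1 mean_distance         4102.    4438.     5014.    TRUE
#> 2 association_600m         0.203    0.0763    0.154 TRUE
#> 3 within_distance_600m    83.7     67.7      97.4   FALSE
#> 4 heading_diff_600m       64.1     76.6      87.8   TRUE
#> 5 step_diff_600m          16.7     18.5      32.5   TRUE
#> 6 sharing_proportion       0.231    0.0879    0.187  TRUE
res$sleep$contrasts
#>   metric        difference    ci_lo    ci_hi n_shared n_unshared
#> 1 tst_min         -25.1    -31.2    -19.0          42        140
#> 2 efficiency       -0.0523  -0.0650  -0.0397       42        140
#> 3 fragmentation     0.557    0.507    0.607        42        140
```

Reading the output: the inferred response radius equals the simulated
600 m; the groups are significantly closer (mean distance below the null
band), together more often, and more aligned in heading than chance while
within the radius; the sharing proportion exceeds its null because the
scenario forces frequent co-sleeping; and on shared nights individuals
sleep ~25 min less, with lower efficiency and about half an extra
awakening per hour of sleep — the disruption built into the generator,
recovered through the accelerometer classifier. `render_report("demo_run")`
writes a text summary and schematic figures.

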