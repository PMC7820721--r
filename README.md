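# runsit — situation mining for running activity data

`runsit` studies a question from physical-activity research: **under which
temporal and environmental circumstances do people run longer or shorter than
their own average distance — and does the answer differ between sporadic and
regular runners?** It is aimed at researchers in physical-activity
epidemiology and mobile-health who want a tested, reproducible implementation
of the two-stage analysis, and at method developers who need a weighted
(signed) frequent-itemset miner with a correctness oracle.

Because the mobile-fitness and geographic source data such studies use are
proprietary, the package ships a first-class **synthetic world generator**:
landscapes, runner populations and run records with *planted,
known-by-construction* situation effects, so every downstream stage can be
validated by parameter recovery rather than by eyeballing.

## The method

Each run is described by a **situation vector** of 29 categorical items:
3 temporal (3-hour slot, weekday, month), 4 weather (temperature bin, weather
/ wind / humidity type), 18 topographical (distance to, and 1 km² coverage
of, each of 9 landuse classes on a 100 m grid), and 4 demographic
(neighborhood attributes via point-in-polygon). Geographic features are
discretized by a dedicated `0` category plus 10 nearest-rank decile bins over
the reference landscape.

Its **weight** is the per-user normalized distance

```
w = (y − mean(y_user)) / (max(y_user) − min(y_user))  ∈ [−1, 1]
```

so w > 0 means "longer than this user's average". Two analyses follow:

1. **Runner clustering.** Each user's 52-week activity sequence (weekly run
   counts from their most active 52-consecutive-week window) is compared by
   dynamic time warping; Ward agglomerative clustering (Lance–Williams
   update) on the DTW matrix separates sporadic from regular runners.
2. **Weighted frequent itemset mining.** The weighted support of an itemset
   X is `w(X) = Σ w_m` over transactions containing X. A signed-weight
   FP-growth enumerates situations with `|w(X)| ≥ σ`; because signed weights
   break anti-monotonicity, the default `exhaustive` mode guarantees the
   complete answer (oracle-tested), while `pruned` mode reproduces the
   classic heuristic. Per-feature variability (the standard deviation of a
   feature's value supports), value histograms, and per-category top-k
   situation tables summarise the result.

## Worked example

```r
library(runsit)
cfg <- runsit_config(seed = 42, n_users = 150, horizon_years = 3)
rep <- run_pipeline(cfg)
print(rep)
```

```
== runsit pipeline report (seed 42) ==
20851 simulated runs -> 20686 transactions (drops: missing_field=112, bad_category=0, bad_timestamp=0, short_distance=52, missing_context=1)

Runner clusters:
 cluster   n mean_annual_runs
       1  28         97.28571
       2 122         36.59016

Mining threshold sigma = 59.53

Top temporal situations, less active cluster (2):
  above average:
                      itemset  support count
 hour=[9,12) + weekday=Sunday 171.4030   728
                  hour=[9,12) 160.9806  3117
               weekday=Sunday 140.7299  3100
  below average:
                          itemset   support count
                     hour=[18,21) -99.08688  3321
                weekday=Wednesday -81.56218  1553
 hour=[18,21) + weekday=Wednesday -73.94421   391
```

Reading this: the generator planted +800 m on Sunday-morning runs and
−600 m on Wednesday-evening runs; the pipeline recovers the two runner
archetypes (~97 vs ~37 runs/year clusters) and ranks exactly the planted
situations first, with the expected signs. `summary(rep)` additionally shows
that the hour and weekday features carry far more distance variability than
any weather, topographic or demographic feature — the planted structure.

The stages are also usable à la carte (`make_landscape`, `simulate_runs`,
`build_geo_context`, `national_quantile_bins`, `build_transactions`,
`pairwise_dtw`, `ward_linkage`, `mine_situations`, …), and a thin CLI over
them lives at `inst/cli/runsit.R` (`simulate`, `enrich`, `prepare`,
`cluster`, `mine`, `report`, `all`). All artifacts are plain text: CSV
tables, Esri ASCII-grid rasters, GeoJSON neighborhoods, JSON schemes.

## Vignette

`vignettes/situation-mining.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and the numerical conventions
(tie-breaks, bin boundaries, degenerate inputs).
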