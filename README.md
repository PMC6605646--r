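# spiderling

Tools for studying the onset of natal dispersal in gregarious spiderlings of
solitary spiders — the transient phase during which newly emerged siblings
first aggregate tightly and then, within about a week, disband. The central
scientific question the package addresses is *why* groups dissolve: does
mutual attraction between spiderlings fade, or does a maturational increase
in mobility alone pull the group apart while social behavior stays
unchanged? The package provides the complete computational pipeline for
answering that question from coordinate data: a stochastic agent-based
arena simulator, a heavy-tailed stop-duration survival model, a
trajectory-superimposition null model with Cox hazard-ratio quantification
of interattraction, wall-aware spatial dispersal metrics, and a
synthetic-data generator that makes every stage testable offline.

## The model

Stopped spiderlings resume moving with a probability per unit time that
*decreases* with the time `t` already spent stopped:

    P_leave(t) = delta + alpha / (beta + t)

equivalently, stop durations follow the survival function

    F(t) = exp(-delta t) * (1 + t / beta)^(-alpha)

a power law with an exponential cutoff (`delta`, fixed at 1e-6/s, caps the
hazard decay for very long rests). The fit to Day-1 single spiderlings
gives `alpha = 0.48`, `beta = 0.74` s. Interattraction enters as a
group-size scaling of the per-individual leaving parameter: a member of a
pair uses the pair-aggregate dissolution parameter divided by two
(`0.57 / 2 = 0.285`), and members of trios and quartets use the
single-spider `alpha` divided by 5 and 10. Maturation enters as a single
1.95-fold increase of `alpha` on Day 4 (the ontogenic shift). An
agent-based model embeds these rules in a partitioned circular arena with
wall-following, diffusive central movement, social stopping and
collision-triggered departures, and lets each ingredient be switched off —
`no_social` (spiders behave as if alone) and `no_shift` (no maturational
change) — to test which one drives dispersal.

Interattraction is measured from data, not assumed: the lifetimes of real
pair aggregates (interindividual distance < 10 mm for more than 1 s) are
compared with the lifetimes of "virtual pairs" built by superimposing the
recentered paths of two spiders recorded alone. A Cox proportional-hazards
model with Breslow ties on the pooled lifetimes yields a hazard ratio:
HR = 1 means aggregates last no longer than chance; HR > 1 means real
aggregates outlive chance, i.e. mutual attraction.

## Worked example

```r
library(spiderling)

# 1. stop-duration model: simulate Day-1 stops and refit them
stops <- gen_stop_durations(survival_params(alpha = 0.48, beta = 0.74,
                                            delta = 1e-6),
                            n = 10000, seed = 42)
fit <- fit_stop_survival(stops, delta = 1e-6)
fit
#> <stop_survival_fit> alpha = 0.4657, beta = 0.7001 s (delta fixed at 1e-06 /s)
#>   10000 events, SSE = 0.04096
```

The fitted `alpha` and `beta` recover the generating values (0.48, 0.74 s)
to within a few percent; `autoplot(fit)` overlays the fitted curve on the
Kaplan–Meier step function on log–log axes, where the power-law regime is a
straight line.

```r
# 2. interattraction: simulated pairs with social rules on, against the
#    no-interaction null
real <- null <- list()
for (s in 1:4) {
  on  <- gen_pair_trajectories(3 * 3600, interattraction = TRUE,  seed = 100 + s)
  off <- gen_pair_trajectories(3 * 3600, interattraction = FALSE, seed = 200 + s)
  real[[s]] <- extract_aggregate_lifetimes(on$pair)
  null[[s]] <- extract_aggregate_lifetimes(off$pair)
}
cox_hazard_ratio(dplyr::bind_rows(real), dplyr::bind_rows(null))
#> <cox_hr> hazard ratio (null vs real) = 1.401 [1.233-1.592]
#>   events: 446 real, 663 null
```

The hazard ratio above 1 (with a CI excluding 1) says that aggregates of
interacting spiders dissolve more slowly than chance encounters — the
model's interattraction is visible to the same estimator used on real
recordings.

```r
# 3. dispersal dynamics: the full model against the random-placement level
base <- random_baseline_distance(arena_preset("dispersal_80mm_4c"),
                                 n_individuals = 4, n_resamples = 500, seed = 1)
base$mean_nn_mm
#> [1] 25.5   # mm; random level of aggregation (band 11.6-44.5)

summary <- run_condition(sim_config(condition = "full", n_runs = 100, seed = 2024))
autoplot(summary, baseline = base)
```

The daily mean nearest-neighbour geodesic distance starts far below the
random level (a dense cluster), then rises from Day 4 — the ontogenic
shift — toward the random level: dispersal without any change in social
rules. Running `condition = "no_shift"` keeps the group aggregated
indefinitely; `condition = "no_social"` never aggregates in the first
place.

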