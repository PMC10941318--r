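# flocknet

Social-network ontogeny from RFID feeder visits.

Wild birds fitted with PIT tags leave a stream of timestamped antenna
reads every time they visit an instrumented feeder. **flocknet** turns
such streams into foraging-flock association networks and asks how the
social ties of juveniles develop as they reach independence and move
through their first year: do fledglings prefer siblings and peers over
unrelated adults, do they inherit their parents' associations, do
flocks assort by age, and do preferred associations persist from season
to season?

The package covers the full chain:

* **Gathering events.** Reads at each feeder are segmented by hard
  temporal gaps and decomposed with BIC-selected one-dimensional
  Gaussian mixtures into discrete gathering events (foraging flocks),
  each with its member set.
* **Association networks.** Under a gambit-of-the-group assumption,
  dyads are scored with the simple ratio index

  `SRI = x / (x + y_AB + y_A + y_B)`

  — the proportion of sampling groups containing both birds out of
  those containing either (0 = never together, 1 = always together).
  Birds seen in fewer than five distinct groups per window are
  excluded. Weekly networks cover the spring–summer deployments;
  seasonal networks pool three 48-h deployments.
* **Dyadic regression.** SRI responses are modelled with a
  zero-inflated beta likelihood — `y = 0` with probability `pi`,
  positive `y ~ Beta(mu*phi, (1-mu)*phi)`,
  `logit(mu) = X beta + a_focal + m_i + m_j` — with a focal-individual
  random intercept and a multi-membership random effect (one effect
  per bird, entering for both members of every dyad; an unordered-dyad
  intercept is also available). Covariates include relationship class
  (parents / siblings / peers / other adults), space-use overlap, age
  since fledging, homophily differences, cumulative association with
  or between parents, and previous-season association. Effects are
  reported as odds ratios with 95% credible intervals. Sampling is by
  a compiled adaptive Metropolis-within-Gibbs sampler (a JAGS engine
  fits the identical model as an independent cross-check).
* **Assortment and stability.** Weighted assortativity by age class
  with node-permutation p-values, and season-to-season stability
  models of current on previous-season association.
* **A synthetic world.** A seeded generator of pedigrees, latent
  co-foraging preferences, home ranges and detection streams — with
  the true event log kept as ground truth — validates every stage end
  to end.

## Worked example

Simulate a small study world with a planted sibling preference
(multiplier 3), detect events, build weekly networks and fit the
relationship-by-age model:

```r
library(flocknet)

cfg <- world_config(n_nest_boxes = 6, n_weekly_deployments = 2,
                    deployment_duration_h = 12, event_rate = 5,
                    seed = 42,
                    preference_params = list(sibling = 3, parent = 1.5,
                                             peer = 1.5, other_adult = 1,
                                             familiarity_carryover = 0.75))
birds <- generate_population(cfg)          # 51 birds, 39 first-year
soc   <- sample_social_structure(birds, cfg)
sched <- subset(build_schedule(cfg), season == "summer")
sim   <- simulate_detections(birds, soc, cfg, schedule = sched)
nrow(sim$detections)                       # 5706 antenna reads

ev <- detect_gathering_events(sim$detections, sched)
nrow(ev$events)                            # 477 gathering events

sc <- study_config(seed = 42, overlap_method = "min_share", models = list(
  model1 = zib_model_spec(
    fixed_terms  = c("relationship", "overlap", "focal_age_days"),
    interactions = list(c("relationship", "focal_age_days")),
    random_structure = list(dyad_intercept = TRUE),
    chains = 2, iterations = 1500, warmup = 600, seed = 421)))
res <- run_ontogeny_analysis(sim$detections, birds, sched, sc,
                             which_models = "model1")
res$summaries$model1
#>                                  term or_mean ci_low ci_high significant
#> 1                 relationshipparents   0.990  0.873   1.099       FALSE
#> 2                relationshipsiblings   1.190  1.066   1.312        TRUE
#> 3                   relationshippeers   1.000  0.927   1.064       FALSE
#> 4                             overlap   2.789  2.418   3.163        TRUE
#> 5                      focal_age_days   1.009  0.999   1.019       FALSE
#> 6  relationshipparents:focal_age_days   1.002  0.981   1.025       FALSE
#> 7 relationshipsiblings:focal_age_days   0.984  0.972   0.997        TRUE
#> 8    relationshippeers:focal_age_days   1.000  0.989   1.010       FALSE
```

Reading the output: odds ratios compare association strength per unit
change of each predictor against the `other_adults` baseline. The
planted sibling preference is recovered — juveniles associate more
strongly with siblings (OR 1.19, CI excluding 1) — space-use overlap
is, as always, a strong predictor (OR 2.79 comparing complete to no
overlap), and the sibling preference declines as juveniles age
(interaction OR 0.984 per day, CI below 1). Parents and peers, planted
with weaker biases, sit near 1 at this sample size.

Seasonal analyses work the same way from the year-round schedule:
`run_seasonal_analysis()` builds pooled seasonal networks, tests age
assortativity with node permutations, and fits the stability models on
dyads observed in consecutive seasons.

A thin command-line wrapper over these functions is installed at
`inst/scripts/flocknet.R`
(`Rscript flocknet.R all --config world.yaml --out dir/ --seed 1`).

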