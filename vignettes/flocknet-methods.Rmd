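---
title: "From feeder visits to social strategies: the flocknet methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From feeder visits to social strategies: the flocknet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

flocknet infers foraging association networks of individually PIT-tagged
birds from raw RFID antenna reads, and models how those associations
change as juveniles transition to independence and across their first
year. This vignette explains the models and procedures, the tunable
parameters and their defaults, the synthetic world used for validation,
and the numerical and design choices that shape the results.

## The pipeline at a glance

1. **Detections to gathering events.** Timestamped reads
   (`tag_id`, `feeder_id`, `timestamp_s`) are split per feeder and
   deployment window into bursts separated by hard temporal gaps, and
   each burst is decomposed by a BIC-selected one-dimensional Gaussian
   mixture into discrete *gathering events* — the foraging flocks.
2. **Events to networks.** Under the gambit of the group (all members
   of a detected group are taken to be associating), the event-by-bird
   membership table yields, for every dyad, the simple ratio index
   `SRI = x / (x + y_AB + y_A + y_B)`: the proportion of sampling
   groups containing both birds out of the groups containing either.
   Birds seen in fewer than five distinct groups in a window are
   excluded before edges are computed.
3. **Dyadic regression.** Dyad-level association strengths are
   modelled with a zero-inflated beta likelihood: `y = 0` with
   probability `pi`, and positive `y ~ Beta(mu * phi, (1 - mu) * phi)`
   with `logit(mu) = X beta + a_focal + m_i + m_j`, where `a` is a
   focal-individual intercept and `m` the multi-membership term — one
   effect per bird, entering additively for both members of the dyad.
   Effects are reported as odds ratios (OR, `exp(beta)`) with 95%
   credible intervals; an effect is called significant when the CI
   excludes 1.
4. **Assortment and stability.** Pooled seasonal networks are tested
   for weighted assortativity by age class with node-permutation
   nulls, and season-to-season stability is modelled by regressing
   current SRI on previous-season SRI, age class and their
   interaction, controlling for space-use overlap.

## The synthetic world

Real colour-ringed populations cannot ship with a package, so every
stage is validated against a generator with known ground truth. Its
defaults emulate a woodland great-tit study system:

* **Population.** 43 occupied nest boxes, each with a breeding pair
  and a tagged brood of `Poisson(6.5 x 0.66)` nestlings truncated at
  one — about 6.5 eggs laid per clutch of which roughly two-thirds
  survive to day-15 tagging, so ~185 tagged nestlings in total.
  Fledging is 22 days after hatching; fledge weights are log-normal
  around 18 g (only differences between birds enter any analysis, so
  the location is arbitrary).
* **Deployment calendar.** Six feeders read simultaneously for one
  48-h window per week over 14 spring–summer weeks, then three 48-h
  windows in each of autumn, winter and spring. Timestamps are integer
  seconds on a study clock whose day 0 is the first deployment;
  windows are half-open `[start, end)`.
* **Space use.** Each bird's home range is an independent Dirichlet
  draw over feeders (total concentration 6, i.e. moderately
  feeder-specific). Home ranges are deliberately independent of
  pedigree: relationship effects on association are then identifiable
  net of space, which is what the validation suite must test. Real
  great-tit families do share space — see *Limitations*.
* **Social preference.** `preference(i, j) = multiplier(relationship)
  x Bhattacharyya(home_range_i, home_range_j)`, symmetric with zero
  diagonal. The multipliers (defaults: siblings 2.5, parents 1.5,
  peers 1.5, other adults 1) encode the latent co-foraging biases the
  dyadic models should recover.
* **Events and reads.** Gathering events arrive per feeder-window as a
  Poisson process (4 events per feeder-hour), thinned so centres are
  at least `5 x` the 60-s emission spread apart — the regime in which
  the event detector is required to work. A seed attendee is drawn by
  home-range weight; others join with probability proportional to
  `preference x home-range weight`, scaled so three birds join in
  expectation (flock sizes then do not grow with population size).
  Every attendee emits `1 + Poisson(2)` reads at integer seconds
  `Normal(centre, 60 s)`. The paper trail of every simulated read —
  which latent event produced it, with which true members — is kept as
  the oracle for recovery tests.
* **Seasons.** Between seasons each bird is removed with probability
  0.15 (death/dispersal), and the preference structure persists with
  weight `familiarity_carryover` (default 0.75; 1 reproduces the
  summer structure exactly, 0 draws home ranges and preferences
  afresh). This is the dial the stability analyses must detect.

The generator is seeded end to end: a fixed seed gives bit-identical
detection streams, and each pipeline stage derives its own sub-seed
from the global one so stages are independently reproducible.

## Event detection: numerical choices

* **Hard gap.** Reads separated by more than `hard_gap_s` (default
  600 s) at one feeder can never belong to one gathering; this
  pre-segmentation bounds the mixture problems and defines the
  detector's timescale.
* **Mixture fit.** Within a segment, Gaussian mixtures with
  k = 1..min(`k_max`, n) components are fitted by EM (package mclust,
  model `"V"`) and k is selected by BIC. The fit uses mclust's
  conjugate prior on the variances: antenna timestamps are integer
  seconds, and tied values otherwise spawn spurious near-zero-variance
  components. Degenerate segments (single read, or all reads in the
  same second) bypass the fit entirely and return a single component
  with a variance floor of 1 s².
* **Resolution limit.** Two post-fit merges keep the component count
  honest: (a) components whose means are closer than
  `0.3 x hard_gap_s` are merged (events that close are not resolvable
  at the declared timescale — and the generator never produces them,
  since centres are kept at least five spreads apart); (b) adjacent
  components within four spreads of each other are refitted in
  isolation, and merged if one Gaussian explains their reads better
  than two (the variance prior occasionally slices one burst into two
  components of the same mode). The per-segment component cap
  `1 + span / (0.6 x hard_gap_s)` bounds the BIC search for speed.
* **Small events.** Components with fewer than `min_reads_per_event`
  reads (default 1, i.e. no minimum — single visits are kept) are
  absorbed by the nearest event in time at the same feeder.
* **Determinism.** mclust's EM with hierarchical initialisation is
  deterministic, so the whole event stage is reproducible without a
  random seed; the `seed` slot in `event_params()` exists for
  interface stability.

On synthetic streams at the generator's defaults the detector recovers
about 97% of latent events with exactly the correct member sets; the
validation suite requires at least 95%.

## Networks, the index, and its denominators

`sri_counts()` counts, for a dyad over the groups of one window: `x`
groups containing both; `y_A`/`y_B` groups containing only one bird;
and `y_AB`, observations of one bird in a group while the other was
present in a *different, time-overlapping* group at the same feeder.
Because the event detector partitions reads, overlapping groups are
rare and `y_AB` is usually zero; on plain membership tables without
event metadata it is exactly zero. The inclusion filter (at least five
distinct groups per bird) is applied once per weekly window, or once
to the pooled counts of a season's three deployments; survivors are
not re-screened after empty groups are dropped. Among retained birds
every dyad has a positive denominator, so the undefined all-zero case
cannot occur post-filter.

## Dyad covariates

* **Space-use overlap** supports two readings. `"proportion"` is the
  share of the focal bird's reads made at feeders the partner also
  used — asymmetric, and the reading used for reported overlap ORs
  ("comparing complete to no overlap"). `"min_share"` is the summed
  feeder-wise minimum of the two normalised usage profiles — a
  continuous symmetric similarity. Null-calibration experiments on the
  synthetic world showed that the binary-presence `"proportion"`
  under-controls shared space when feeder counts are small (a partner
  with one incidental read at a feeder counts as fully present there),
  which can push residual spatial structure into the relationship
  coefficients; the validation suites therefore run the pipeline with
  `"min_share"`, and `"proportion"` remains the default reading of
  `space_overlap()` itself.
* **Relationship classes** — parents, siblings, peers (same-cohort
  non-sibling juveniles), other adults — are mutually exclusive and
  exhaustive, derived from the pedigree.
* **Homophily covariates** are absolute differences (|fledge-weight
  difference| in grams, |hatch-date difference| in days), z-scored
  within the full spring–summer dyad table; juvenile age (days since
  fledging) is centred. Transform parameters are stored on the vectors
  for reporting and inversion.
* **Parental network covariates** pool weeks 1..t (week 5 uses weeks
  1–5) and sum SRI terms between the partner adult and the focal's
  parents, or over the up-to-four pairs of the two juveniles'
  parents. The pooled table is used *unfiltered*: these are
  covariates, not responses, and the inclusion filter would discard
  most parent observations. Terms involving untagged or never-observed
  parents contribute zero; juveniles with no tagged parent at all are
  flagged and excluded.
* **Collinearity** is screened with variance inflation factors on the
  main-effect design (interaction columns excluded), `VIF_j = 1 / (1 -
  R²_j)` from least-squares regressions of each predictor on the rest.

## The zero-inflated beta model

The response is an SRI weight in `[0, 1]` with genuine zeros.
Exact ones (possible when a dyad is always together) are mapped to
`1 - 1e-6` by default; a Smithson–Verkuilen compression
`(y (n - 1) + 0.5) / n` of all positive responses is available.

Priors are weakly informative — Normal(0, 2.5) on fixed effects of
standardised predictors, half-Normal(0, 1) on random-effect SDs,
Exponential(0.1) on the beta precision, and Logistic(0, 1) on the
zero-inflation intercept (uniform on the probability scale). The
contract of the inference engine is parameter recovery under the
model, not bit-level replication of any particular software's fits.

Two engines fit the identical model. The default is the package's
compiled adaptive Metropolis-within-Gibbs sampler: the fixed-effect
block uses a Haario-style adaptive multivariate proposal on
column-scaled covariates with a least-squares warm start, plus a
robust per-coordinate pass; the zero-inflation probability is drawn
exactly by beta-binomial conjugacy; random effects are single-site
random walks; and two interweaving moves — an intercept sweep (shift
the intercept against a random-effect block, leaving the linear
predictor invariant) and a group rescale (multiply a block's SD and
effects by a common factor) — remove the slow directions that plain
Gibbs schemes suffer in hierarchical models. All proposal scales adapt
during warm-up only, so the post-warm-up kernel is fixed and valid.
`engine = "jags"` fits the same model through rjags and serves as the
independent cross-check in the package's tests; on shared fixtures the
two engines agree on posterior means and spreads well within Monte
Carlo error. Both engines derive per-chain RNG seeds from the spec
seed and are bit-reproducible.

Convergence is summarised by split-chain R-hat (flagged above 1.05 on
the fixed effects, SDs, precision and zero-inflation parameters) and
effective sample sizes; `posterior_predictive_check()` replicates the
data from joint posterior draws and locates the observed zero fraction
and positive mean within the replicated distributions.

**Random structure.** "The dyad as a random effect" admits two
readings: the multi-membership term (one Normal effect per individual,
added for both members) and an unordered-dyad intercept. The package
implements both; the multi-membership term is on by default, matching
the modelling tradition this pipeline follows. For tables in which the
same dyad contributes several rows — the weekly spring–summer tables
stack up to 14 windows, and both-directions tables contain each
unordered pair twice — the validation suites additionally switch the
dyad intercept on: without it, repeated rows of one dyad are treated
as independent, credible intervals shrink below their nominal
coverage, and null worlds produce spurious "significant" relationship
effects. Analysts using the multi-membership-only default on stacked tables
should interpret borderline intervals accordingly.

## Assortativity and its permutation null

The weighted mixing matrix `E` allocates each edge's weight half to
`(g, h)` and half to `(h, g)`; `r = (sum_g E_gg - sum_g a_g b_g) / (1
- sum_g a_g b_g)` with `a`, `b` the marginal sums, giving -1 for
purely between-class and +1 for purely within-class association.
`node_permutation_pvalue()` shuffles labels over all nodes (isolates
included) with edges fixed, and reports the one-sided tail proportion
in the observed direction: permuted values strictly greater than the
observed `r` for assortment (`r >= 0`, with 0 counted as assortment),
strictly smaller for disassortment. Ties with the observed value are
excluded from numerator and denominator; a fully degenerate
permutation distribution (a complete equal-weight graph, where every
labelling gives the same `r`) yields `p = 1`. A flag restores the
tie-as-extreme and plain-denominator conventions.

Because the tail is chosen *after* seeing the sign of `r`, this
one-sided `p` belongs to a two-sided procedure: comparing it directly
to `alpha` would reject true nulls at up to `2 alpha` (analytically,
`min(q, alpha) + min(1 - q, alpha)` where `q` is the null mass above
zero; empirically ~8% at `alpha = 0.05` on 30-node networks). The
package therefore reports `p_assort` exactly as defined, but its
significance flag applies the two one-sided tests rule — reject at
level `alpha` when `p <= alpha / 2` — which restores the nominal
type-I rate (measured ~5-7% across seeds under label independence, well
inside the binomial band the calibration suite checks).

## The validation suite and its problem sizes

The test and acceptance suites run everything at desk scale, chosen
once as a compromise between statistical resolution and a laptop-class
runtime; all sizes are stated here as the package's own choices.

* Dyad-count identities: seasonal tables over 75, 43, 105 and 58
  retained birds must contain exactly `n (n - 1)` directed rows
  (5550, 1806, 10920, 3306).
* SRI agrees exactly with exhaustive enumeration on 100 random
  membership tables (up to 10 groups x 6 birds), plus the boundary
  semantics 0 and 1.
* Assortativity limits ±1; permutation calibration on 200 replicate
  30-node networks with 200 permutations each.
* Event recovery ≥95% exact member sets on a 6-box world with four
  12-h weekly windows at the generator's spacing regime.
* Sampler coverage: 20 replicates of 600 dyads among 40 birds
  simulated from the model (intercept -2, overlap effect log 2, a
  standard-normal covariate -0.3); each coefficient's 95% interval
  must cover its generating value in at least 90% of replicates, at
  2 chains x 1200 iterations (500 warm-up).
* End-to-end: ten seeded 6-box worlds with sibling preference x3 over
  two 12-h weekly windows must flag OR(siblings) > 1 as significant in
  at least 8, and ten matched null worlds (all multipliers equal) in
  at most 2.

Passing these suites shows that the pipeline recovers what its own
generative model plants, at the planted effect sizes and sample sizes
— it does not certify any particular biological conclusion on real
data, where detection processes, space use and social structure are
all richer than the generator.

## Known limitations

* Family members share no space in the synthetic world; in real
  populations kin often do, and the overlap covariate then carries
  part of the kin effect. The `"min_share"` overlap is the better
  space control of the two offered, but no feeder-count covariate can
  fully separate space from preference when both are family-structured.
* The generator has no weather, food-availability or dominance
  structure, no cross-feeder movement model beyond the per-feeder home
  range, and events at different feeders never interact.
* Gatherings are modelled as Gaussian pulses in time; real flocks have
  skewed arrival/departure dynamics, and no duration distribution for
  foraging flocks is established for this system — the Normal emission
  is a modelling convenience.
* The zero-inflation part is intercept-only by default; covariates
  can be supplied, but zero-generating and positive processes are
  then still assumed independent.
* The stability analyses condition on birds observed in consecutive
  seasons; mortality and dispersal make this a selected subsample,
  and the package does not model the selection.
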