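---
title: "Quantifying trends in local rarity across assemblage time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying trends in local rarity across assemblage time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raretrends)
```

## The question and the quantities

Most species in any ecological assemblage are locally rare, so how the
*number* of rare species changes over time is a first-order descriptor of
biodiversity change. A rise in local rarity can come about through two very
different processes: (1) resident populations declining until they fall below
a rarity threshold, or (2) new species entering the assemblage in low
numbers. The two processes leave different fingerprints on the joint trends
of three facets of assemblage structure:

* **rarity** — the number of species represented by one individual
  (singletons) or one or two individuals (singletons + doubletons) in a
  standardized yearly sample; Fisher's log-series alpha serves as a third,
  distribution-based rarity metric;
* **species richness** `S` — the number of species in the yearly sample;
* **assemblage size** `N` — the number of individuals in the yearly sample.

Declining populations without extra extinctions push rarity up, leave
richness flat and pull size down. Declines that do drive local extinctions
pull richness and size down together. Net immigration pushes rarity and
richness up together, with a slight rise in size. `raretrends` implements the
full chain needed to measure these fingerprints on long-format monitoring
data, plus a generator that synthesizes data under each process so every
stage can be validated against known truth.

## Sampling standardization

Monitoring effort is rarely constant, and every rarity metric here is
effort-sensitive (a singleton is only meaningful at fixed effort). Effort is
standardized by sample-based rarefaction within each assemblage:

1. Years with fewer than half the mean number of sampling occasions are
   excluded (`filter_years()`). The mean is computed once, on the series as
   supplied, and ties at exactly half are retained.
2. The minimum number of occasions over the remaining years, `n_min`, is
   found, and exactly `n_min` whole occasions are drawn uniformly without
   replacement from every year (`rarefy()`). Occasions are never split:
   either all records of an occasion enter, or none. The year attaining the
   minimum contributes all of its occasions.
3. Abundances are summed per species within each year over the drawn
   occasions, which also removes within-year seasonality.

Because the draw is random, the whole analysis is repeated over independent
rarefaction iterations (`rarefy_iterations()`, default 20). The first
iteration is the headline analysis; the rest feed a robustness summary of
the fitted slopes. Each iteration derives its own seed from the base seed
via a fixed integer mixing scheme (`iteration_seed()`), so iteration *k* is
reproducible in isolation and results are bit-identical across runs.

The trend predictor is the mean-centred year: calendar year minus the mean
of the retained years of that assemblage. Centring is per-assemblage, which
makes the overall slope invariant to shifting calendar time and keeps
intercepts interpretable as mid-series levels.

## Rarity metrics

`summarize_years()` reduces each rarefied assemblage-year to `n_singletons`,
`n_rare` (singletons + doubletons), `richness_S`, `size_N` and
`fisher_alpha`. A *doubleton* is a species with exactly two individuals;
"rare" means abundance 1 or 2. Fisher's alpha is the unique positive root of

$$S = \alpha \,\ln(1 + N/\alpha),$$

found by bracketed root-finding with Newton polishing; the returned root
reproduces `S` to within `1e-8 * S` (asserted in the tests against an
independent bisection oracle and against `vegan::fisher.alpha`). When every
species is a singleton (`S == N`) no finite root exists; such years get `NA`
with a warning rather than an imputed value, and are dropped (with a logged
count) from the Fisher's-alpha trend model only.

## Trend models

Each facet is modelled with a mixed-effect regression against mean-centred
year with a random intercept *and* random slope per assemblage, so that one
overall slope is estimated while every assemblage keeps its own rate of
change:

| response | family | link / transform |
|---|---|---|
| `n_rare`, `n_singletons` | negative binomial (`Var = mu + mu^2/theta`) | log |
| `log10_richness`, `log10_size` | Gaussian | identity on log10 |
| `fisher_alpha` | Gaussian, `Var(e) = sigma^2 |fitted|^(2 delta)` | identity |

Estimation is maximum likelihood with the Laplace approximation (glmmTMB)
for the count and Gaussian models, and `nlme::lme` with a `varPower`
variance function for Fisher's alpha, whose residual spread grows with its
fitted level. Intervals on the overall slope are 95% Wald intervals. The
random intercept–slope covariance is unstructured by default. Boundary
fits (a variance estimate at zero) are common in small or weakly
heterogeneous data and are kept, with a warning; only when a structure
yields non-finite fixed-effect standard errors does the fit fall back along
unstructured → diagonal → intercept-only → fixed-effects-only, recording the
structure used. A constant response short-circuits to the exact maximum
likelihood limit (zero slope, zero residual variance) rather than letting
the optimizer chase an unbounded likelihood.

Per-assemblage slopes are `beta1 + b1_i` with `b1_i` the conditional mode
(BLUP); they are shrunken towards the overall slope relative to
per-assemblage OLS fits, which is desirable when series are short.
`classify_assemblage_trends()` marks an assemblage positive/negative only
when a 95% interval around its slope (combining the fixed-effect SE with
the conditional SD of its slope deviation, treated as independent) excludes
zero. For the power-variance model the conditional covariance is computed
explicitly as `(Z' R^-1 Z + G^-1)^-1` per assemblage, with `R` the fitted
power-variance residual covariance.

On the log10 scale a slope `b` means a multiplicative change of `10^b` per
year; `slope_to_ratio(0.0007)` = `r slope_to_ratio(0.0007)` and
`slope_to_ratio(0.0043)` = `r slope_to_ratio(0.0043)`, i.e. +0.2% to +1.0%
per year.

## Relating trends across facets

The process fingerprints live in the *correlations* between per-assemblage
slopes of different facets (`pair_slopes()`, `correlate_slopes()`,
`slope_correlation_matrix()`): rarity–richness, rarity–size, richness–size,
plus the metric-agreement pairs rarity–singletons and rarity–Fisher's-alpha.
Pearson's r is computed on the slope point estimates; estimation error in
the slopes is deliberately not propagated (no attenuation correction), so r
values are descriptive, matching standard practice for this analysis. To
guard against a few extreme series driving a correlation,
`sensitivity_correlations()` re-estimates r while removing
`round(f * n)` randomly chosen assemblages, 200 times each at f = 5%, 10%
and 20%. `round()` semantics are kept as-is: at small n a 5% drop can round
to zero removals, and such replicates simply reproduce the full-data r.

## Persistence classification of rare populations

To ask whether rare species are immigrating more than they are going locally
extinct, every population (species × assemblage) whose rarefied abundance is
1 or 2 in at least one year is selected, keeping its full trajectory
(`select_rare_populations()`). The trajectory becomes a binary presence
string over the retained years; a 0→1 transition is an immigration event, a
1→0 transition a local extinction (`count_transitions()`).

Noise in detection can fabricate such transitions, so classification is
gated by a two-sided Wald–Wolfowitz runs test (`runs_test()`, normal
approximation without continuity correction, alpha = 0.05 by default):

* no absences at all → **persistent**;
* runs test undefined (one-level string) or non-significant → **persistent**
  (events indistinguishable from noise);
* otherwise one immigration and no extinction → **immigration**; one
  extinction and no immigration → **extinction**; two or more events in
  total → **multiple** (this includes strings that start and end present
  with significant interior absences).

The 0.05 two-sided gate is a documented choice (the convention for this
test), configurable via `alpha`. The normal approximation is accurate in
the significance tail that actually decides the gate — for the canonical
alternating string `0101010101` it gives p = 0.0073 against an exact
enumeration value of 0.016 — but it is *not* uniformly accurate for short
strings: enumerating all arrangements of lengths up to 12 shows
absolute p discrepancies up to about 0.68 near the centre of the run-count
distribution for short, unbalanced strings. This mirrors the behaviour of
the standard implementation of the test and is measured, not hidden, by the
test suite; for the string lengths where the gate matters (10+ years) the
decisions are stable.

## The synthetic-data generator

`generate_scenario()` emits records in the same long schema as the reader,
plus full ground truth (latent expected abundances, per-species slopes,
arrival and extinction years, noise-free trajectories, effort). The model:
initial expected abundances are drawn from a log-series distribution whose
mixing parameter is derived from the pool size and `sad_alpha`; each species
follows `lambda(t) = lambda(0) * exp(b t)` with `b ~ N(trend_mean,
trend_sd^2)`; immigrants arrive as a Poisson process and start at expected
abundance 1. Observations split each yearly expectation evenly across a
uniformly drawn number of occasions, with independent Poisson counts per
occasion (or a fixed multinomial yearly total for size-controlled tests).

Defaults (60 resident species, `sad_alpha = 15`, 2–4 occasions per year)
give yearly samples of several hundred individuals with 40–55 observed
species and 15–25 rare species — the shape of a typical well-sampled
monitoring series. The three presets encode the conceptual processes:

* `population_decline`: `trend_mean = -0.05` (5%/yr decline,
  `trend_sd = 0.03`), no immigration; latent abundances are floored at 0.5
  so declining species linger as rare instead of vanishing. Noise-free
  richness is exactly flat, size falls, rarity rises, and rarity slopes
  anticorrelate with (log10) size slopes.
* `decline_extinction`: the same declines, but a species whose latent
  abundance falls below the presence threshold (0.5) goes extinct
  permanently. The latent-threshold rule (rather than, say, a run of
  sampled zeros) keeps the ground-truth trajectories deterministic given
  the config, which the scenario-logic checks rely on. Richness and size
  fall together.
* `immigration`: stable residents (`trend_sd = 0.01`) with 0.5 expected
  arrivals per year at abundance 1. The rate is calibrated so the true
  rarity trend is roughly +1% per year on the log scale against a baseline
  of ~25–30 observed rare species. Rarity and richness rise together.

Ground-truth trajectories count a species as present at latent abundance
≥ 0.5 and rare in [0.5, 2.5]; `truth_slopes()` reports richness and size
slopes on the log10 scale to match the fitted models. For recovery testing,
`expected_rarity_slope()` computes the *exact* expectation of the rarefied
rare-species count implied by the latent abundances and realized effort
(rarefied counts are Poisson with mean `lambda * n_min / n_t`), and takes
the per-assemblage OLS slope of its log — the same log-linear functional
the negative-binomial model estimates. `rarity_slope_recovery()` wraps the
whole loop: on 50 replicates of 60 assemblages × 20 years, the fitted
overall slope recovers the true sign in 100% of replicates and its 95%
interval covers the truth in 98% (computed by the acceptance suite; the
checks require ≥ 95% and ≥ 85%).

What the generator does *not* emulate: detection heterogeneity among
species, temporal autocorrelation in the environment, species interactions,
and spatial structure. Passing recovery tests therefore demonstrate that
the estimation chain is consistent with its own assumptions at realistic
sizes, not that those assumptions hold for any particular field dataset.

## Numerical and design choices

* **Year filter**: the effort mean is computed once on the raw series, not
  iteratively; ties at exactly half the mean are kept.
* **Non-integer abundances** (some sources store summed counts as numeric)
  are floored, with a logged count, preserving count semantics
  deterministically; rows with abundance ≤ 0 are dropped as implicit
  absences; duplicated keys are summed.
* **Fisher's alpha tolerance**: root-finding to `1e-12` with Newton
  polishing; degenerate `S == N` years raise or return `NA` per
  `on_degenerate`.
* **Seeds**: every stochastic function takes an explicit seed and restores
  the global RNG state (`withr::with_seed`); derived seeds come from a
  fixed mixing scheme and stay below 2^31.
* **Pipeline sizes**: the bundled end-to-end runs use 10–20 assemblages ×
  12 years with 3–20 rarefaction iterations, and the recovery experiment
  uses 50 replicates of 60 × 20 — sizes at which every stage's behaviour is
  already stable and a full run completes in minutes on one CPU.
* **Degenerate correlations**: if a facet's random-slope variance collapses
  to zero, its per-assemblage slopes are all equal and correlations with it
  are undefined; the pipeline reports `NA` for those pairs (with a warning)
  instead of aborting.

## Known limitations

* Wald intervals on the overall slope ignore uncertainty in the variance
  components; with ≥ 30 assemblages this is minor (coverage 98% in the
  recovery experiment) but intervals can be anticonservative for very few
  assemblages.
* The runs-test gate uses the normal approximation everywhere, including
  short strings where it is crude (see above); an exact gate would change
  classifications mainly for series near the 10-year minimum.
* Slope correlations are attenuated by estimation error in the slopes; the
  package reproduces the conventional analysis and does not correct for
  this.
* `is_aggregable = FALSE` data (sessile/floral studies that should not be
  summed within years) are handled by the default single-occasion path;
  no separate seasonality treatment is implemented.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  scenario = scenario_preset("immigration", n_assemblages = 20,
                             n_years = 12, seed = 11),
  n_iterations = 20, seed = 5
)
run <- run_all(cfg)
print(run)
```
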