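# raretrends

Trends in local rarity across ecological assemblage time series.

Most assemblages contain a few common species and many rare ones, so the
number of locally rare species — species represented by only one or two
individuals in a standardized yearly sample — is a sensitive lens on recent
biodiversity change. Rising rarity can mean two very different things:
resident populations declining toward local extinction, or new species
immigrating in low numbers. The two processes are distinguishable from the
*joint* trends of rarity, species richness and assemblage size, and from
the balance of immigration vs. local-extinction events among rare-species
populations.

`raretrends` is for ecologists analysing long-format monitoring data (one
row per assemblage × year × sampling occasion × species count, as exported
by community time-series databases). It implements the full analysis chain:

1. **Sample-based rarefaction** — excludes under-sampled years (fewer than
   half the mean number of sampling occasions), then draws the minimum
   yearly number of *whole* occasions from every year, summing species
   abundances within years; repeated over independent iterations to check
   robustness to the random draw.
2. **Rarity metrics per year** — singletons, singletons + doubletons,
   Fisher's log-series alpha (the positive root of
   `S = alpha * ln(1 + N/alpha)`), richness `S`, assemblage size `N`.
3. **Mixed-effect trend models** — each facet regressed on mean-centred
   year with a random intercept and slope per assemblage: negative binomial
   (log link) for counts, Gaussian for log10 richness/size, and a
   power-of-fitted variance structure for Fisher's alpha. One overall slope
   plus per-assemblage slopes (BLUPs).
4. **Slope correlations across facets** — Pearson's r between
   per-assemblage slopes (rarity–richness, rarity–size, richness–size, and
   metric-agreement pairs), with a drop-5/10/20% resampling sensitivity
   analysis (200 replicates).
5. **Persistence classification** — rare-species populations become binary
   presence strings; 0→1 and 1→0 transitions are immigration and local
   extinction events, gated by a Wald–Wolfowitz runs test so noise does not
   inflate event counts; each population ends up persistent / immigration /
   extinction / multiple.
6. **Synthetic scenarios with ground truth** — a generator that emulates
   multi-assemblage count data under population decline (with or without
   extinctions) or immigration, used to validate every stage against known
   truth.

## Worked example

Simulate an immigration-driven world (20 assemblages, 12 years, ~0.5 new
species arriving per assemblage-year) and run the full pipeline:

```r
library(raretrends)

cfg <- run_config(
  scenario = scenario_preset("immigration", n_assemblages = 20,
                             n_years = 12, seed = 11),
  n_iterations = 5, seed = 5
)
run <- run_all(cfg)
print(run)
```

```
Rarity-trend pipeline run
  assemblages analysed: 20  ( 0  excluded )
  overall slopes (per year, link scale):
    n_rare          +0.01103  [+0.00243, +0.01962]
    n_singletons    +0.01228  [+0.00043, +0.02413]
    fisher_alpha    +0.05860  [+0.02095, +0.09625]
    log10_richness  +0.00132  [+0.00002, +0.00262]  (x1.003 per year)
    log10_size      +0.00028  [-0.00427, +0.00483]  (x1.001 per year)
  slope correlations:
    n_rare ~ log10_richness: r = -0.021 (n = 20)
    n_rare ~ log10_size: r = -0.667 (n = 20)
    log10_richness ~ log10_size: r = -0.100 (n = 20)
    n_rare ~ n_singletons: r = 0.888 (n = 20)
    n_rare ~ fisher_alpha: r = 0.763 (n = 20)
  rare populations: 907 
    persistent    847 (93.4%)
    immigration    25 ( 2.8%)
    extinction     13 ( 1.4%)
    multiple       22 ( 2.4%)
```

Reading the output: the number of rare species rises by about 1.1% per year
(the negative-binomial model works on a log link, and the 95% interval
excludes zero), richness rises by a factor 1.003 per year, and assemblage
size shows no clear trend. Among the 907 populations that were ever rare,
most are persistent, and immigration events outnumber local extinctions
(2.8% vs 1.4%) — the fingerprint of the immigration process that generated
the data. Per-assemblage slopes, per-iteration robustness and the
sensitivity distributions are in `run$assemblage_trends`, `run$robustness`
and `run$sensitivity`; `run_config(out_dir = ...)` writes every stage as
CSV plus a JSON report.

To analyse real data instead, point `run_config(input = "file.csv")` at a
long-format CSV; the default column mapping (`biotime_schema()`) matches
BioTIME-style exports and is fully remappable.

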