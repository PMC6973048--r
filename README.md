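# phenosynch

Quantitative analysis of flowering phenology from individual-level records
on a weekly census calendar.

Field surveys of flowering phenology often record, for every individual
plant (or flowering shoot), the first and last census dates on which it was
seen in flower. From such records, community ecologists want to compare
life forms — trees, perennial herbs, annuals — on variables like how long a
species flowers in total, how long its individuals flower on average, and
how synchronized those individuals are, and then ask whether species-level
flowering is phylogenetically conserved and how synchronous the community
is as a whole. `phenosynch` implements that workflow end to end, including
the sample-size standardization needed when species differ widely in the
number of observed individuals, and a synthetic-data generator so the whole
pipeline can be exercised against known ground truth.

## What it computes

**Species-level variables** (per species and year, from individual
`[onset, end]` intervals observed on census dates):

- total flowering length `TFL = max(end) − min(onset) + 1` (days),
- mean and variance of individual flowering lengths (`MFL`, `VFL`;
  inclusive-day lengths, sample variance),
- moment skewness and kurtosis of the length distribution,
- onset variance (days² since the first-blooming individual),
- Morisita's aggregation index over the season's census bins,
  `Iδ = q Σ nᵢ(nᵢ−1) / (N(N−1))`, with `nᵢ` the count of individuals in
  flower at census `i`; large `Iδ` = high intraspecific synchrony.

**Sample-size standardization** by bootstrap rarefaction–extrapolation:
per species, the bootstrap mean of each variable at sample sizes
`j = 1..n`; linear, logarithmic, quadratic and logistic mean functions
fitted to the pooled max-standardized curves; the BIC-selected form fitted
back to each species' raw curve and evaluated at standardized sizes
(default 5, 7, 12, 18, 22 individuals).

**Life-form comparisons**: Student's *t*, Wilcoxon rank-sum or the
Fligner–Policello robust rank-order test chosen from Shapiro–Wilk and
median-centered Levene diagnostics, Holm-adjusted across pairs; and gamma
(log link) or Gaussian mixed models with a genus random intercept
(`lme4`), including likelihood-ratio screens for year and sampling-effort
effects.

**Community-wide synchrony** (Loreau & de Mazancourt):

    φ = Var[x_T(t)] / ( Σᵢ SD[xᵢ(t)] )²,   x_T(t) = Σᵢ xᵢ(t)

on the census-date × species matrix of simultaneously flowering
individuals; φ = 1 for perfectly synchronous species, ≈ 1/S for S
independent ones. Species-bootstrap percentile confidence intervals, and
D'Agostino–Pearson K² tests of onset-date skewness.

**Phylogenetic signal**: Felsenstein's independent contrasts, Blomberg's
K (K = 1 under Brownian motion on the given tree), and a tip-shuffling
permutation test on the contrast variance.

**Synthetic data**: hierarchical generator of flowering records under the
weekly census protocol (species peak onsets, within-species onset spread,
gamma flowering lengths, census-resolution observation and censoring),
plus Yule trees and Brownian traits.

## Worked example

```r
library(phenosynch)

cals <- list(weekly_calendar(2016), weekly_calendar(2017))
sim  <- simulate_records(default_sim_config(), cals, seed = 42)
ds   <- filter_species(sim$dataset)   # >2 flowering days, >=5 individuals/year
ds
#> Flowering phenology dataset: 1692 records, 48 species, years 2016, 2017
#>   life forms: annual=20, perennial=15, tree=13

s <- summarize_species(ds)
aggregate(cbind(TFL, VFL, morisita) ~ life_form, data = s, FUN = median)
#>   life_form TFL  VFL morisita
#> 1    annual  64 90.0     2.48
#> 2 perennial  57 63.8     2.74
#> 3      tree  29 17.0     5.77
```

The generated community reproduces the expected life-form contrast: trees
flower for a much shorter total period (median TFL 29 vs 57–64 d), with
far smaller length variance and higher intraspecific synchrony (Iδ), even
though all three life forms share the same mean flowering length by
construction. Standardizing to 12 observed individuals and testing:

```r
std <- standardize_estimates(ds, variables = c("TFL", "VFL", "morisita"),
                             n_std = 12, B = 200, seed = 42)
attr(std, "forms")
#>        TFL        VFL   morisita
#> "logistic"   "linear" "logistic"

d <- subset(std, variable == "VFL")
compare_groups(d$value, d$life_form)
#>     group_a   group_b test_used statistic    p_raw p_adjusted
#> 1    annual perennial         t      2.95 5.84e-03   5.84e-03
#> 2    annual      tree         t      7.08 5.92e-08   1.18e-07
#> 3 perennial      tree         t      8.31 8.66e-09   2.60e-08

M <- build_community_matrix(ds, 2016, "annual")
bootstrap_group_ci(M, "phi", B = 1000, seed = 42)
#> phi = 0.4645, 1000 bootstrap replicates (1000 defined): [0.3328, 0.6992]
```

The standardized VFL comparison finds trees significantly below both herb
groups after Holm adjustment, and annual flowering is weakly but
positively synchronized across species (φ ≈ 0.46, CI excluding 0).
`run_phenology_pipeline()` chains all stages (filter → summaries →
rarefaction → comparisons → synchrony → phylogenetic signal) from one
seeded config and writes CSV reports plus a run log.

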