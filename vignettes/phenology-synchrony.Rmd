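---
title: "Methods: flowering phenology statistics, standardization and synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flowering phenology statistics, standardization and synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the observation
model, each statistic and test, the tunable parameters and why their
defaults are what they are, the numerical choices, what the synthetic-data
generator does and does not emulate, and the known limitations.

## The observation model

All analyses start from individual-level flowering records collected on a
**weekly census calendar** (by default 1 March–31 July, censuses every 7
days; `weekly_calendar()`). For each individual — a tree, or a flowering
shoot of a herb, the package does not distinguish — two dates are recorded:
the first census on which it was seen in flower (*onset*) and the last
(*end*). Consequently:

- every onset/end is a member of the calendar, which validation enforces;
- all date arithmetic is in integer days on ISO-8601 dates;
- individual flowering length is **inclusive**, `(end − onset) + 1`, so an
  individual seen in flower exactly once has length 1 day rather than 0.
  The alternative (exclusive) convention shifts every length by one day and
  therefore cannot change any of the comparisons; the inclusive form is
  used because a length of 0 for an observed flowering is not meaningful.
- records missing either date are rejected, not imputed: the analyses are
  defined on complete intervals only.

Two inclusion filters are applied before species-level statistics
(`filter_species()`): a species must have flowered on **more than**
`min_flowering_days` census dates (default 2; the count is of distinct
year–date pairs with at least one individual in flower — a species-level
reading, since an individual-level one would discard short-lived but
well-sampled species), and must have at least `min_individuals` (default
5) individuals, per year in every year when `require_both_years = TRUE`.
The filter is idempotent and monotone in its thresholds.

## Species-level variables

For each species-year (`summarize_species()`):

- **TFL** (days): `max(end) − min(onset) + 1`. Gaps between disjoint
  individual intervals count, by definition.
- **MFL** (days): arithmetic mean of individual lengths. **VFL** (days²):
  their sample variance. All variances in the package use the `n − 1`
  denominator.
- **skewness / kurtosis** of the length distribution: raw moment
  estimators `m₃/m₂^{3/2}` and `m₄/m₂²` without small-sample bias
  correction; kurtosis is *non-excess* (normal = 3), with an
  `excess_kurtosis` flag. The raw convention was chosen because the
  variables are reported on the "normal = 3" scale elsewhere in the
  workflow; both are flagged undefined below n = 3 and n = 4 respectively,
  or when `m₂ = 0`.
- **onset variance** (days²): sample variance of onset offsets (days since
  the species' first onset that year). The offset standardization is
  cosmetic — variance is shift-invariant — but keeps the values readable.
- **Morisita's aggregation index** `Iδ = q Σ nᵢ(nᵢ−1) / (N(N−1))`, where
  `nᵢ` counts the individuals of the species in flower at census `i`
  (an individual contributes to every census inside its interval — the
  index describes the temporal distribution of flowering individuals, not
  of onset events; an onset-count variant exists via `counts = "onset"`).

### Why the Morisita bins are the season calendar

The bin set for `Iδ` was a genuinely open choice. The package's default is
the **full season calendar** (`bins = "season"`): every species is scored
over the same `q` census bins, and a species whose individuals concentrate
their flowering into a few of those bins gets a large index. This matches
the intended reading "larger `Iδ` = higher intraspecific synchrony" and
what one gets by feeding a fixed community matrix to a dispersion-index
routine. The alternative — bins restricted to the species' own flowering
window (`bins = "flowering"`) — turns out to measure something else:
within its own window a *perfectly synchronous* species has uniform counts
(`Iδ = q(n−1)/(qn−1) < 1`, slightly **below** 1), while an asynchronous
species has hump-shaped counts over a long window and `Iδ > 1`. The
window-restricted variant thus inverts the synchrony ordering and is kept
only as an explicit flag for studying within-period aggregation.

## Bootstrap rarefaction–extrapolation

Observed sample sizes per species vary widely (realistically 1–69), and
several variables — TFL and `Iδ` especially — increase with the number of
individuals observed. To compare species at a common effort
(`standardize_estimates()`):

1. **Curves.** For each species(-year) and variable, and each sample size
   `j` from the statistic's minimum (1 for TFL/MFL; 2 for VFL, onset
   variance, `Iδ`; 3 for skewness; 4 for kurtosis) to the species' own `n`,
   draw `j` individuals with replacement `B` times (default `B = 1000`)
   and average the statistic over the replicates in which it is defined.
   Replicates where a statistic is undefined (e.g. skewness of an
   all-identical draw) are dropped and the effective replicate count is
   recorded; a whole-`j` point with no defined replicate is dropped with a
   warning.
2. **Model selection.** Each species' curve is rescaled by its own maximum
   and the points pooled across species; linear `a + bj`, logarithmic
   `a + b ln j`, quadratic `a + bj + cj²` and 3-parameter logistic
   `a / (1 + e^{−b(j−c)})` mean functions are fitted by least squares and
   compared by `BIC = m ln(RSS/m) + k ln m` with `k` = mean-function
   parameters + 1 (Gaussian error model on the curve points).
3. **Standardized values.** The selected form is then fitted to each
   species' **raw** (unstandardized) curve and evaluated at the
   standardized sizes (default 5, 7, 12, 18, 22), interpolating or
   extrapolating beyond the species' own `n` as the fitted form dictates.
   Max-standardization is applied only for the pooled model selection,
   where it stops large-valued species dominating the fit; per-species
   evaluation must stay on the original scale.

Numerical choices: `RSS/m` is floored at `1e−12` so that exactly
interpolating fits compare by parameter count alone; BIC ties go to the
model with fewer parameters and then to the fixed order linear <
logarithmic < quadratic < logistic; the logistic fit is initialized at
`a₀ = max y`, `c₀ = j` at half-maximum, `b₀ = 1`, bounded, with at most
500 Levenberg–Marquardt iterations, and is excluded from the comparison
with a warning if it fails to converge; a failed per-species fit falls
back to the bootstrap mean at the nearest available `j`, with a warning.
Reproducibility: one master seed; per-(species, year, variable) sub-seeds
are derived by hashing so results do not depend on evaluation order.

## Life-form comparisons

`compare_groups()` applies, per pair of life forms, the decision rule:
Student's *t* (pooled variance) when both samples pass Shapiro–Wilk at
`alpha`; otherwise Wilcoxon rank-sum when a median-centered Levene test
finds no variance difference at `alpha`; otherwise the Fligner–Policello
robust rank-order test. Shapiro–Wilk and median-centered Levene at
`alpha = 0.05` are the package's choices where the procedure itself was
open; both are arguments. The Fligner–Policello statistic uses
half-weighted tie placements and the large-sample normal reference — group
sizes here (≈13–20 species) are in the range where that approximation is
standard; under complete separation the placement variance vanishes and
the statistic is reported as ±∞ with p = 0, while fully tied samples are
an error. Holm's step-down adjustment (via `stats::p.adjust`) is applied
across the pairs.

`fit_pheno_glmm()` fits genus-random-intercept models: gamma errors with a
**log link** for positive variables, Gaussian/identity for sign-changing
ones (skewness), by Laplace-approximated ML in `lme4`. (A "lognormal link"
does not exist as a GLM link; log link with gamma errors is the standard
reading of that phrase, and is what is implemented.) Fixed-effect p values
are Wald normal approximations; the year/effort screens in
`compare_lmm_models()` use ML likelihood-ratio tests of the nested models
(random intercept only; + year; + number of observed individuals), each on
1 df. Gaussian fits expose `REML = TRUE` because REML — not ML — is the
estimator that coincides with the closed-form ANOVA variance components in
balanced designs, which is also how the variance-component tests validate
the implementation. Singular fits (genus variance 0) are returned with a
warning, not an error. The pipeline pools the two survey years for a
variable only when its year effect is non-significant at `alpha`
(`pool_years = "auto"`; either mode can be forced).

## Community-wide synchrony

`build_community_matrix()` lays out `xᵢ(t)`, the number of individuals of
species `i` in flower at census `t`, over the full season of one year, and

`synchrony_phi()` computes `φ = Var[x_T] / (Σᵢ SD[xᵢ])²`. The squared
*sum of standard deviations* in the denominator is the Loreau–de
Mazancourt (2008) definition; it guarantees `φ ∈ [0, 1]` (Cauchy–Schwarz)
with 1 at perfect positive linear synchrony and expectation ≈ `1/S` for
`S` independent equal-variance series. A literal sum-of-variances
denominator is available (`denominator = "var_sum"`) purely for
sensitivity analysis — it is not bounded by 1. Sample (`T − 1`) variances
are used in numerator and denominator; the ratio is invariant to that
choice when consistent.

Species-level onset (for skewness and its test) is the earliest individual
onset of the species in that year. D'Agostino–Pearson's `K²` combines the
skewness transform (D'Agostino 1970) and the kurtosis transform
(Anscombe–Glynn 1983) into `Z₁² + Z₂² ~ χ²(2)`; `n ≥ 8` is enforced
because the kurtosis approximation degrades below that.

`bootstrap_group_ci()` resamples **species** with replacement at the
group's own size (columns of the community matrix for φ, onset values for
skewness) and returns percentile intervals. One property of this design is
worth knowing: resampled communities contain duplicated species, and
duplicated series are perfectly synchronous, so for independent equal-SD
series the resampled φ has expectation `(2S−1)/S²` (≈ 0.19 at S = 10),
about twice the unresampled `1/S`. The interval is therefore a spread
summary of the species-resampling distribution, not an unbiased CI for φ
itself; comparisons *between* life forms, which is how it is used, are
unaffected because the same inflation applies to every group.

## Phylogenetic signal

`pic_contrasts()` implements Felsenstein's pruning pass (contrast
`(x₁−x₂)/√(b₁+b₂)` at each node, branch-length-weighted ancestral values,
parent branch extended by `b₁b₂/(b₁+b₂)`); `blomberg_k()` the
ratio-of-ratios `K` with the Brownian-motion expectation term computed
from the tree covariance. `signal_test()` shuffles trait values across
tips and compares the observed mean squared contrast against the
permutation distribution with the add-one estimator
`p = (1 + #{s_perm ≤ s_obs}) / (n_perm + 1)` — small contrast variance
relative to shuffles means relatives resemble each other; `p` can never be
exactly 0. A `K`-based permutation (rejecting for large `K`) is available
behind `statistic = "K"`; the contrast-variance statistic is the default
because the permutation null is exchangeability of tips, under which the
contrast variance is the natural pivot. Trees are **consumed, never
estimated**: polytomies are resolved arbitrarily into zero-length binary
splits and any zero branch length is perturbed by `1e−8 ×` tree depth so
contrast standardization never divides by zero; duplicate tips or missing
branch lengths are errors. Constant traits yield `p = 1` with a warning.

## The synthetic-data generator

`simulate_records()` generates what the weekly protocol would record from
a hierarchical ground truth, per life form (`life_form_params()`):

| parameter | units | role |
|---|---|---|
| `peak_onset_mean`, `peak_onset_sd_between` | day of year, days | placement and spread of species peaks across the season |
| `onset_sd_within` | days | within-species onset spread — the intraspecific synchrony dial |
| `mfl_mean`, `mfl_sd_between` | days | species mean flowering length and its spread |
| `vfl_within` | days² | within-species variance of gamma-distributed lengths (mean/variance parameterization, truncated at 1 d) |
| `n_individuals_range` | counts | per-species observed-individual range |

Observation is census-resolution only: observed onset (end) is the first
(last) census covered by the true continuous interval, so censoring can
only shorten intervals, and individuals covering no census are dropped
entirely. Genus labels are assigned round-robin over species ordered by
peak onset with at most three species per genus — shallow, slightly
unbalanced structure that exercises the random-intercept machinery —
and families group two genera each.

`default_sim_config()` encodes a temperate-forest-like community: 13 tree
/ 15 perennial / 20 annual species; trees peak in May with
`onset_sd_within = 3` d and `vfl_within = 9` d², herbs peak earlier with
spreads of 12–14 d and length variances of 64–100 d²; `mfl_mean = 20` d
for everyone, so TFL differences arise from synchrony and length variance
alone, not from mean length. These are fixed study conditions, chosen once
to match the qualitative structure the analyses are meant to detect
(brief, synchronous mass flowering in trees; extended, staggered flowering
in herbs with annuals starting earliest).

What the generator does **not** emulate: spatial plot structure, weather
covariates or climate-driven between-year differences (beyond an optional
constant year offset), flower abundance within individuals, observation
error in flower detection, and phylogenetic correlation between the trait
values and the genus labels (genera group by flowering time, not by
descent). Tests passing on this substrate therefore validate the
statistical machinery and its operating characteristics, not the
biological realism of any particular field system.

`simulate_yule_tree()` builds a pure-birth tree by the waiting-time
construction (time with `k` lineages ~ Exp(`k·λ`), uniformly chosen lineage
splits, final Exp(`n·λ`) stretch), giving expected depth
`Σ_{k=2}^{n} 1/(kλ)`; `simulate_bm()` adds preorder Gaussian increments
with variance `σ² ×` branch length from a root value of 0.

## Problem sizes used in the package's own checks

The simulation-based checks fix their sizes as follows: synchrony's
independence law with S = 10 series × 200 time points × 500 replicates;
Blomberg's K under Brownian motion with 200 replicate traits on a 100-tip
Yule tree; curve-family recovery with noise σ = 0.01 over 100 seeded runs;
the end-to-end life-form contrast with 15 + 15 species × 15 individuals,
B = 200 bootstrap replicates per curve point, 100 simulated communities
(B = 200 there controls only the Monte-Carlo error of curve points, which
is far below the between-species spread that drives the tests; the
analysis default stays B = 1000); and size checks of the permutation and
likelihood-ratio tests with 500 replicates at nominal α = 0.05.

## Known limitations

- Census resolution bounds every quantity: onsets and lengths are only
  known to ±1 census interval, and `Iδ` depends on the census spacing.
- The Fligner–Policello p value is asymptotic; below ~n = 12 per group an
  exact placement-table version would be preferable (not implemented).
- The rarefaction curves extrapolate beyond a species' own `n` through the
  fitted form; extrapolation error is not propagated into the downstream
  tests, mirroring the plug-in design of the original procedure.
- Wald p values in the gamma GLMM use the normal approximation; for the
  small genus counts typical here they are approximate, and the LRT-based
  screens should be preferred where the two disagree.
- The species-bootstrap φ interval is biased upward relative to the
  plug-in φ (see above); use it comparatively, not as an absolute CI.
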