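---
title: "Methods: diversity partitioning, plant strength, nested models and power for bumblebee transect surveys"
author: "corridorbees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity partitioning, plant strength, nested models and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridorbees)
```

# The data model

A transect survey has a two-level sampling frame: spatially discrete
**sites** (some bisected by an electricity transmission corridor, some
not), each holding several 50 m **transects** spread over up to seven
habitat types, each transect walked in two (or more) survey **rounds**.
Every foraging bumblebee individual is one visit record carrying its
species and, where identified, its host plant; every transect-round
carries an ordinal flower-density class (seven classes of percent flower
cover: `<1`, `1–5`, `6–10`, `11–20`, `21–40`, `41–60`, `>61`).

`SurveyDesign` validates the frame (closed habitat vocabulary, classes in
1..7, unique transect-round keys, corridor status defined per site).
`BeeAbundance` is a `SummarizedExperiment` with species as rows and
observations as columns, so the count matrix and the per-observation
design metadata travel together and subset together.

**Observation unit.** The default unit is the transect-round: each survey
round is one model observation, which keeps the flower covariate at the
resolution it was recorded. `buildAbundance(aggregateRounds = TRUE)` sums
rounds per transect (averaging the flower class) for analyses that treat
the transect as the unit. Both conventions are supported because printed
degrees of freedom in the field's reports can rarely be reconstructed
unambiguously from the design alone; all downstream functions respect the
chosen unit.

**Species identity.** Labels are free text, normalized only by trimming
and whitespace collapsing; taxonomic pooling happens solely through the
explicit alias map (by default *Bombus lucorum* → *B. terrestris*, the two
being effectively indistinguishable as workers in the field). The alias
map is idempotent by construction. Species groups follow the standard
north-European split: *B. muscorum*, *B. humilis*, *B. sylvarum* and
*B. soroeensis* as threatened; *B. terrestris*, *B. lapidarius*,
*B. pascuorum*, *B. hypnorum*, *B. pratorum* and *B. hortorum* as the main
crop-pollination providers. Visits with unidentified host plants count for
abundance and richness but are excluded from the visitation matrix, since
dependency fractions are only defined over identified visits.

# Additive diversity partitioning

For a unit with observations $t = 1..n$ and per-observation richness
$S_t$:

$$\alpha = \frac{1}{n}\sum_t S_t, \qquad \gamma = \text{richness of the
pooled unit}, \qquad \beta = \gamma - \alpha.$$

At the **site** scale gamma is the plain pooled richness. At the
**habitat** scale gamma is rarefied (below) to $m$ individuals, default
$m = 90$, so habitats sampled with very different intensity are
comparable; the default is a conventional depth for communities of roughly
a thousand pooled individuals and is overridable everywhere
(`rarefactionM` in the pipeline, `m` in `partitionHabitat()`).

Two numerical points. First, $\beta$ is stored as the correctly rounded
double `gamma - alpha`, so `gamma - alpha == beta` holds bitwise;
re-summation `alpha + beta` recovers `gamma` to within one ulp, and that
is the strongest attainable guarantee — for some $(\alpha,\gamma)$ pairs
no representable double $\beta$ makes the rounded sum hit $\gamma$
exactly, because round-to-even can step past it. Second, rarefied gamma
can fall below raw alpha in species-poor, very even habitats, making
rarefied beta negative; the value is reported with a warning rather than
clipped, since clipping would silently break additivity.

# Exact individual-based rarefaction

The expected richness of a uniform random subsample of $m$ individuals
from pooled counts $N_1..N_S$, $N = \sum_i N_i$, is

$$E[S_m] = \sum_{i=1}^{S}\left[1 -
\binom{N-N_i}{m}\Big/\binom{N}{m}\right],$$

evaluated as `1 - exp(lchoose(N - Ni, m) - lchoose(N, m))` so that
communities of arbitrary size neither overflow nor lose the small terms;
when $m > N - N_i$ the log-binomial is $-\infty$ and the species
contributes exactly 1. Identities pinned by tests: $E[S_1] = 1$,
$E[S_N] = S_{obs}$, monotone and concave in $m$. When $m$ exceeds the
pooled total the observed richness is returned with a `shallow` flag that
propagates into partition tables — reporting a number while marking that
the standardization was not achievable. The implementation is checked two
independent ways: against full enumeration of all subsamples on a small
community, against heavy seeded Monte-Carlo subsampling, and against
`vegan::rarefy`.

# The corridor beta contrast

Whether corridor-bisected sites have more homogeneous composition is
tested by a one-way fixed-effects ANOVA of the per-site beta on corridor
status: with 10 sites (5 + 5) the F statistic has (1, 8) degrees of
freedom. The estimator is deliberately the textbook one — the quantity of
interest is a single number per site, and anything more elaborate would
manufacture precision the design does not have. If every site has
identical beta both mean squares vanish and the ratio is undefined; the
test reports F = 0, p = 1 for that degenerate case instead of a ratio of
rounding errors.

# Plant species strength

With visit counts $v_{ij}$ of pollinator $j$ on plant $i$ in a habitat
subset, dependency and strength are

$$d_{ij} = v_{ij} \Big/ \sum_i v_{ij}, \qquad s_i = \sum_j d_{ij},$$

so each dependency column sums to exactly 1 and
$\sum_i s_i = $ (number of pollinator species with at least one
identified visit in the subset) — a conservation identity the tests
enforce to $10^{-12}$. Strength is invariant to uniform scaling of any
pollinator's counts and unaffected by plants with zero visits. Ranks are
assigned by descending strength with ties broken alphabetically by plant
name; printed strength tables in the field show unique ranks without
stating a tie rule, and an explicit deterministic rule keeps output
reproducible. `strengthReport()` computes the three standard subsets
(all habitats, transmission corridors, semi-natural grasslands); a plant
absent from a subset is shown as `NA` there — zero identified visits and
true absence from the habitat are not distinguishable from visit data
alone, so both print identically.

# Nested Gaussian mixed models

Per-observation abundance or richness is modelled as

$$y_{srt} = \beta_0 + \beta_f\,\text{flower}_{srt} +
\text{habitat}_{srt} + \text{corridor}_{s} + b_s + b_{t(s)} +
\varepsilon_{srt},$$

with random intercepts $b_s$ (site) and $b_{t(s)}$ (transect within site),
fitted by REML through `nlme::lme` — the standard engine for this model
family with variance functions. Although counts are discrete, the Gaussian
analysis is the one this pipeline reproduces; a `logTransform` option
(`log(y+1)`) is available, and non-Gaussian GLMMs are out of scope by
design. The flower covariate defaults to the ordinal scores 1..7; a
midpoint encoding (0.5, 3, 8, 15.5, 30.5, 50.5, 70 percent cover) is
provided because the class-to-number mapping is a genuine modelling choice
the data do not settle.

"Constant variance" across strata is the default; `varStruct = "habitat"`
adds per-habitat variance weights (`nlme::varIdent`) for heteroscedastic
data, and reduces exactly to the homoscedastic fit when only one stratum
is present. The group models (provider and threatened abundance) use
habitat + flower with the same random structure and no corridor term.

**Sequential tests and denominator df.** `anovaTable()` reports type-I
(sequential) F-tests in the entry order flower, habitat, corridor — the
order the field's tables print. Denominator degrees of freedom follow the
grouping-level (containment) rule: corridor status is constant within
sites, so it is tested in the site stratum with
$n_{sites} - 1 - 1 = 8$ df for 10 sites; habitat varies between transects
within sites ($n_{transects} - n_{sites} - 6$ for seven habitats); the
flower class varies between rounds within transects
($n_{obs} - n_{transects} - 1$). The rule is validated against the
closed-form split-plot ANOVA on balanced designs. Note that observation
exclusions (which field datasets often have) change the inner df — the
rule is implemented generically rather than targeting any particular
printed value.

**Degenerate inputs.** A constant response (e.g. a species group never
recorded) yields a flagged non-converged `ModelFit` rather than an error
or a silent fit; a corridor term with a single site type is an error;
`lme` non-convergence is caught and flagged with its message.

On fully balanced designs the mixed fit's fixed effects equal ordinary
least squares to machine precision for any estimated variance components
(the projection argument), which is how the zero-variance degenerate limit
is tested without depending on whether REML lands exactly on the boundary.

# Synthetic surveys

The generator's defaults are the study conditions the package is built
around, chosen once: 10 sites of which half are corridor-bisected, the
seven habitats with a mean of 2.25 transects per site-habitat cell drawn
Poisson (so some sites lack some habitats; corridor transects exist only
at bisected sites), two rounds, and a 20-species community with log-series
relative abundances ($p_i \propto x^i/i$, $x = 0.85$) giving two dominant
species and a long rare tail. Counts follow a log link,

$$\log E[\text{count}] = \log(\text{baseMean}) + \beta_f(\text{flower}-1)
+ \text{habitat} + \text{corridor} + b_s + b_{t(s)},$$

drawn negative-binomial per species (variance $\mu + \mu^2/k$, default
$k = 2$; $k = \infty$ gives Poisson). Defaults `baseMean = 1.6` and
$\beta_f = 0.25$ per flower class step put the realized total around a
thousand individuals per survey with flower density as the dominant
predictor; habitat and corridor effects default to zero, and site and
transect random-effect SDs to 0.3 on the log scale. Flower classes are
drawn per habitat from unimodal distributions centred low in forest
(class 2), mid in crop edges and high on roadsides and grasslands
(class 5), mirroring typical cover differences. Host plants are allocated
per individual with probability proportional to (per-habitat availability)
× (bee-plant preference) over a 30-plant pool on a deterministic staggered
availability grid; 5% of visits get an unidentified host.

The generator is deliberately more dispersed than the Gaussian model used
for inference — that mismatch is informative, since the pipeline should
behave on realistic ecological counts. A Gaussian response generator
(`simulateResponse()`) with the same linear predictor exists for
exact-recovery and power experiments. What the generator does **not**
emulate: spatial structure and foraging distances, phenology within the
season, detection error, and any correlation between a species' abundance
and its plant preferences. Tests passing on synthetic data therefore
certify the computations and their calibration, not the field realism of
any particular dataset.

All realizations are reproducible from `(config, seed)`; the seed is
mandatory and every stage derives its stream from it.

# Power

"A 20% difference" is interpreted as the focal group's expected response
being 20% above the reference group's mean expected response, holding
everything else fixed — the percentage-change convention of
simulation-based power tools for mixed models. `setEffect()` rescales the
focal coefficient accordingly (`pct = 0` returns the null generator
unchanged); the direction is positive, and for Gaussian models power is
symmetric in sign. `estimatePower()` simulates over the observed design,
refits, tests the focal term at $\alpha$ (default 0.05) with the
sequential F-test, and reports the rejection fraction with a 95% Wilson
interval; non-convergent replicates are dropped and counted, never
imputed. Calibration is tested three ways: rejection at zero effect equals
$\alpha$; on a two-group design the simulated power matches the
closed-form noncentral-t power; and power is monotone in effect size and
design size.

# Problem sizes in the test suite

The suite exercises the full 158-transect, 10-site frame where the
df structure matters, and smaller seeded frames elsewhere: 100 seeded
surveys for partition additivity, 50 random communities against a
$10^5$-replicate Monte-Carlo subsampler for rarefaction, 1000 null
refits for the type-I calibration of the corridor test, 200 refits for
flower-effect recovery and coverage, and 500-replicate power runs on the
two-group analytic design. These sizes give Monte-Carlo standard errors
comfortably inside the asserted 3-SE bands while keeping a full run in
the minutes range.

# Known limitations

* Gaussian inference on counts: adequate for the moderately large
  per-observation totals the defaults produce, questionable for very
  sparse responses (the threatened-species model on thin data); the
  log(x+1) option mitigates but does not remove this.
* The containment df rule is one convention; Satterthwaite or
  Kenward-Roger approximations would differ on unbalanced designs and are
  not provided.
* Rarefaction is individual-based only; coverage-based and
  incidence-based estimators are out of scope.
* Strength measures use, not preference: a plant can rank high simply by
  being abundant. No null-model correction is attempted.
* The beta contrast treats per-site beta as an ordinary response; with 10
  sites its power is intrinsically low.
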