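# corridorbees

Bumblebee (*Bombus* spp.) transect-survey analysis for habitat mosaics that
include maintained infrastructure corridors — electricity transmission
corridors, mown roadsides and ditches — alongside semi-natural grasslands,
forest and crop edges. The package is aimed at community ecologists who
survey pollinators along fixed transects across several sites and habitat
types and want a tested, reproducible route from raw visit records to
diversity partitions, plant-importance tables, mixed-model tests and power
estimates.

The typical study design it serves: a set of spatially discrete sites, some
bisected by a transmission corridor and some not, each surveyed over several
habitat types with multiple 50 m transects per site-habitat cell and repeat
survey rounds, recording every foraging bumblebee and, where possible, its
host plant, together with an ordinal flower-density class (seven classes of
percent cover) per transect and round.

## What it computes

**Additive diversity partitioning.** For a unit (site or habitat) with
per-transect species richness, alpha is the mean richness per observation,
gamma the richness of the pooled unit, and beta the turnover component

> β = γ − α

so the three components are additive. At the habitat scale gamma is
rarefied to a fixed number of individuals (default m = 90) to remove
differences in sampling intensity.

**Exact individual-based rarefaction.** The expected richness of a uniform
subsample of m individuals from pooled counts N₁…N_S (N = ΣNᵢ) is the
hypergeometric expectation

> E[S_m] = Σᵢ [ 1 − C(N−Nᵢ, m) / C(N, m) ]

computed with log-combinatorics so large communities do not overflow.

**Plant species strength.** With visit counts v_ij of pollinator j on plant
i, the dependency of pollinator j on plant i is d_ij = v_ij / Σᵢ v_ij, and
a plant's strength is s_i = Σⱼ d_ij. Strengths across plants sum exactly to
the number of pollinator species; the metric measures use, not preference.

**Nested Gaussian mixed models.** Abundance or richness per observation is
modelled as flower density + habitat + corridor status with random
intercepts for transect nested within site (REML via `nlme`), optional
per-habitat variance weights, sequential F-tests, and level-based
denominator degrees of freedom: with 10 sites the corridor test has
df = (1, 8) regardless of the number of transects. Provider-species and
threatened-species abundance models drop the corridor term.

**Simulation-based power.** A focal percentage difference (default 20%) is
injected into the generator, responses are simulated over the observed
design, the model refitted and the focal term tested at α = 0.05; power is
the rejection fraction with a Wilson interval.

**Synthetic surveys with known truth.** A seeded generator emulates the
whole design (10 sites, half with corridors, 7 habitats, ~2.25 transects
per site-habitat cell, 2 rounds, a 20-species log-series community of about
a thousand individuals, habitat-specific plant availability), so every
stage is testable against ground truth without field data.

## Worked example

```r
library(corridorbees)

cfg <- simConfig(seed = 2024)     # default = the emulated study conditions
sv  <- simulateSurvey(cfg)
sv$abundance
#> BeeAbundance: 20 species x 296 observations; 1212 individuals

ps <- diversityPartitions(sv$abundance, "site")
head(ps[, 1:5], 3)
#>   scope unit    alpha     beta gamma
#> 1  site  S01 3.178571 11.82143    15
#> 2  site  S02 2.375000  5.62500     8
#> 3  site  S03 2.947368 12.05263    15

betaContrastTest(ps, sv$design)[c("statistic", "df", "p.value")]
#> $statistic
#> [1] 0.05424021
#> $df
#> [1] 1 8
#> $p.value
#> [1] 0.8216908

anovaTable(fitAbundanceModel(sv$abundance, "abundance"))
#>       term df_num df_den         F          p significant
#> 1   flower      1    147 90.903251 0.00000000        TRUE
#> 2  habitat      6    132  0.623702 0.71105103       FALSE
#> 3 corridor      1      8  4.804787 0.05973607       FALSE

head(strengthReport(sv$visits, sv$design)$tables$all_habitats[, 1:3], 5)
#>                plant strength rank
#> 1    Centaurea jacea 2.545502    1
#> 2   Calluna vulgaris 2.155883    2
#> 3 Trifolium pratense 2.140719    3
#> 4    Cirsium arvense 1.937567    4
#> 5 Centaurea scabiosa 1.167433    5

estimatePower(sv$design, gaussianTruth(mu0 = 10, sdSite = 1, sdTransect = 1,
                                       sigma = 2),
              term = "corridor", effectPct = 20, nSims = 100L, seed = 2024L)
#> PowerResult: term 'corridor', +20% effect: power 0.760 (95% CI 0.668-0.833),
#> 100 sims, 0 non-converged, alpha 0.05
```

Reading the output: in this synthetic realization flower density is by far
the strongest predictor of abundance (F = 90.9 on 1 and 147 df), habitat
and corridor status explain little once flower density is accounted for,
and site-level beta diversity does not differ between corridor and
non-corridor sites (F₁,₈ = 0.05, p = 0.82) — the generator's default truth
has no corridor effect, and the analysis correctly reports none. The
strength table identifies the plants carrying the pollinator community;
the 20 per-plant strengths sum exactly to the number of bee species
observed visiting identified plants.

`runPipeline(pipelineConfig(...))` chains every stage and writes one CSV or
JSON artefact per stage plus a manifest with the seed, settings and file
checksums; `costReference()` returns the collated per-hectare annual
management costs of the habitat types (no computation — a packaged
reference table).

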