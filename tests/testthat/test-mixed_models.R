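test_that("with zero random-effect variance the mixed fit equals OLS", {
  bd <- balancedDesign()
  for (s in c(99L, 7L, 23L)) {
    dat <- simulateResponse(bd, mu0 = 5, betaFlower = 0.3,
                            corridorEffect = 1, sdSite = 0, sdTransect = 0,
                            sigma = 1, seed = s)
    fmix <- fitLmm(dat)
    fols <- fitLmm(dat, engine = "lm")
    expect_true(fmix@converged)
    expect_lt(max(abs(fixedEffects(fmix)$estimate -
                        fixedEffects(fols)$estimate)), 1e-6)
  }
})

test_that("a balanced one-way design reproduces the classical ANOVA F", {
  # habitat as the only term, ordinary least squares: the sequential F must
  # equal the explicit sum-of-squares one-way F
  bd <- balancedDesign()
  dat <- simulateResponse(bd, mu0 = 5,
                          habitatEffects = c(
                            cereal_crop_edge = 0, forest = -1,
                            forest_grassland_boundary = 0,
                            maintained_ditch = 0.5,
                            maintained_roadside = 1,
                            seminatural_grassland = 1),
                          sdSite = 0, sdTransect = 0, sigma = 1, seed = 3)
  f <- fitLmm(dat, includeFlower = FALSE, includeCorridor = FALSE,
              engine = "lm")
  at <- anovaTable(f)
  oracle <- oneWayF(dat$y, dat$habitat)
  expect_equal(at$F[at$term == "habitat"], oracle$F, tolerance = 1e-10)
  expect_identical(c(at$df_num[1], at$df_den[1]),
                   c(oracle$df[1], oracle$df[2]))
})

test_that("denominator df follow the grouping-level rule", {
  # survey frame: 10 sites, 158 transects, 316 observations
  d <- readSurveyDesign(fixtureDesignPath())
  dat <- simulateResponse(d, mu0 = 10, betaFlower = 0.3, sdSite = 1,
                          sdTransect = 1, sigma = 2, seed = 61)
  at <- anovaTable(fitLmm(dat))
  nSites <- 10L
  nTrans <- 158L
  nObs <- 316L
  # corridor: site-level term -> n_sites - 1 - 1
  expect_identical(at$df_den[at$term == "corridor"], nSites - 2L)
  expect_identical(at$df_num[at$term == "corridor"], 1L)
  # habitat: 7 levels varying between transects within sites
  expect_identical(at$df_num[at$term == "habitat"], 6L)
  expect_identical(at$df_den[at$term == "habitat"], nTrans - nSites - 6L)
  # flower varies between rounds within transects
  expect_identical(at$df_den[at$term == "flower"], nObs - nTrans - 1L)
  # terms enter in the printed order
  expect_identical(at$term, c("flower", "habitat", "corridor"))

  # closed-form split-plot rule on a balanced design
  bd <- balancedDesign(8L)
  datb <- simulateResponse(bd, mu0 = 5, sdSite = 1, sdTransect = 0,
                           sigma = 1, seed = 62)
  atb <- anovaTable(fitLmm(datb))
  expect_identical(atb$df_den[atb$term == "corridor"], 8L - 2L)
  expect_identical(atb$df_num[atb$term == "habitat"], 5L)
  # one observation per transect: habitat and flower tested within sites
  expect_identical(atb$df_den[atb$term == "habitat"], 48L - 8L - 6L)
})

test_that("estimates are invariant to row order and site relabeling", {
  d <- readSurveyDesign(fixtureDesignPath())
  dat <- simulateResponse(d, mu0 = 10, betaFlower = 0.4, sdSite = 0.5,
                          sdTransect = 0.5, sigma = 1.5, seed = 71)
  f1 <- fitLmm(dat)
  set.seed(2)
  f2 <- fitLmm(dat[sample(nrow(dat)), ])
  expect_equal(fixedEffects(f1)$estimate, fixedEffects(f2)$estimate,
               tolerance = 1e-8)
  relab <- dat
  relab$site <- factor(paste0("site_", as.integer(relab$site) * 13))
  f3 <- fitLmm(relab)
  expect_equal(fixedEffects(f1)$estimate, fixedEffects(f3)$estimate,
               tolerance = 1e-8)
  expect_equal(anovaTable(f1)$F, anovaTable(f3)$F, tolerance = 1e-8)
})

test_that("per-habitat variance weights reduce to the homoscedastic fit", {
  # a single variance stratum is exactly the constant-variance model
  d <- readSurveyDesign(fixtureDesignPath())
  dat <- simulateResponse(d, mu0 = 10, betaFlower = 0.4, sdSite = 0.5,
                          sdTransect = 0.5, sigma = 1.5, seed = 73)
  one <- dat[dat$habitat == "cereal_crop_edge", ]
  fh <- fitLmm(one, includeCorridor = FALSE, varStruct = "habitat")
  fc <- fitLmm(one, includeCorridor = FALSE, varStruct = "homoscedastic")
  expect_equal(fixedEffects(fh)$estimate, fixedEffects(fc)$estimate,
               tolerance = 1e-6)
  # the weighted fit runs and reports per-stratum components
  fw <- fitLmm(dat, varStruct = "habitat")
  expect_true(fw@converged)
  expect_identical(fw@varStruct, "habitat")
})

test_that("degenerate inputs are flagged or rejected, never silent", {
  d <- tinyDesign()
  # constant response -> flagged degenerate fit
  v <- data.frame(transect_id = "t9", round = 1L, bee_species = "x",
                  plant_species = "p")
  mf <- modelFrame(buildAbundance(data.frame(
    transect_id = character(0), round = integer(0),
    bee_species = character(0), plant_species = character(0)), d),
    "abundance")
  fit <- fitLmm(mf, includeCorridor = FALSE)
  expect_false(fit@converged)
  expect_match(fit@message, "constant")
  expect_error(anovaTable(fit), "converge")
  # single site type with a corridor term -> error
  mfA <- mf[mf$site == "A", ]
  mfA$y <- rnorm(nrow(mfA))
  expect_error(fitLmm(mfA), "both site types")
})

test_that("model frames expose the four response definitions", {
  sv <- simulateSurvey(simConfig(seed = 79, nSites = 6L))
  cts <- beeCounts(sv$abundance)
  g <- speciesGroups()
  mfA <- modelFrame(sv$abundance, "abundance")
  expect_equal(mfA$y, unname(colSums(cts)))
  mfR <- modelFrame(sv$abundance, "richness")
  expect_equal(mfR$y, unname(colSums(cts > 0)))
  mfP <- modelFrame(sv$abundance, "provider_abundance", groups = g)
  expect_equal(mfP$y, unname(colSums(
    cts[rownames(cts) %in% providerSpecies(g), ])))
  mfT <- modelFrame(sv$abundance, "threatened_abundance", groups = g)
  expect_equal(mfT$y, unname(colSums(
    cts[rownames(cts) %in% threatenedSpecies(g), ])))
  mfL <- modelFrame(sv$abundance, "abundance", logTransform = TRUE)
  expect_equal(mfL$y, log1p(mfA$y))
  mfM <- modelFrame(sv$abundance, "abundance", flowerEncoding = "midpoint")
  expect_equal(mfM$flower,
               flowerScores(observationData(sv$abundance)$flower_class,
                            "midpoint"))
})

test_that("an unrecorded species group yields a flagged fit, not a crash", {
  d <- tinyDesign()
  v <- data.frame(transect_id = c("t1", "t2"), round = 1L,
                  bee_species = "Bombus jonellus", # neither group
                  plant_species = "p")
  gm <- groupModels(buildAbundance(v, d))
  expect_false(gm$threatened@converged)
  expect_match(gm$threatened@message, "constant")
})

test_that("a habitat-restricted group is detected against shuffled refits", {
  # threatened species present in three habitats only; their habitat F
  # should beat the F from a transect-level habitat shuffle nearly always
  d <- readSurveyDesign(fixtureDesignPath())
  tr <- transects(d)
  st <- sites(d)
  goodHabs <- c("seminatural_grassland", "maintained_roadside",
                "transmission_corridor")
  nWin <- 0L
  nSim <- 200L
  set.seed(83)
  for (i in seq_len(nSim)) {
    lam <- ifelse(tr$habitat %in% goodHabs, 1.2, 0)
    cts <- rbind(
      "Bombus muscorum" = rpois(nrow(tr), lam),
      "Bombus sylvarum" = rpois(nrow(tr), lam / 2),
      "Bombus terrestris" = rpois(nrow(tr), 2))
    obs <- data.frame(
      transect_id = tr$transect_id, round = tr$round, site_id = tr$site_id,
      habitat = tr$habitat,
      has_corridor = st$has_corridor[match(tr$site_id, st$site_id)],
      flower_class = tr$flower_class)
    ab <- beeAbundance(cts, obs)
    fit <- fitAbundanceModel(ab, "threatened_abundance")
    # shuffle habitat labels at the transect level and refit
    tmap <- unique(tr[, c("transect_id", "habitat")])
    shuf <- setNames(sample(tmap$habitat), tmap$transect_id)
    obs2 <- obs
    obs2$habitat <- unname(shuf[obs$transect_id])
    fit2 <- fitAbundanceModel(beeAbundance(cts, obs2),
                              "threatened_abundance")
    if (!fit@converged || !fit2@converged) next
    fH <- anovaTable(fit)
    fS <- anovaTable(fit2)
    if (fH$F[fH$term == "habitat"] > fS$F[fS$term == "habitat"])
      nWin <- nWin + 1L
  }
  expect_gte(nWin / nSim, 0.95)
})

test_that("the flower effect is routinely detected at the default effect size", {
  nSig <- 0L
  nSim <- 60L
  for (i in seq_len(nSim)) {
    cfg <- simConfig(seed = 9000L + i)
    sv <- simulateCounts(simulateDesign(cfg), cfg)
    fit <- fitAbundanceModel(sv$abundance, "provider_abundance")
    if (!fit@converged) next
    at <- anovaTable(fit)
    if (at$p[at$term == "flower"] < 0.05) nSig <- nSig + 1L
  }
  expect_gte(nSig / nSim, 0.8)
})
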