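test_that("alpha diversity is the mean per-observation richness", {
  obs <- data.frame(transect_id = c("t1", "t2"), round = 1L,
                    site_id = "A", habitat = "forest", has_corridor = FALSE,
                    flower_class = 3L)
  cts <- matrix(c(1L, 2L, 0L, 0L, 0L, 5L), nrow = 3,
                dimnames = list(c("A", "B", "C"), NULL))
  ab <- beeAbundance(cts, obs)
  expect_equal(alphaDiversity(ab), 1.5) # {A,B} and {C}

  zero <- beeAbundance(matrix(0L, 2, 2,
                              dimnames = list(c("A", "B"), NULL)),
                       obs)
  expect_equal(alphaDiversity(zero), 0)
  expect_error(alphaDiversity(ab, subset = logical(2)), "no observations")
})

test_that("alpha diversity equals the brute-force per-row mean", {
  set.seed(101)
  cts <- matrix(rpois(20 * 8, 0.7), nrow = 8,
                dimnames = list(paste0("sp", 1:8), NULL))
  obs <- data.frame(transect_id = paste0("t", 1:20), round = 1L,
                    site_id = "A", habitat = "forest", has_corridor = FALSE,
                    flower_class = 1L)
  ab <- beeAbundance(cts, obs)
  brute <- mean(vapply(seq_len(20), function(j) sum(cts[, j] > 0),
                       numeric(1)))
  expect_equal(alphaDiversity(ab), brute)
})

test_that("rarefied richness honours its analytic identities", {
  counts <- c(12, 5, 3, 1)
  n <- sum(counts)
  expect_equal(as.numeric(rarefiedRichness(counts, n)), 4) # m = N -> S_obs
  expect_equal(as.numeric(rarefiedRichness(counts, 1)), 1) # m = 1 -> 1
  shallow <- rarefiedRichness(counts, n + 10)
  expect_equal(as.numeric(shallow), 4)
  expect_true(attr(shallow, "shallow"))
  expect_error(rarefiedRichness(counts, 0), "positive integer")
  expect_error(rarefiedRichness(counts, -3), "positive integer")
  expect_error(rarefiedRichness(c(0, 0), 1), "empty")
})

test_that("rarefied richness equals full enumeration of subsamples", {
  # all C(10, 4) = 210 subsamples of the (5,3,2) community, enumerated
  counts <- c(5, 3, 2)
  labels <- rep.int(1:3, counts)
  combos <- utils::combn(10, 4)
  exact <- mean(apply(combos, 2, function(ix) length(unique(labels[ix]))))
  expect_equal(as.numeric(rarefiedRichness(counts, 4)), exact,
               tolerance = 1e-12)
})

test_that("rarefied richness matches a seeded Monte-Carlo subsampler", {
  set.seed(202)
  counts <- c(5, 3, 2)
  mc <- mcRarefy(counts, 4, 2e4)
  expect_lt(abs(as.numeric(rarefiedRichness(counts, 4)) - mc$mean),
            3 * mc$se)
})

test_that("rarefied richness agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(303)
  for (i in 1:10) {
    counts <- rpois(sample(3:15, 1), sample(2:20, 1)) + 1
    m <- sample(seq_len(sum(counts)), 1)
    expect_equal(as.numeric(rarefiedRichness(counts, m)),
                 unname(c(suppressWarnings(vegan::rarefy(counts, m)))),
                 tolerance = 1e-8)
  }
})

test_that("rarefaction curves are monotone, concave and pinned at both ends", {
  set.seed(404)
  for (i in 1:10) {
    counts <- rpois(sample(3:12, 1), sample(1:15, 1)) + 1
    cv <- rarefactionCurve(counts)
    expect_equal(cv$expected[1], 1)
    expect_equal(cv$expected[nrow(cv)], length(counts))
    expect_true(all(diff(cv$expected) >= -1e-12))
    if (nrow(cv) > 2)
      expect_true(all(diff(diff(cv$expected)) <= 1e-12))
  }
})

test_that("site partitions are additive with gamma as the species union", {
  d <- tinyDesign()
  # one observation only: alpha = gamma, beta = 0
  v1 <- data.frame(transect_id = "t3", round = 1L,
                   bee_species = c("Bombus terrestris", "Bombus pratorum"),
                   plant_species = "p")
  p1 <- partitionSite(buildAbundance(v1, d, aggregateRounds = TRUE), "B")
  expect_equal(p1$beta, 0)
  expect_equal(p1$alpha, p1$gamma)

  # disjoint species pairs on two observations: alpha 2, gamma 4, beta 2
  v2 <- data.frame(
    transect_id = c("t1", "t1", "t2", "t2"), round = 1L,
    bee_species = c("a", "b", "c", "d"), plant_species = "p")
  p2 <- partitionSite(buildAbundance(v2, d, aggregateRounds = TRUE), "A")
  expect_equal(p2$alpha, 2)
  expect_equal(p2$gamma, 4)
  expect_equal(p2$beta, 2)
  expect_error(partitionSite(buildAbundance(v2, d), "nowhere"), "nowhere")

  # simulated site: gamma equals the brute-force union of species sets
  sv <- simulateSurvey(simConfig(seed = 31, nSites = 6L))
  ps <- partitionSite(sv$abundance, "S03")
  od <- observationData(sv$abundance)
  cts <- beeCounts(sv$abundance)[, od$site_id == "S03", drop = FALSE]
  union <- unique(unlist(apply(cts, 2, function(col)
    rownames(cts)[col > 0], simplify = FALSE)))
  expect_equal(ps$gamma, length(union))
})

test_that("habitat partitions rarefy gamma and flag shallow pools", {
  d <- tinyDesign()
  v <- data.frame(transect_id = "t3", round = 1L,
                  bee_species = "Bombus pratorum", plant_species = "p")
  ab <- buildAbundance(v, d)
  ph <- partitionHabitat(ab, "forest", m = 90L)
  expect_true(ph$shallow)
  expect_equal(ph$gamma, 1)
  expect_lt(abs(ph$beta - (1 - 0.5)), 1e-12) # alpha over 2 forest obs

  sv <- simulateSurvey(simConfig(seed = 37, nSites = 8L))
  for (h in unique(observationData(sv$abundance)$habitat)) {
    od <- observationData(sv$abundance)
    pooled <- rowSums(beeCounts(sv$abundance)[, od$habitat == h,
                                              drop = FALSE])
    if (sum(pooled) == 0) next
    ph <- suppressWarnings(partitionHabitat(sv$abundance, h, m = 50L))
    # rarefied gamma never exceeds the pooled observed richness
    expect_lte(ph$gamma, sum(pooled > 0) + 1e-12)
    # partition equals an independent recomputation from the rarefier
    expect_equal(ph$alpha + ph$beta, ph$gamma, tolerance = 1e-15)
    expect_equal(ph$gamma, as.numeric(rarefiedRichness(pooled, 50L)))
  }
})

test_that("rarefied beta below zero is reported with a warning, not clipped", {
  d <- tinyDesign()
  v <- data.frame(
    transect_id = rep(c("t1", "t2"), each = 10),
    round = 1L,
    bee_species = rep(c("a", "b", "a", "b"), each = 5),
    plant_species = "p", stringsAsFactors = FALSE)
  ab <- buildAbundance(v, d, aggregateRounds = TRUE)
  # the corridor transect holds {a, b} evenly, so alpha = 2; at m = 2 the
  # expected richness is below 2, hence beta < 0
  expect_warning(ph <- partitionHabitat(ab, "transmission_corridor", m = 2L),
                 "negative")
  expect_lt(ph$beta, 0)
  expect_equal(ph$alpha + ph$beta, ph$gamma)
})

test_that("partitions are invariant to observation order", {
  sv <- simulateSurvey(simConfig(seed = 41, nSites = 6L))
  ab <- sv$abundance
  set.seed(1)
  perm <- sample(ncol(ab))
  ps1 <- diversityPartitions(ab, "site")
  ps2 <- diversityPartitions(ab[, perm], "site")
  expect_equal(ps1, ps2)
  ph1 <- suppressWarnings(diversityPartitions(ab, "habitat"))
  ph2 <- suppressWarnings(diversityPartitions(ab[, perm], "habitat"))
  expect_equal(ph1, ph2)
})

test_that("every partition of seeded surveys is additive to machine precision", {
  for (s in 1:10) {
    sv <- simulateSurvey(simConfig(seed = 600 + s, nSites = 5L,
                                   meanTransects = 1.5))
    ps <- diversityPartitions(sv$abundance, "site")
    ph <- suppressWarnings(diversityPartitions(sv$abundance, "habitat"))
    both <- rbind(ps, ph)
    expect_true(all(both$gamma - both$alpha == both$beta))
    expect_true(all(abs(both$alpha + both$beta - both$gamma) <=
                      2 * .Machine$double.eps * pmax(1, both$gamma)))
  }
})

test_that("the beta contrast is a textbook one-way ANOVA over sites", {
  d <- readSurveyDesign(fixtureDesignPath())
  sv <- simulateCounts(d, simConfig(seed = 47))
  ps <- diversityPartitions(sv$abundance, "site")
  ct <- betaContrastTest(ps, d)
  expect_identical(ct$df, c(1L, 8L)) # 10 sites -> F(1, 8)
  expect_identical(ct$n, 10L)
  corr <- sites(d)$has_corridor[match(ps$unit, sites(d)$site_id)]
  oracle <- oneWayF(ps$beta, corr)
  expect_equal(ct$statistic, oracle$F, tolerance = 1e-12)
  expect_equal(ct$p.value,
               pf(oracle$F, 1, 8, lower.tail = FALSE), tolerance = 1e-12)

  # identical betas in every site: degenerate, F = 0 and p = 1
  flat <- ps
  flat$beta <- 5
  ctFlat <- betaContrastTest(flat, d)
  expect_equal(ctFlat$statistic, 0)
  expect_equal(ctFlat$p.value, 1)

  # fewer than two sites per group is an error
  expect_error(betaContrastTest(ps[c(1, 6, 7, 8, 9, 10), ], d),
               "at least 2 sites")
})
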