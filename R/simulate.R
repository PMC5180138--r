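## Seeded generator of synthetic transect surveys with known ground truth.
## Counts follow a log-link model: log E[count] = log(baseMean) +
## betaFlower*(flower-1) + habitat offset + corridor offset + site RE +
## transect RE, drawn negative-binomial (variance = mu + mu^2/k) and split
## across species by a log-series abundance distribution. Host plants are
## allocated per individual with probability proportional to per-habitat
## plant availability times bee-plant preference.

.DEFAULT_BEES <- c(
  "Bombus pascuorum", "Bombus terrestris", "Bombus lapidarius",
  "Bombus pratorum", "Bombus hypnorum", "Bombus hortorum",
  "Bombus jonellus", "Bombus ruderarius", "Bombus soroeensis",
  "Bombus sylvestris", "Bombus campestris", "Bombus sylvarum",
  "Bombus bohemicus", "Bombus humilis", "Bombus norvegicus",
  "Bombus rupestris", "Bombus muscorum", "Bombus vestalis",
  "Bombus subterraneus", "Bombus distinguendus")

.DEFAULT_PLANTS <- c(
  "Centaurea jacea", "Trifolium pratense", "Carduus crispus",
  "Cirsium arvense", "Calluna vulgaris", "Lythrum salicaria",
  "Trifolium hybridum", "Clinopodium vulgare", "Centaurea scabiosa",
  "Succisa pratensis", "Trifolium repens", "Lathyrus pratensis",
  "Leontodon autumnalis", "Campanula rapunculoides", "Filipendula ulmaria",
  "Melampyrum pratense", "Centaurea cyanus", "Cirsium helenioides",
  "Arctium tomentosum", "Malva moschata", "Campanula rotundifolia",
  "Crepis tectorum", "Prunella vulgaris", "Epilobium adenocaulon",
  "Vicia cracca", "Lamium maculatum", "Trifolium medium",
  "Galeopsis tetrahit", "Solidago virgaurea", "Hypericum maculatum")

## flower-class distribution peaked at `center` (1..7)
.flowerProbs <- function(center) stats::dbinom(0:6, 6, (center - 1) / 6)

.defaultFlowerProbs <- function(habitats) {
  centers <- c(transmission_corridor = 4, maintained_roadside = 5,
               forest = 2, forest_grassland_boundary = 4,
               seminatural_grassland = 5, cereal_crop_edge = 3,
               maintained_ditch = 4)
  m <- t(vapply(habitats, function(h)
    .flowerProbs(if (h %in% names(centers)) centers[[h]] else 4),
    numeric(7)))
  rownames(m) <- habitats
  m
}

## deterministic long-tailed availability pattern: plant p present in
## habitat h on a staggered grid, weight decaying with plant rank
.defaultPlantPool <- function(plants, habitats) {
  np <- length(plants); nh <- length(habitats)
  m <- matrix(0, np, nh, dimnames = list(plants, habitats))
  for (p in seq_len(np))
    for (h in seq_len(nh))
      if ((p + 3L * h) %% 10L < 6L) m[p, h] <- 0.9^p
  m
}

#' Log-series relative abundances
#'
#' Relative abundance of the i-th most common species proportional to
#' `x^i / i` (Fisher log-series shape): a couple of dominant species and a
#' long tail of rare ones, the typical shape of bumblebee communities.
#'
#' @param s number of species.
#' @param x shape parameter in (0, 1); larger x flattens the tail.
#' @return numeric vector of length `s` summing to 1, decreasing.
#' @export
sadLogseries <- function(s, x = 0.85) {
  stopifnot(s >= 1, x > 0, x < 1)
  p <- x^seq_len(s) / seq_len(s)
  p / sum(p)
}

#' Build a synthetic-survey configuration
#'
#' Defaults emulate a two-round survey of 10 four-square-km sites (half
#' bisected by a transmission corridor) over the seven habitat types, with a
#' mean of 2.25 transects per site-habitat cell, a 20-species bumblebee pool
#' with log-series abundances totalling roughly a thousand individuals, a
#' flower-density effect as the dominant predictor, and no corridor or
#' residual habitat effect. See \linkS4class{SimConfig} for every knob.
#'
#' @param seed integer seed (mandatory; all realizations derive from it).
#' @param nSites,fracCorridor,habitats,meanTransects,nRounds sampling frame.
#' @param beeSpecies,sadX,relAbundance bumblebee community.
#' @param baseMean,betaFlower,habitatEffects,corridorEffect fixed effects
#'   (log scale).
#' @param sdSite,sdTransect,dispersion,family random effects and count family.
#' @param flowerClassProbs per-habitat distribution over flower classes.
#' @param plantSpecies,plantPool,preference,propUnidentified plant-visit
#'   model.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed,
    nSites = 10L, fracCorridor = 0.5, habitats = habitatLevels(),
    meanTransects = 2.25, nRounds = 2L,
    beeSpecies = .DEFAULT_BEES, sadX = 0.85, relAbundance = numeric(0),
    baseMean = 1.6, betaFlower = 0.25,
    habitatEffects = setNames(rep(0, length(habitats)), habitats),
    corridorEffect = 0, sdSite = 0.3, sdTransect = 0.3,
    dispersion = 2, family = c("nbinom", "poisson", "gaussian"),
    flowerClassProbs = .defaultFlowerProbs(habitats),
    plantSpecies = .DEFAULT_PLANTS,
    plantPool = .defaultPlantPool(plantSpecies, habitats),
    preference = matrix(1, length(beeSpecies), length(plantSpecies),
                        dimnames = list(beeSpecies, plantSpecies)),
    propUnidentified = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  family <- match.arg(family)
  if (length(relAbundance) &&
      abs(sum(relAbundance) - 1) > 1e-8)
    stop("relAbundance must sum to 1")
  new("SimConfig", nSites = as.integer(nSites), fracCorridor = fracCorridor,
      habitats = habitats, meanTransects = meanTransects,
      nRounds = as.integer(nRounds), beeSpecies = beeSpecies, sadX = sadX,
      relAbundance = relAbundance, baseMean = baseMean,
      betaFlower = betaFlower,
      habitatEffects = habitatEffects, corridorEffect = corridorEffect,
      sdSite = sdSite, sdTransect = sdTransect, dispersion = dispersion,
      family = family, flowerClassProbs = flowerClassProbs,
      plantSpecies = plantSpecies, plantPool = plantPool,
      preference = preference, propUnidentified = propUnidentified,
      seed = as.integer(seed))
}

.relAbund <- function(config) {
  if (length(config@relAbundance)) {
    setNames(config@relAbundance, config@beeSpecies)
  } else {
    setNames(sadLogseries(length(config@beeSpecies), config@sadX),
             config@beeSpecies)
  }
}

#' Simulate a survey design
#'
#' Draws the number of transects per site-habitat cell from a Poisson with
#' the configured mean (so some sites lack some habitats, as in real
#' surveys); transmission-corridor transects exist only at corridor-bisected
#' sites. Each transect is surveyed in every round with its flower class
#' drawn from the habitat-specific class distribution per round.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a validated \linkS4class{SurveyDesign}; deterministic given the
#'   config seed.
#' @export
simulateDesign <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nC <- round(config@nSites * config@fracCorridor)
  siteIds <- sprintf("S%02d", seq_len(config@nSites))
  hasCorr <- seq_len(config@nSites) <= nC
  rows <- list()
  tcount <- 0L
  for (i in seq_len(config@nSites)) {
    for (h in config@habitats) {
      if (h == "transmission_corridor" && !hasCorr[i]) next
      n <- rpois(1L, config@meanTransects)
      if (n == 0L) next
      for (k in seq_len(n)) {
        tcount <- tcount + 1L
        tid <- sprintf("T%03d", tcount)
        fc <- sample.int(7L, config@nRounds, replace = TRUE,
                         prob = config@flowerClassProbs[h, ])
        rows[[length(rows) + 1L]] <- data.frame(
          transect_id = tid, site_id = siteIds[i], habitat = h,
          round = seq_len(config@nRounds), flower_class = fc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no transects")
  tr <- do.call(rbind, rows)
  surveyDesign(tr, sites = data.frame(site_id = siteIds,
                                      has_corridor = hasCorr,
                                      stringsAsFactors = FALSE))
}

## observation-level linear predictor and random-effect draws; shared by
## the count and the Gaussian generators
.drawEffects <- function(design, config) {
  tr <- transects(design)
  st <- sites(design)
  siteIds <- st$site_id
  tids <- unique(tr$transect_id)
  bSite <- setNames(rnorm(length(siteIds), 0, config@sdSite), siteIds)
  bTrans <- setNames(rnorm(length(tids), 0, config@sdTransect), tids)
  corr <- st$has_corridor[match(tr$site_id, st$site_id)]
  eta <- log(config@baseMean) +
    config@betaFlower * (tr$flower_class - 1) +
    config@habitatEffects[tr$habitat] +
    config@corridorEffect * corr +
    bSite[tr$site_id] + bTrans[tr$transect_id]
  list(eta = unname(eta), bSite = bSite, bTransect = bTrans)
}

#' Simulate bumblebee counts over a design
#'
#' Draws a per-observation expected total from the log-link model, splits it
#' across the species pool by the community's relative abundances and draws
#' independent negative-binomial (or Poisson) counts per species. All latent
#' draws are returned as ground truth for parameter-recovery experiments.
#'
#' @param design a \linkS4class{SurveyDesign} (e.g. from
#'   [simulateDesign()]).
#' @param config a \linkS4class{SimConfig}.
#' @return list with `abundance` (a \linkS4class{BeeAbundance}) and `truth`
#'   (relative abundances, random-effect draws, per-observation expected
#'   means, and the config echo).
#' @export
simulateCounts <- function(design, config) {
  if (nrow(transects(design)) == 0L) stop("design is empty")
  set.seed(config@seed + 1L)
  eff <- .drawEffects(design, config)
  mu <- exp(eff$eta)
  p <- .relAbund(config)
  tr <- transects(design)
  nObs <- nrow(tr)
  cts <- matrix(0L, length(p), nObs,
                dimnames = list(names(p),
                                paste(tr$transect_id, tr$round, sep = ":")))
  for (s in seq_along(p)) {
    ms <- mu * p[s]
    cts[s, ] <- if (config@family == "poisson" || !is.finite(config@dispersion))
      rpois(nObs, ms)
    else
      rnbinom(nObs, mu = ms, size = config@dispersion)
  }
  st <- sites(design)
  cd <- DataFrame(
    transect_id = tr$transect_id, round = tr$round, site_id = tr$site_id,
    habitat = tr$habitat,
    has_corridor = st$has_corridor[match(tr$site_id, st$site_id)],
    flower_class = tr$flower_class,
    row.names = colnames(cts))
  ab <- new("BeeAbundance",
            SummarizedExperiment(assays = list(counts = cts), colData = cd))
  truth <- list(relAbundance = p, bSite = eff$bSite,
                bTransect = eff$bTransect, mu = mu,
                family = config@family, dispersion = config@dispersion,
                config = config)
  list(abundance = ab, truth = truth)
}

#' Simulate host-plant visits for every recorded individual
#'
#' Each individual in the count matrix is assigned a host plant with
#' probability proportional to the plant's availability in the observation's
#' habitat times the bee species' preference for it; a configured fraction
#' of records gets an unidentified host.
#'
#' @param abund a \linkS4class{BeeAbundance} from [simulateCounts()].
#' @param config the \linkS4class{SimConfig} used to generate it.
#' @return data.frame of visit records (`transect_id`, `round`,
#'   `bee_species`, `plant_species`).
#' @export
simulateVisits <- function(abund, config) {
  set.seed(config@seed + 2L)
  cts <- beeCounts(abund)
  od <- observationData(abund)
  idx <- which(cts > 0, arr.ind = TRUE)
  out <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    s <- rownames(cts)[idx[r, 1L]]
    o <- idx[r, 2L]
    n <- cts[idx[r, 1L], o]
    h <- od$habitat[o]
    w <- config@plantPool[, h] * config@preference[s, ]
    if (all(w == 0))
      stop("habitat '", h, "' has an empty plant pool")
    plants <- sample(config@plantSpecies, n, replace = TRUE, prob = w)
    unid <- runif(n) < config@propUnidentified
    plants[unid] <- .UNIDENTIFIED
    out[[r]] <- data.frame(
      transect_id = od$transect_id[o], round = od$round[o],
      bee_species = s, plant_species = plants, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(transect_id = character(0), round = integer(0),
                      bee_species = character(0),
                      plant_species = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-call synthetic survey
#'
#' Runs [simulateDesign()], [simulateCounts()] and [simulateVisits()] in
#' sequence.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with `design`, `abundance`, `visits`, `truth`.
#' @export
simulateSurvey <- function(config) {
  design <- simulateDesign(config)
  sc <- simulateCounts(design, config)
  visits <- simulateVisits(sc$abundance, config)
  list(design = design, abundance = sc$abundance, visits = visits,
       truth = sc$truth)
}

#' Simulate a Gaussian per-observation response
#'
#' The Gaussian counterpart of the count generator, used for exact-recovery
#' and power experiments: the response is the linear predictor on the
#' response scale (intercept `mu0` plus flower, habitat and corridor
#' effects) plus site and transect random intercepts and residual noise.
#'
#' @param design a \linkS4class{SurveyDesign}.
#' @param mu0 intercept (expected response at flower class 1, reference
#'   habitat, no corridor).
#' @param betaFlower effect of one flower-class step.
#' @param habitatEffects named per-habitat offsets (0 when unnamed scalar).
#' @param corridorEffect offset for corridor-bisected sites.
#' @param sdSite,sdTransect,sigma site, transect and residual SDs.
#' @param seed integer seed.
#' @return data.frame with one row per observation: `y`, `flower`,
#'   `habitat`, `corridor`, `site`, `transect`.
#' @export
simulateResponse <- function(design, mu0 = 10, betaFlower = 0,
                             habitatEffects = 0, corridorEffect = 0,
                             sdSite = 1, sdTransect = 1, sigma = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  tr <- transects(design)
  st <- sites(design)
  if (length(habitatEffects) == 1L && is.null(names(habitatEffects)))
    habitatEffects <- setNames(rep(habitatEffects, length(unique(tr$habitat))),
                               sort(unique(tr$habitat)))
  siteIds <- st$site_id
  tids <- unique(tr$transect_id)
  bSite <- setNames(rnorm(length(siteIds), 0, sdSite), siteIds)
  bTrans <- setNames(rnorm(length(tids), 0, sdTransect), tids)
  corr <- st$has_corridor[match(tr$site_id, st$site_id)]
  mu <- mu0 + betaFlower * (tr$flower_class - 1) +
    unname(habitatEffects[tr$habitat]) + corridorEffect * corr +
    unname(bSite[tr$site_id]) + unname(bTrans[tr$transect_id])
  data.frame(
    y = mu + rnorm(nrow(tr), 0, sigma),
    flower = tr$flower_class,
    habitat = factor(tr$habitat),
    corridor = factor(ifelse(corr, "corridor", "no_corridor"),
                      levels = c("no_corridor", "corridor")),
    site = factor(tr$site_id),
    transect = factor(tr$transect_id),
    stringsAsFactors = FALSE)
}
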