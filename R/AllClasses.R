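#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom stats anova as.formula coef dbinom lm p.adjust pf qnorm
#'   rnbinom rnorm rpois runif sd setNames vcov qt
#' @importFrom utils read.csv write.csv packageVersion
NULL

## closed habitat vocabulary of the survey design
.HABITATS <- c("transmission_corridor", "maintained_roadside", "forest",
               "forest_grassland_boundary", "seminatural_grassland",
               "cereal_crop_edge", "maintained_ditch")

.UNIDENTIFIED <- "UNIDENTIFIED"

#' Habitat vocabulary
#'
#' The seven habitat labels recognised by the survey design: transmission
#' corridors, maintained roadsides, forest, forest/grassland boundaries,
#' semi-natural grasslands, cereal crop edges and maintained ditches.
#'
#' @return Character vector of the seven allowed habitat labels.
#' @export
#' @examples
#' habitatLevels()
habitatLevels <- function() .HABITATS

#' SurveyDesign: the sampling frame of a transect survey
#'
#' Holds the transect table (one row per transect-round survey event) and the
#' site table (one row per site, with its corridor status). All downstream
#' containers are validated against this frame.
#'
#' @slot transects data.frame with columns `transect_id`, `site_id`,
#'   `habitat`, `round`, `flower_class` and optionally `date`.
#' @slot sites data.frame with columns `site_id`, `has_corridor` and
#'   optionally `name`.
#' @export
setClass("SurveyDesign",
  representation(transects = "data.frame", sites = "data.frame"))

setValidity("SurveyDesign", function(object) {
  tr <- object@transects
  st <- object@sites
  msg <- character(0)
  need <- c("transect_id", "site_id", "habitat", "round", "flower_class")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    return(paste("transect table lacks columns:", paste(miss, collapse = ", ")))
  if (nrow(tr) == 0L)
    return("no transects")
  bad <- !tr$habitat %in% .HABITATS
  if (any(bad))
    msg <- c(msg, sprintf(
      "unknown habitat label(s) %s at row(s) %s; allowed labels: %s",
      paste(unique(tr$habitat[bad]), collapse = ", "),
      paste(utils::head(which(bad), 5L), collapse = ", "),
      paste(.HABITATS, collapse = ", ")))
  badf <- !(tr$flower_class %in% 1:7)
  if (any(badf))
    msg <- c(msg, sprintf("flower_class outside 1..7 at row(s) %s",
                          paste(utils::head(which(badf), 5L), collapse = ", ")))
  key <- paste(tr$transect_id, tr$round)
  if (anyDuplicated(key))
    msg <- c(msg, sprintf("duplicate (transect_id, round): %s",
                          paste(unique(key[duplicated(key)]), collapse = ", ")))
  if (!all(c("site_id", "has_corridor") %in% names(st)))
    msg <- c(msg, "site table lacks site_id/has_corridor")
  else {
    if (anyDuplicated(st$site_id))
      msg <- c(msg, "duplicate site_id in site table")
    if (any(is.na(st$has_corridor)))
      msg <- c(msg, "has_corridor must be defined for every site")
    orphan <- setdiff(tr$site_id, st$site_id)
    if (length(orphan))
      msg <- c(msg, sprintf("transects reference unknown site(s): %s",
                            paste(orphan, collapse = ", ")))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SpeciesGroups: conservation and service-provision species sets
#'
#' Partitions the bumblebee species pool into species of conservation concern
#' ("threatened") and the main crop-pollination species ("providers"), plus an
#' alias map applied during data loading (by default *Bombus lucorum* workers
#' are pooled with *B. terrestris*, the two being inseparable in the field).
#'
#' @slot threatened character vector of species labels.
#' @slot providers character vector of species labels.
#' @slot aliases named character vector mapping synonym to canonical label.
#' @export
setClass("SpeciesGroups",
  representation(threatened = "character", providers = "character",
                 aliases = "character"))

setValidity("SpeciesGroups", function(object) {
  ov <- intersect(object@threatened, object@providers)
  if (length(ov))
    return(paste("species in both groups:", paste(ov, collapse = ", ")))
  if (length(object@aliases) && is.null(names(object@aliases)))
    return("aliases must be a named character vector (synonym -> canonical)")
  TRUE
})

#' BeeAbundance: transect-round x species count container
#'
#' A \linkS4class{SummarizedExperiment} with bumblebee species as rows and
#' survey observations (transect-round, or transect when rounds are
#' aggregated) as columns. `colData` carries the per-observation design
#' metadata (site, habitat, corridor status, flower class); the single assay
#' `"counts"` holds non-negative integer counts of foraging individuals.
#'
#' @export
setClass("BeeAbundance", contains = "SummarizedExperiment")

setValidity("BeeAbundance", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' missing")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    return("counts must be non-negative integers")
  need <- c("transect_id", "site_id", "habitat", "has_corridor", "flower_class")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    return(paste("colData lacks:", paste(miss, collapse = ", ")))
  TRUE
})

#' VisitationMatrix: plant x pollinator visit counts
#'
#' Visit counts restricted to a habitat subset; rows are host-plant species,
#' columns bumblebee species. Visits with unidentified host plants are
#' excluded (their number is kept in `nUnidentified`); pollinator columns
#' with no identified visits in the subset are dropped.
#'
#' @slot visits integer matrix, plants x pollinators.
#' @slot subset character label of the habitat subset.
#' @slot habitats the habitat labels pooled into the subset.
#' @slot nUnidentified number of visit records dropped for unidentified hosts.
#' @export
setClass("VisitationMatrix",
  representation(visits = "matrix", subset = "character",
                 habitats = "character", nUnidentified = "integer"))

setValidity("VisitationMatrix", function(object) {
  v <- object@visits
  if (length(v) && (any(v < 0) || any(v != round(v))))
    return("visit counts must be non-negative integers")
  if (length(v) && any(colSums(v) == 0))
    return("all-zero pollinator columns must be dropped")
  if (.UNIDENTIFIED %in% rownames(v))
    return("UNIDENTIFIED plants must be excluded")
  TRUE
})

#' SimConfig: parameters of the synthetic survey generator
#'
#' Fully specifies a synthetic transect survey: the sampling frame (sites,
#' habitats, transect intensity, rounds), the bumblebee community (species
#' pool and log-series abundance distribution), the count model on the log
#' scale (flower, habitat and corridor effects; site and transect random
#' effects; negative-binomial overdispersion), and the plant-visit model
#' (per-habitat plant availability, bee-plant preference, unidentified-host
#' rate). A seed is mandatory: all realizations are reproducible from
#' (config, seed).
#'
#' @slot nSites integer, number of sites.
#' @slot fracCorridor fraction of sites bisected by a transmission corridor.
#' @slot habitats habitat labels surveyed.
#' @slot meanTransects mean transects per site-habitat cell (Poisson).
#' @slot nRounds survey rounds per transect.
#' @slot beeSpecies species pool, most to least abundant.
#' @slot sadX log-series shape parameter in (0,1); relative abundance of the
#'   i-th species is proportional to `sadX^i / i`.
#' @slot relAbundance optional explicit relative abundances (overrides sadX).
#' @slot baseMean expected individuals per observation at flower class 1 in
#'   the reference habitat, before random effects.
#' @slot betaFlower log-scale effect of one flower-class step.
#' @slot habitatEffects named log-scale habitat offsets.
#' @slot corridorEffect log-scale effect of a site being bisected.
#' @slot sdSite,sdTransect random-intercept standard deviations (log scale).
#' @slot dispersion negative-binomial size k (variance = mu + mu^2/k);
#'   `Inf` gives Poisson.
#' @slot family count family, "nbinom" or "poisson".
#' @slot flowerClassProbs 7-column matrix of per-habitat distributions over
#'   flower classes 1..7 (rows named by habitat).
#' @slot plantSpecies host-plant pool.
#' @slot plantPool plants x habitats availability weights.
#' @slot preference bees x plants preference weights.
#' @slot propUnidentified fraction of visits with unidentified host plant.
#' @slot seed integer seed.
#' @export
setClass("SimConfig",
  representation(nSites = "integer", fracCorridor = "numeric",
    habitats = "character", meanTransects = "numeric", nRounds = "integer",
    beeSpecies = "character", sadX = "numeric", relAbundance = "numeric",
    baseMean = "numeric", betaFlower = "numeric", habitatEffects = "numeric",
    corridorEffect = "numeric", sdSite = "numeric", sdTransect = "numeric",
    dispersion = "numeric", family = "character",
    flowerClassProbs = "matrix", plantSpecies = "character",
    plantPool = "matrix", preference = "matrix",
    propUnidentified = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (object@sdSite < 0 || object@sdTransect < 0)
    msg <- c(msg, "random-effect SDs must be >= 0")
  if (!object@family %in% c("nbinom", "poisson", "gaussian"))
    msg <- c(msg, "family must be nbinom, poisson or gaussian")
  p <- object@flowerClassProbs
  if (ncol(p) != 7L || any(p < 0) ||
      any(abs(rowSums(p) - 1) > 1e-8))
    msg <- c(msg, "flowerClassProbs rows must be length-7 probability vectors")
  if (!all(object@habitats %in% rownames(p)))
    msg <- c(msg, "flowerClassProbs must have one row per habitat")
  if (object@propUnidentified < 0 || object@propUnidentified > 1)
    msg <- c(msg, "propUnidentified must be in [0, 1]")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ModelFit: a fitted mixed (or linear) model with its test table
#'
#' Wraps the underlying `nlme::lme` (or `stats::lm`) fit together with the
#' model specification, the sequential F-test table with level-based
#' denominator degrees of freedom, and a convergence flag. Degenerate inputs
#' (e.g. an all-zero response) yield a flagged, non-converged fit rather than
#' an error.
#'
#' @slot fit the underlying fitted model object (or NULL if degenerate).
#' @slot response which response was modelled.
#' @slot formula character representation of the fixed-effects formula.
#' @slot random character description of the random structure.
#' @slot varStruct "homoscedastic" or "habitat" (per-habitat variance weights).
#' @slot converged logical convergence flag.
#' @slot message diagnostic message for non-converged/degenerate fits.
#' @slot data the model frame used.
#' @export
setClass("ModelFit",
  representation(fit = "ANY", response = "character", formula = "character",
    random = "character", varStruct = "character", converged = "logical",
    message = "character", data = "data.frame"))

#' PowerResult: simulation-based power estimate
#'
#' @slot power rejection fraction among converged replicates.
#' @slot ciLow,ciHigh 95\% Wilson score interval for the power.
#' @slot nSims replicates attempted.
#' @slot nonConverged replicates dropped for non-convergence.
#' @slot alpha test level.
#' @slot effectPct percentage difference injected into the focal term.
#' @slot term the focal model term.
#' @export
setClass("PowerResult",
  representation(power = "numeric", ciLow = "numeric", ciHigh = "numeric",
    nSims = "integer", nonConverged = "integer", alpha = "numeric",
    effectPct = "numeric", term = "character"))

setValidity("PowerResult", function(object) {
  if (object@power < 0 || object@power > 1) return("power must be in [0,1]")
  if (object@ciLow > object@power || object@ciHigh < object@power)
    return("confidence interval must contain the estimate")
  TRUE
})
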