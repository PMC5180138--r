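#' @describeIn SurveyDesign-class transect table accessor
#' @param x,object a `SurveyDesign`
#' @export
transects <- function(x) {
  stopifnot(is(x, "SurveyDesign"))
  x@transects
}

#' @describeIn SurveyDesign-class site table accessor
#' @export
sites <- function(x) {
  stopifnot(is(x, "SurveyDesign"))
  x@sites
}

#' @describeIn SurveyDesign-class number of distinct transects
#' @export
nTransects <- function(x) length(unique(transects(x)$transect_id))

setMethod("show", "SurveyDesign", function(object) {
  tr <- object@transects
  cat("SurveyDesign:", length(unique(tr$site_id)), "sites,",
      nTransects(object), "transects,",
      length(unique(tr$round)), "round(s)\n")
  tab <- table(tr$habitat[!duplicated(tr$transect_id)])
  cat("transects per habitat:\n")
  print(tab)
})

#' Per-habitat transect counts of a design
#'
#' @param design a `SurveyDesign`.
#' @return named integer vector, one entry per habitat present, counting
#'   distinct transects.
#' @export
habitatCounts <- function(design) {
  tr <- transects(design)
  tr <- tr[!duplicated(tr$transect_id), ]
  tab <- table(factor(tr$habitat, levels = .HABITATS))
  c(tab)[tab > 0 | names(tab) %in% tr$habitat]
}

#' @describeIn SpeciesGroups-class threatened-species accessor
#' @param x,object a `SpeciesGroups`
#' @export
threatenedSpecies <- function(x) {
  stopifnot(is(x, "SpeciesGroups"))
  x@threatened
}

#' @describeIn SpeciesGroups-class provider-species accessor
#' @export
providerSpecies <- function(x) {
  stopifnot(is(x, "SpeciesGroups"))
  x@providers
}

#' @describeIn SpeciesGroups-class alias map accessor
#' @export
speciesAliases <- function(x) {
  stopifnot(is(x, "SpeciesGroups"))
  x@aliases
}

setMethod("show", "SpeciesGroups", function(object) {
  cat("SpeciesGroups\n")
  cat("  threatened:", paste(object@threatened, collapse = ", "), "\n")
  cat("  providers: ", paste(object@providers, collapse = ", "), "\n")
  if (length(object@aliases))
    cat("  aliases:   ",
        paste(names(object@aliases), "->", object@aliases, collapse = "; "),
        "\n")
})

#' Count matrix of a BeeAbundance
#'
#' @param x a `BeeAbundance`.
#' @return integer matrix, species x observations.
#' @export
beeCounts <- function(x) {
  stopifnot(is(x, "BeeAbundance"))
  SummarizedExperiment::assay(x, "counts")
}

#' Observation metadata of a BeeAbundance
#'
#' @param x a `BeeAbundance`.
#' @return `data.frame` of per-observation design metadata (transect, site,
#'   habitat, corridor status, flower class, round).
#' @export
observationData <- function(x) {
  stopifnot(is(x, "BeeAbundance"))
  as.data.frame(colData(x))
}

setMethod("show", "BeeAbundance", function(object) {
  cat("BeeAbundance:", nrow(object), "species x", ncol(object),
      "observations;", sum(beeCounts(object)), "individuals\n")
  callNextMethod()
})

#' @describeIn VisitationMatrix-class count matrix accessor
#' @param x,object a `VisitationMatrix`
#' @export
visitCounts <- function(x) {
  stopifnot(is(x, "VisitationMatrix"))
  x@visits
}

setMethod("show", "VisitationMatrix", function(object) {
  cat("VisitationMatrix [", object@subset, "]: ",
      nrow(object@visits), " plants x ", ncol(object@visits),
      " pollinators, ", sum(object@visits), " identified visits (",
      object@nUnidentified, " unidentified dropped)\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSites, "sites (",
      round(object@fracCorridor * object@nSites), "with corridor ),",
      length(object@habitats), "habitats,",
      object@nRounds, "rounds;",
      length(object@beeSpecies), "bee species,",
      length(object@plantSpecies), "plants; family",
      object@family, "; seed", object@seed, "\n")
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit:", object@response, "~", object@formula, "\n")
  cat("  random:", object@random, "| variance:", object@varStruct, "\n")
  if (!object@converged) {
    cat("  NOT CONVERGED:", object@message, "\n")
  } else {
    print(anovaTable(object))
  }
})

setMethod("show", "PowerResult", function(object) {
  cat(sprintf(
    "PowerResult: term '%s', %+g%% effect: power %.3f (95%% CI %.3f-%.3f), %d sims, %d non-converged, alpha %.3g\n",
    object@term, object@effectPct, object@power, object@ciLow, object@ciHigh,
    object@nSims, object@nonConverged, object@alpha))
})
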