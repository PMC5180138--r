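## End-to-end driver: validation -> abundance -> models -> diversity ->
## strength -> power, writing one plain-text artefact per stage plus a run
## manifest (config echo, seed, versions, file checksums). The driver adds
## no computation of its own: every table is re-derivable by calling the
## stage functions directly.

#' Pipeline configuration
#'
#' Either `designPath` + `visitsPath` (CSV inputs) or `sim` (a
#' \linkS4class{SimConfig}) must be given. Defaults follow the standard
#' protocol: rarefaction to 90 individuals, ordinal flower encoding,
#' transect-round observations, alpha 0.05 and a 20\% focal difference for
#' the power stage.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed for any simulation stages.
#' @param designPath,visitsPath CSV inputs (ignored when `sim` is given).
#' @param sim optional \linkS4class{SimConfig} to generate the survey.
#' @param rarefactionM rarefaction depth in individuals.
#' @param flowerEncoding `"ordinal"` or `"midpoint"`.
#' @param aggregateRounds sum survey rounds per transect?
#' @param runPower run the (comparatively slow) power stage?
#' @param powerEffectPct,powerNSims,alpha power-stage settings.
#' @param groups a \linkS4class{SpeciesGroups}.
#' @param verbose log stage progress to stderr?
#' @return a named list of settings.
#' @export
pipelineConfig <- function(outDir, seed = 1L, designPath = NULL,
                           visitsPath = NULL, sim = NULL,
                           rarefactionM = 90L,
                           flowerEncoding = "ordinal",
                           aggregateRounds = FALSE, runPower = FALSE,
                           powerEffectPct = 20, powerNSims = 200L,
                           alpha = 0.05, groups = speciesGroups(),
                           verbose = TRUE) {
  if (is.null(sim) && (is.null(designPath)))
    stop("either input paths or a simulation config is required")
  list(outDir = outDir, seed = as.integer(seed), designPath = designPath,
       visitsPath = visitsPath, sim = sim, rarefactionM = rarefactionM,
       flowerEncoding = flowerEncoding, aggregateRounds = aggregateRounds,
       runPower = runPower, powerEffectPct = powerEffectPct,
       powerNSims = powerNSims, alpha = alpha, groups = groups,
       verbose = verbose)
}

.stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  if (verbose)
    message("[", name, "] done in ",
            sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full survey analysis pipeline
#'
#' Produces, in order: the validation report, the abundance matrix, the
#' abundance/richness and group model tables, the site- and habitat-level
#' diversity partitions, the beta contrast test, the strength tables with
#' the bipartite edge list, optionally the power estimate, and a manifest.
#' Any stage error halts the run naming the stage; artefacts of completed
#' stages remain on disk.
#'
#' @param config list from [pipelineConfig()].
#' @return (invisibly) a list with every stage result.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  vb <- config$verbose

  if (!is.null(config$sim)) {
    survey <- .stage("simulate", vb, simulateSurvey(config$sim))
    design <- survey$design
    visits <- survey$visits
    writeSurveyDesign(design, out("design.csv"))
    writeVisits(visits, out("visits.csv"))
  } else {
    design <- .stage("load-design", vb, readSurveyDesign(config$designPath))
    visits <- .stage("load-visits", vb, {
      if (is.null(config$visitsPath)) stop("no visit table configured")
      readVisits(config$visitsPath, design, config$groups)
    })
  }

  validation <- .stage("validate", vb, {
    v <- list(n_sites = nrow(sites(design)),
              n_transects = nTransects(design),
              habitat_counts = as.list(habitatCounts(design)),
              n_visits = nrow(visits),
              n_unidentified_plants =
                sum(visits$plant_species == .UNIDENTIFIED))
    jsonlite::write_json(v, out("validation.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    v
  })

  abund <- .stage("abundance", vb, {
    a <- buildAbundance(visits, design,
                        aggregateRounds = config$aggregateRounds)
    tab <- cbind(observationData(a), t(beeCounts(a)))
    .writeTable(tab, out("abundance.csv"))
    a
  })

  models <- .stage("models", vb, {
    fits <- list(
      abundance = fitAbundanceModel(abund, "abundance",
                                    flowerEncoding = config$flowerEncoding),
      richness = fitAbundanceModel(abund, "richness",
                                   flowerEncoding = config$flowerEncoding))
    fits <- c(fits, groupModels(abund, config$groups,
                                flowerEncoding = config$flowerEncoding))
    tabs <- lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      if (!f@converged)
        return(data.frame(response = nm, term = NA, df_num = NA,
                          df_den = NA, F = NA, p = NA, significant = NA,
                          note = f@message))
      cbind(response = nm, anovaTable(f, alpha = config$alpha), note = "")
    })
    .writeTable(do.call(rbind, tabs), out("model_tests.csv"))
    fits
  })

  partitions <- .stage("diversity", vb, {
    ps <- diversityPartitions(abund, "site")
    ph <- withCallingHandlers(
      diversityPartitions(abund, "habitat", m = config$rarefactionM),
      warning = function(w) invokeRestart("muffleWarning"))
    .writeTable(rbind(ps, ph), out("partitions.csv"))
    list(site = ps, habitat = ph)
  })

  contrast <- .stage("beta-contrast", vb, {
    ct <- betaContrastTest(partitions$site, design)
    jsonlite::write_json(
      list(F = ct$statistic, df_num = ct$df[1L], df_den = ct$df[2L],
           p = ct$p.value, n = ct$n, group_means = as.list(ct$groupMeans)),
      out("beta_contrast.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    ct
  })

  strength <- .stage("strength", vb, {
    sr <- strengthReport(visits, design)
    .writeTable(sr$comparison, out("strength_comparison.csv"))
    for (nm in names(sr$tables))
      .writeTable(sr$tables[[nm]], out(paste0("strength_", nm, ".csv")))
    .writeTable(sr$edges, out("edge_list.csv"))
    sr
  })

  power <- NULL
  if (isTRUE(config$runPower)) {
    power <- .stage("power", vb, {
      pr <- estimatePower(design, gaussianTruth(),
                          term = "corridor",
                          effectPct = config$powerEffectPct,
                          nSims = config$powerNSims, alpha = config$alpha,
                          seed = config$seed + 500L)
      jsonlite::write_json(
        list(term = pr@term, effect_pct = pr@effectPct, power = pr@power,
             ci = c(pr@ciLow, pr@ciHigh), n_sims = pr@nSims,
             non_converged = pr@nonConverged, alpha = pr@alpha),
        out("power.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
      pr
    })
  }

  .stage("manifest", vb, {
    files <- setdiff(list.files(config$outDir), "manifest.json")
    sums <- tools::md5sum(file.path(config$outDir, files))
    manifest <- list(
      package = as.character(packageVersion("corridorbees")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      rarefaction_m = config$rarefactionM,
      flower_encoding = config$flowerEncoding,
      aggregate_rounds = config$aggregateRounds,
      alpha = config$alpha,
      power = list(run = isTRUE(config$runPower),
                   effect_pct = config$powerEffectPct,
                   n_sims = config$powerNSims),
      checksums = as.list(setNames(unname(sums), files)))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    manifest
  })

  invisible(list(design = design, visits = visits, validation = validation,
                 abundance = abund, models = models,
                 partitions = partitions, contrast = contrast,
                 strength = strength, power = power))
}

#' Reference table of habitat management costs
#'
#' Collated published per-hectare annual costs (euros) of maintaining or
#' enhancing the surveyed habitat types: mechanical transmission-corridor
#' maintenance, roadside mowing, agri-environment-scheme funding for
#' semi-natural grassland, sowing of nectar-rich flower seed and shrub
#' removal. Shipped verbatim as a packaged CSV; no computation, inflation or
#' currency adjustment is applied.
#'
#' @return data.frame with columns `item`, `habitat`, `cost_eur_ha_yr_low`,
#'   `cost_eur_ha_yr_high`, `note`.
#' @export
costReference <- function() {
  read.csv(system.file("extdata", "management_costs.csv",
                       package = "corridorbees"),
           stringsAsFactors = FALSE)
}
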