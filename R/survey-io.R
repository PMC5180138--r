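## Readers, writers and validated constructors for survey tables.
## All tabular IO is plain CSV/TSV with a header row, UTF-8.

.readTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE,
           check.names = FALSE, fileEncoding = "UTF-8")
}

.writeTable <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
}

.normLabel <- function(x) {
  x <- trimws(x)
  gsub("\\s+", " ", x)
}

#' Construct a validated SurveyDesign
#'
#' @param transects data.frame with columns `transect_id`, `site_id`,
#'   `habitat`, `round`, `flower_class` and optionally `date`. One row per
#'   transect-round survey event.
#' @param sites data.frame with `site_id`, `has_corridor` (logical) and
#'   optionally `name`. If NULL and `transects` carries a `has_corridor`
#'   column, the site table is derived from it.
#' @return a \linkS4class{SurveyDesign}.
#' @export
surveyDesign <- function(transects, sites = NULL) {
  if (nrow(transects) == 0L) stop("no transects")
  transects$habitat <- .normLabel(as.character(transects$habitat))
  transects$transect_id <- as.character(transects$transect_id)
  transects$site_id <- as.character(transects$site_id)
  transects$round <- as.integer(transects$round)
  transects$flower_class <- as.integer(transects$flower_class)
  if (is.null(sites)) {
    if (!"has_corridor" %in% names(transects))
      stop("need a site table or a has_corridor column in the transect table")
    sites <- unique(transects[, c("site_id", "has_corridor")])
    conflict <- sites$site_id[duplicated(sites$site_id)]
    if (length(conflict))
      stop("inconsistent has_corridor within site(s): ",
           paste(conflict, collapse = ", "))
  }
  sites$site_id <- as.character(sites$site_id)
  sites$has_corridor <- as.logical(sites$has_corridor)
  keep <- intersect(c("transect_id", "site_id", "habitat", "round",
                      "flower_class", "date", "has_corridor"),
                    names(transects))
  new("SurveyDesign", transects = transects[, keep],
      sites = sites[, intersect(c("site_id", "has_corridor", "name"),
                                names(sites))])
}

#' Read a transect table from CSV/TSV
#'
#' Expected columns: `site_id`, `has_corridor`, `habitat`, `transect_id`,
#' `round`, `flower_class`, optionally `date`. One row per transect-round.
#' Validation errors name the offending rows and, for habitat labels, list
#' the allowed vocabulary.
#'
#' @param path path to a CSV (or `.tsv`) file.
#' @return a validated \linkS4class{SurveyDesign}.
#' @export
readSurveyDesign <- function(path) {
  df <- .readTable(path)
  need <- c("site_id", "habitat", "transect_id", "round", "flower_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("transect table lacks required column(s): ",
         paste(miss, collapse = ", "))
  surveyDesign(df)
}

#' @rdname readSurveyDesign
#' @param design a `SurveyDesign` to write.
#' @export
writeSurveyDesign <- function(design, path) {
  tr <- transects(design)
  st <- sites(design)
  tr$has_corridor <- st$has_corridor[match(tr$site_id, st$site_id)]
  .writeTable(tr, path)
  invisible(path)
}

#' Default species groups
#'
#' The default grouping of the north-European bumblebee fauna used
#' throughout: *B. muscorum*, *B. humilis*, *B. sylvarum* and *B. soroeensis*
#' as species of conservation concern ("threatened"), and the six main
#' crop-pollinating species (*B. terrestris*, *B. lapidarius*,
#' *B. pascuorum*, *B. hypnorum*, *B. pratorum*, *B. hortorum*) as
#' "providers". The default alias map pools *B. lucorum* with
#' *B. terrestris*, the two being effectively indistinguishable as workers.
#'
#' @param threatened,providers character vectors of species labels.
#' @param aliases named character vector, synonym -> canonical label.
#' @return a \linkS4class{SpeciesGroups}.
#' @export
speciesGroups <- function(
    threatened = c("Bombus muscorum", "Bombus humilis",
                   "Bombus sylvarum", "Bombus soroeensis"),
    providers = c("Bombus terrestris", "Bombus lapidarius",
                  "Bombus pascuorum", "Bombus hypnorum",
                  "Bombus pratorum", "Bombus hortorum"),
    aliases = c("Bombus lucorum" = "Bombus terrestris")) {
  new("SpeciesGroups", threatened = threatened, providers = providers,
      aliases = aliases)
}

#' Apply the species alias map
#'
#' Labels are trimmed and whitespace-normalized; any label present in the
#' alias map is replaced by its canonical form. The mapping is idempotent:
#' applying it twice equals applying it once (alias targets must themselves
#' be canonical).
#'
#' @param species character vector of species labels.
#' @param groups a \linkS4class{SpeciesGroups} supplying the alias map.
#' @return canonicalized character vector.
#' @export
canonicalizeSpecies <- function(species, groups = speciesGroups()) {
  species <- .normLabel(species)
  al <- speciesAliases(groups)
  hit <- species %in% names(al)
  species[hit] <- unname(al[species[hit]])
  species
}

#' Read visit records
#'
#' Reads a table of individual foraging observations (columns `transect_id`,
#' `round`, `bee_species`, `plant_species`; unidentified host plants as
#' `"UNIDENTIFIED"` or empty). Species labels are canonicalized through the
#' alias map; records referencing transect-rounds absent from the design are
#' rejected with their row numbers.
#'
#' @param path path to a CSV/TSV file.
#' @param design the \linkS4class{SurveyDesign} the records belong to.
#' @param groups \linkS4class{SpeciesGroups} supplying the alias map.
#' @return data.frame of visit records (one row per observed individual).
#' @export
readVisits <- function(path, design, groups = speciesGroups()) {
  df <- .readTable(path)
  validateVisits(df, design, groups)
}

#' @rdname readVisits
#' @param visits data.frame of raw visit records.
#' @export
validateVisits <- function(visits, design, groups = speciesGroups()) {
  need <- c("transect_id", "round", "bee_species", "plant_species")
  miss <- setdiff(need, names(visits))
  if (length(miss))
    stop("visit table lacks required column(s): ", paste(miss, collapse = ", "))
  if (nrow(visits) == 0L) {
    warning("visit table is empty")
    visits$transect_id <- character(0)
    return(visits[, need])
  }
  visits$transect_id <- as.character(visits$transect_id)
  visits$round <- as.integer(visits$round)
  visits$bee_species <- canonicalizeSpecies(visits$bee_species, groups)
  visits$plant_species <- .normLabel(as.character(visits$plant_species))
  visits$plant_species[visits$plant_species == "" |
                         is.na(visits$plant_species)] <- .UNIDENTIFIED
  if (any(visits$bee_species == "" | is.na(visits$bee_species)))
    stop("empty bee_species at row(s): ",
         paste(which(visits$bee_species == "" | is.na(visits$bee_species)),
               collapse = ", "))
  tr <- transects(design)
  key <- paste(tr$transect_id, tr$round)
  vkey <- paste(visits$transect_id, visits$round)
  bad <- !vkey %in% key
  if (any(bad))
    stop("visit record(s) reference transect-rounds absent from the design: ",
         paste(unique(visits$transect_id[bad]), collapse = ", "),
         " (row(s) ", paste(utils::head(which(bad), 10L), collapse = ", "), ")")
  visits[, need]
}

#' @rdname readVisits
#' @export
writeVisits <- function(visits, path) {
  .writeTable(visits[, c("transect_id", "round", "bee_species",
                         "plant_species")], path)
  invisible(path)
}

#' Flower-class scores
#'
#' Maps the seven ordinal flower-density classes (percent cover `<1`, `1-5`,
#' `6-10`, `11-20`, `21-40`, `41-60`, `>61`) to a numeric covariate. The
#' default treats the class index itself as an ordinal score 1..7; the
#' `"midpoint"` encoding uses interval midpoints in percent cover.
#'
#' @param flowerClass integer vector of classes in 1..7.
#' @param encoding `"ordinal"` (default) or `"midpoint"`.
#' @return numeric scores.
#' @export
flowerScores <- function(flowerClass, encoding = c("ordinal", "midpoint")) {
  encoding <- match.arg(encoding)
  stopifnot(all(flowerClass %in% 1:7))
  if (encoding == "ordinal") as.numeric(flowerClass)
  else c(0.5, 3, 8, 15.5, 30.5, 50.5, 70)[flowerClass]
}

#' Construct a BeeAbundance from a count matrix
#'
#' @param counts integer matrix, species (rows) x observations (columns).
#' @param obs data.frame of per-observation metadata with columns
#'   `transect_id`, `round`, `site_id`, `habitat`, `has_corridor`,
#'   `flower_class` (one row per column of `counts`).
#' @return a validated \linkS4class{BeeAbundance}.
#' @export
beeAbundance <- function(counts, obs) {
  stopifnot(nrow(obs) == ncol(counts))
  cn <- colnames(counts)
  if (is.null(cn)) cn <- paste(obs$transect_id, obs$round, sep = ":")
  cd <- DataFrame(obs, row.names = cn)
  colnames(counts) <- cn
  new("BeeAbundance",
      SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

#' Tabulate visits into a BeeAbundance container
#'
#' Builds the species x observation count matrix. The observation unit is
#' the transect-round (default) or the transect with rounds summed. Every
#' surveyed observation in the design gets a column, including all-zero
#' columns for transects where no bumblebee was recorded.
#'
#' @param visits data.frame of (validated) visit records.
#' @param design the \linkS4class{SurveyDesign}.
#' @param aggregateRounds sum the survey rounds per transect into one
#'   observation? When TRUE the flower covariate is averaged over rounds.
#' @return a \linkS4class{BeeAbundance}.
#' @export
buildAbundance <- function(visits, design, aggregateRounds = FALSE) {
  tr <- transects(design)
  st <- sites(design)
  if (aggregateRounds) {
    obs <- tr[!duplicated(tr$transect_id), ]
    obs$flower_class <- as.numeric(tapply(tr$flower_class, tr$transect_id,
                                          mean)[obs$transect_id])
    obs$round <- NA_integer_
    obsKey <- obs$transect_id
    vKey <- visits$transect_id
  } else {
    obs <- tr
    obsKey <- paste(tr$transect_id, tr$round, sep = ":")
    vKey <- paste(visits$transect_id, visits$round, sep = ":")
  }
  species <- sort(unique(visits$bee_species))
  cts <- matrix(0L, nrow = length(species), ncol = nrow(obs),
                dimnames = list(species, obsKey))
  if (nrow(visits) && length(species)) {
    tab <- table(factor(visits$bee_species, levels = species),
                 factor(vKey, levels = obsKey))
    cts[] <- as.integer(tab)
  }
  cd <- DataFrame(
    transect_id = obs$transect_id,
    round = obs$round,
    site_id = obs$site_id,
    habitat = obs$habitat,
    has_corridor = st$has_corridor[match(obs$site_id, st$site_id)],
    flower_class = obs$flower_class,
    row.names = obsKey)
  new("BeeAbundance",
      SummarizedExperiment(assays = list(counts = cts), colData = cd))
}

#' Split an abundance container by species group
#'
#' Returns the column subsets of the count matrix for the threatened and the
#' provider species; species in neither group appear in neither output, so
#' the three blocks (threatened, providers, others) partition the species
#' pool and per-species counts are conserved exactly.
#'
#' @param abund a \linkS4class{BeeAbundance} (canonical species names).
#' @param groups a \linkS4class{SpeciesGroups}.
#' @return named list with elements `threatened` and `providers`, each a
#'   `BeeAbundance` over the same observations.
#' @export
classifyGroups <- function(abund, groups = speciesGroups()) {
  sp <- rownames(abund)
  list(threatened = abund[sp %in% threatenedSpecies(groups), ],
       providers = abund[sp %in% providerSpecies(groups), ])
}
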