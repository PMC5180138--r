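## Plant-pollinator visitation matrices and plant species strength.
## Dependency d_ij of pollinator j on plant i is the fraction of j's
## identified visits made on i (columns of the dependency matrix sum to 1);
## a plant's strength is the sum of all pollinators' dependencies on it, so
## strengths across plants sum exactly to the number of pollinator species.

#' Build a plant x pollinator visitation matrix for a habitat subset
#'
#' Restricts the visit records to transects of the requested habitats and
#' tabulates identified visits per (plant, bee) pair. Records with an
#' unidentified host plant are dropped (their number is retained in the
#' object); bee species without any identified visit in the subset get no
#' column.
#'
#' @param visits data.frame of visit records.
#' @param design the \linkS4class{SurveyDesign}.
#' @param habitats habitat labels to pool; default all seven.
#' @param subsetLabel label stored with the matrix.
#' @return a \linkS4class{VisitationMatrix}.
#' @export
buildVisitation <- function(visits, design, habitats = habitatLevels(),
                            subsetLabel = paste(habitats, collapse = "+")) {
  if (length(habitats) == 0L) stop("empty habitat set")
  bad <- setdiff(habitats, .HABITATS)
  if (length(bad))
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  tr <- transects(design)
  keep <- tr$transect_id[tr$habitat %in% habitats]
  v <- visits[visits$transect_id %in% keep, , drop = FALSE]
  unid <- v$plant_species == .UNIDENTIFIED
  nUnid <- sum(unid)
  v <- v[!unid, , drop = FALSE]
  if (nrow(v) == 0L) {
    warning("no identified visits in subset '", subsetLabel, "'")
    return(new("VisitationMatrix",
               visits = matrix(0L, 0L, 0L,
                               dimnames = list(character(0), character(0))),
               subset = subsetLabel, habitats = habitats,
               nUnidentified = as.integer(nUnid)))
  }
  tab <- table(plant = v$plant_species, bee = v$bee_species)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m <- m[, colSums(m) > 0, drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  new("VisitationMatrix", visits = m, subset = subsetLabel,
      habitats = habitats, nUnidentified = as.integer(nUnid))
}

#' Pollinator dependencies on each plant
#'
#' @param vm a \linkS4class{VisitationMatrix} (or a plain count matrix,
#'   plants x pollinators).
#' @return numeric matrix of the same shape: `d[i, j]` is the fraction of
#'   pollinator j's identified visits made on plant i; every column sums to
#'   exactly 1.
#' @export
dependencies <- function(vm) {
  m <- if (is(vm, "VisitationMatrix")) visitCounts(vm) else vm
  if (length(m) == 0L || sum(m) == 0) stop("no visits: dependency undefined")
  sweep(m, 2L, colSums(m), "/")
}

#' Plant species strengths
#'
#' Strength of a plant is the row sum of the dependency matrix: high either
#' because many pollinator species use the plant a little, or because a few
#' depend on it heavily. Ranks are by descending strength; ties are broken
#' alphabetically by plant name.
#'
#' @param dep dependency matrix from [dependencies()], or a
#'   \linkS4class{VisitationMatrix} (dependencies computed internally).
#' @return data.frame with columns `plant`, `strength`, `rank` plus one
#'   `dep.<pollinator>` column per pollinator, sorted by rank.
#' @export
strengths <- function(dep) {
  if (is(dep, "VisitationMatrix")) dep <- dependencies(dep)
  s <- rowSums(dep)
  ord <- order(-s, rownames(dep))
  out <- data.frame(plant = rownames(dep)[ord], strength = unname(s[ord]),
                    rank = seq_along(s), stringsAsFactors = FALSE)
  depCols <- as.data.frame(dep[ord, , drop = FALSE])
  names(depCols) <- paste0("dep.", colnames(dep))
  out <- cbind(out, depCols)
  rownames(out) <- NULL
  out
}

#' Strength tables for the standard habitat subsets
#'
#' Computes plant strengths over all habitats combined, over transmission
#' corridors only and over semi-natural grasslands only, plus a long-format
#' edge list (plant, bee, visit count) for bipartite plotting. Plants absent
#' from a subset are reported with `NA` strength in the combined comparison
#' table, mirroring the usual dash convention of printed strength tables
#' (zero identified visits in the subset and true absence are not
#' distinguishable from visit data; both print as `NA`).
#'
#' @param visits data.frame of visit records.
#' @param design the \linkS4class{SurveyDesign}.
#' @return list with `tables` (per-subset strength data.frames),
#'   `comparison` (plants x subsets strength/rank table) and `edges`
#'   (all-habitat edge list).
#' @export
strengthReport <- function(visits, design) {
  subsets <- list(
    all_habitats = habitatLevels(),
    transmission_corridors = "transmission_corridor",
    seminatural_grasslands = "seminatural_grassland")
  tables <- lapply(names(subsets), function(nm) {
    vm <- withCallingHandlers(
      buildVisitation(visits, design, subsets[[nm]], subsetLabel = nm),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(visitCounts(vm)) == 0L)
      return(data.frame(plant = character(0), strength = numeric(0),
                        rank = integer(0)))
    strengths(vm)
  })
  names(tables) <- names(subsets)
  plants <- sort(unique(unlist(lapply(tables, function(t) t$plant))))
  comparison <- data.frame(plant = plants, stringsAsFactors = FALSE)
  for (nm in names(subsets)) {
    t <- tables[[nm]]
    comparison[[paste0("strength_", nm)]] <-
      t$strength[match(plants, t$plant)]
    comparison[[paste0("rank_", nm)]] <- t$rank[match(plants, t$plant)]
  }
  comparison <- comparison[
    order(-ifelse(is.na(comparison$strength_all_habitats), -Inf,
                  comparison$strength_all_habitats), comparison$plant), ]
  rownames(comparison) <- NULL
  vmAll <- withCallingHandlers(
    buildVisitation(visits, design, subsetLabel = "all_habitats"),
    warning = function(w) invokeRestart("muffleWarning"))
  m <- visitCounts(vmAll)
  edges <- if (length(m)) {
    idx <- which(m > 0, arr.ind = TRUE)
    data.frame(plant = rownames(m)[idx[, 1L]], bee = colnames(m)[idx[, 2L]],
               visits = m[idx], stringsAsFactors = FALSE)
  } else {
    data.frame(plant = character(0), bee = character(0), visits = integer(0))
  }
  list(tables = tables, comparison = comparison, edges = edges)
}

#' Pollinator strengths (transposed metric)
#'
#' The mirror-image metric: each plant's visits are normalized across
#' pollinators (plant dependence on each bee) and summed per bee. Provided
#' for completeness; the primary analysis uses plant strengths.
#'
#' @param vm a \linkS4class{VisitationMatrix}.
#' @return data.frame with columns `bee`, `strength`, `rank`.
#' @export
pollinatorStrengths <- function(vm) {
  m <- t(visitCounts(vm))
  if (length(m) == 0L || sum(m) == 0) stop("no visits")
  dep <- sweep(m, 2L, colSums(m), "/")
  s <- rowSums(dep)
  ord <- order(-s, rownames(dep))
  data.frame(bee = rownames(dep)[ord], strength = unname(s[ord]),
             rank = seq_along(s), stringsAsFactors = FALSE)
}
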