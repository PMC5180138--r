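## Additive alpha/beta/gamma partitioning of transect species richness and
## exact individual-based rarefaction. Alpha is the mean per-observation
## richness, gamma the (optionally rarefied) richness of the pooled unit and
## beta = gamma - alpha, so alpha + beta = gamma holds machine-exactly.

.obsRichness <- function(cts) colSums(cts > 0)

#' Alpha diversity: mean species richness per observation
#'
#' @param abund a \linkS4class{BeeAbundance}.
#' @param subset optional logical/integer selection of observations
#'   (columns); default all.
#' @return mean over the selected observations of the number of species with
#'   count > 0.
#' @export
alphaDiversity <- function(abund, subset = NULL) {
  cts <- beeCounts(abund)
  if (!is.null(subset)) cts <- cts[, subset, drop = FALSE]
  if (ncol(cts) == 0L) stop("no observations in unit")
  mean(.obsRichness(cts))
}

#' Exact individual-based rarefied richness
#'
#' Expected number of species in a uniform random subsample of `m`
#' individuals from a pooled community, by the hypergeometric formula
#' \deqn{E[S_m] = \sum_i \left[1 - \binom{N - N_i}{m} / \binom{N}{m}\right]}
#' evaluated with log-combinatorics so large communities do not overflow.
#' When `m` exceeds the pooled total `N`, the observed richness is returned
#' and the result is flagged as a shallow sample (attribute `"shallow"`).
#'
#' @param counts non-negative integer vector of per-species abundances.
#' @param m rarefaction depth (individuals), `m >= 1`.
#' @return expected richness (numeric scalar) with logical attribute
#'   `"shallow"`.
#' @export
rarefiedRichness <- function(counts, m) {
  if (length(m) != 1L || is.na(m) || m <= 0 || m != round(m))
    stop("m must be a positive integer")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) stop("community is empty")
  sObs <- length(counts)
  if (m > n) {
    return(structure(as.numeric(sObs), shallow = TRUE))
  }
  es <- sum(1 - exp(lchoose(n - counts, m) - lchoose(n, m)))
  structure(es, shallow = FALSE)
}

#' Rarefaction curve
#'
#' Exact expected richness at each subsample size `1..N` (or a supplied
#' grid). The curve is non-decreasing and concave, starts at
#' `E[S_1] = 1` and ends at the observed richness.
#'
#' @param counts per-species abundance vector.
#' @param mValues subsample sizes; default `1:N`.
#' @return data.frame with columns `m` and `expected`.
#' @export
rarefactionCurve <- function(counts, mValues = NULL) {
  n <- sum(counts[counts > 0])
  if (is.null(mValues)) mValues <- seq_len(n)
  data.frame(m = mValues,
             expected = vapply(mValues, function(m)
               as.numeric(rarefiedRichness(counts, m)), numeric(1)))
}

.partitionRow <- function(scope, unit, alpha, gamma, rarefied, m, shallow) {
  # beta is the correctly rounded difference, so gamma - alpha == beta holds
  # bitwise and alpha + beta recovers gamma to within one ulp (bitwise
  # equality of the re-summation is unattainable in general: the rounded
  # sum can tie-round past gamma)
  beta <- gamma - alpha
  data.frame(scope = scope, unit = unit, alpha = alpha,
             beta = beta, gamma = gamma, rarefied = rarefied,
             rarefaction_m = if (rarefied) m else NA_integer_,
             shallow = shallow, stringsAsFactors = FALSE)
}

#' Site-level additive diversity partition
#'
#' Alpha is the mean richness over the site's observations (all habitats
#' pooled), gamma the total richness of the pooled site (not rarefied) and
#' beta their difference.
#'
#' @param abund a \linkS4class{BeeAbundance}.
#' @param site a site identifier present in the data.
#' @return one-row data.frame with columns `scope`, `unit`, `alpha`,
#'   `beta`, `gamma`, `rarefied`, `rarefaction_m`, `shallow`.
#' @export
partitionSite <- function(abund, site) {
  sel <- observationData(abund)$site_id == site
  if (!any(sel)) stop("site '", site, "' has no observations")
  cts <- beeCounts(abund)[, sel, drop = FALSE]
  alpha <- mean(.obsRichness(cts))
  gamma <- sum(rowSums(cts) > 0)
  .partitionRow("site", site, alpha, gamma, FALSE, NA_integer_, FALSE)
}

#' Habitat-level additive diversity partition with rarefied gamma
#'
#' Gamma is the expected richness of a uniform subsample of `m` individuals
#' from all the habitat's pooled individuals (standardizing for unequal
#' sampling intensity across habitats); alpha is the raw mean per-observation
#' richness. When the habitat holds fewer than `m` individuals the observed
#' pooled richness is used and the row is flagged shallow. Rarefied beta can
#' be negative for species-poor, even habitats; it is reported with a
#' warning, not clipped.
#'
#' @param abund a \linkS4class{BeeAbundance}.
#' @param habitat a habitat label present in the data.
#' @param m rarefaction depth in individuals (default 90).
#' @return one-row data.frame as in [partitionSite()].
#' @export
partitionHabitat <- function(abund, habitat, m = 90L) {
  sel <- observationData(abund)$habitat == habitat
  if (!any(sel)) stop("habitat '", habitat, "' has no observations")
  cts <- beeCounts(abund)[, sel, drop = FALSE]
  pooled <- rowSums(cts)
  if (sum(pooled) < 1) stop("habitat '", habitat, "' has no individuals")
  alpha <- mean(.obsRichness(cts))
  g <- rarefiedRichness(pooled, m)
  if (as.numeric(g) < alpha)
    warning("rarefied gamma below alpha for habitat '", habitat,
            "'; beta is negative")
  .partitionRow("habitat", habitat, alpha, as.numeric(g), TRUE,
                as.integer(m), isTRUE(attr(g, "shallow")))
}

#' All site- or habitat-level partitions of a survey
#'
#' @param abund a \linkS4class{BeeAbundance}.
#' @param scope `"site"` or `"habitat"`.
#' @param m rarefaction depth for habitat partitions.
#' @return data.frame, one row per unit.
#' @export
diversityPartitions <- function(abund, scope = c("site", "habitat"),
                                m = 90L) {
  scope <- match.arg(scope)
  od <- observationData(abund)
  if (scope == "site") {
    do.call(rbind, lapply(sort(unique(od$site_id)),
                          function(s) partitionSite(abund, s)))
  } else {
    habs <- sort(unique(od$habitat))
    habs <- habs[vapply(habs, function(h)
      sum(beeCounts(abund)[, od$habitat == h, drop = FALSE]) > 0, logical(1))]
    do.call(rbind, lapply(habs, function(h) partitionHabitat(abund, h, m)))
  }
}

#' Beta-diversity contrast between corridor and non-corridor sites
#'
#' One-way fixed-effects ANOVA of the per-site beta diversity on corridor
#' status; with 10 sites (5 + 5) the F statistic has (1, 8) degrees of
#' freedom. If every site has identical beta the test is degenerate and
#' reported as F = 0, p = 1.
#'
#' @param partitions data.frame of site-level partitions (from
#'   [diversityPartitions()] with `scope = "site"`).
#' @param design the \linkS4class{SurveyDesign} supplying corridor status.
#' @return list with `statistic` (F), `df` (numerator, denominator),
#'   `p.value`, `n` and per-group mean betas.
#' @export
betaContrastTest <- function(partitions, design) {
  st <- sites(design)
  grp <- st$has_corridor[match(partitions$unit, st$site_id)]
  if (any(is.na(grp)))
    stop("partition units not found in site table: ",
         paste(partitions$unit[is.na(grp)], collapse = ", "))
  if (min(table(grp)) < 2L)
    stop("each corridor group needs at least 2 sites")
  beta <- partitions$beta
  g <- factor(ifelse(grp, "corridor", "no_corridor"))
  dfs <- c(nlevels(g) - 1L, length(beta) - nlevels(g))
  if (diff(range(beta)) <
      .Machine$double.eps^0.5 * max(1, abs(mean(beta)))) {
    # identical betas everywhere: no variance in either stratum
    f <- 0
    p <- 1
  } else {
    at <- anova(lm(beta ~ g))
    f <- at$`F value`[1L]
    p <- at$`Pr(>F)`[1L]
  }
  list(statistic = f, df = dfs, p.value = p, n = length(beta),
       groupMeans = tapply(beta, g, mean))
}
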