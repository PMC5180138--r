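## Simulation-based power: inject a percentage difference into the focal
## term of the Gaussian generator, simulate over the observed design, refit
## and test at alpha; power is the rejection fraction with a Wilson score
## interval. A "pct % difference" means the focal group's expected response
## is pct % higher than the reference group's mean expected response.

.wilson <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Default Gaussian generator parameters for power experiments
#'
#' @param mu0,betaFlower,habitatEffects,corridorEffect,sdSite,sdTransect,sigma
#'   see [simulateResponse()].
#' @return named list of generator parameters.
#' @export
gaussianTruth <- function(mu0 = 10, betaFlower = 0, habitatEffects = 0,
                          corridorEffect = 0, sdSite = 1, sdTransect = 1,
                          sigma = 2) {
  list(mu0 = mu0, betaFlower = betaFlower, habitatEffects = habitatEffects,
       corridorEffect = corridorEffect, sdSite = sdSite,
       sdTransect = sdTransect, sigma = sigma)
}

## expected response per observation under the null generator
.nullMu <- function(design, params) {
  tr <- transects(design)
  he <- params$habitatEffects
  if (length(he) == 1L && is.null(names(he)))
    he <- setNames(rep(he, length(unique(tr$habitat))),
                   sort(unique(tr$habitat)))
  params$mu0 + params$betaFlower * (tr$flower_class - 1) +
    unname(he[tr$habitat])
}

#' Rescale the focal effect to a percentage difference
#'
#' Sets the focal coefficient so the expected response of the focal group is
#' `pct` percent higher than the reference group's mean expected response,
#' all other terms held fixed. For `term = "corridor"` the focal group is
#' the corridor-bisected sites; for `term = "habitat"` it is the
#' semi-natural grasslands against all other habitats. `pct = 0` returns
#' the null generator unchanged.
#'
#' @param params generator parameters (see [gaussianTruth()]).
#' @param design the \linkS4class{SurveyDesign} the responses will be
#'   simulated over.
#' @param term `"corridor"` or `"habitat"`.
#' @param pct percentage difference in expected response (e.g. 20).
#' @return modified parameter list.
#' @export
setEffect <- function(params, design, term = c("corridor", "habitat"),
                      pct = 20) {
  term <- match.arg(term)
  stopifnot(pct >= 0)
  tr <- transects(design)
  st <- sites(design)
  mu <- .nullMu(design, params)
  if (term == "corridor") {
    corr <- st$has_corridor[match(tr$site_id, st$site_id)]
    if (!any(corr) || all(corr))
      stop("term 'corridor' absent: design has a single site type")
    ref <- mean(mu[!corr])
    params$corridorEffect <- pct / 100 * ref
  } else {
    focal <- tr$habitat == "seminatural_grassland"
    if (!any(focal) || all(focal))
      stop("term 'habitat' contrast needs grassland and non-grassland transects")
    ref <- mean(mu[!focal])
    he <- params$habitatEffects
    if (length(he) == 1L && is.null(names(he)))
      he <- setNames(rep(he, length(unique(tr$habitat))),
                     sort(unique(tr$habitat)))
    he["seminatural_grassland"] <-
      he["seminatural_grassland"] + pct / 100 * ref
    params$habitatEffects <- he
  }
  params
}

#' Simulation-based power for a focal model term
#'
#' For each replicate: simulate Gaussian responses over the design from the
#' effect-adjusted generator, refit the model and test the focal term at
#' `alpha` with the sequential F-test. Power is the rejection fraction among
#' converged replicates; replicates that fail to converge are dropped with
#' a warning, never imputed. Fully reproducible under a fixed seed.
#'
#' @param design a \linkS4class{SurveyDesign}.
#' @param params null-generator parameters (see [gaussianTruth()]).
#' @param term focal term, `"corridor"` or `"habitat"`.
#' @param effectPct percentage difference to detect (default 20).
#' @param nSims number of simulation replicates.
#' @param alpha test level (default 0.05).
#' @param seed integer seed.
#' @param engine model engine passed to [fitLmm()]; use `"lm"` for designs
#'   without random structure.
#' @param includeHabitat include the habitat fixed term in the refitted
#'   model?
#' @return a \linkS4class{PowerResult}.
#' @export
estimatePower <- function(design, params = gaussianTruth(),
                          term = c("corridor", "habitat"), effectPct = 20,
                          nSims = 200L, alpha = 0.05, seed,
                          engine = c("lme", "lm"), includeHabitat = TRUE) {
  term <- match.arg(term)
  engine <- match.arg(engine)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nSims >= 1L)
  p2 <- setEffect(params, design, term, effectPct)
  includeCorridor <- term == "corridor" ||
    length(unique(sites(design)$has_corridor)) > 1L
  rejected <- 0L
  bad <- 0L
  for (i in seq_len(nSims)) {
    dat <- simulateResponse(
      design, mu0 = p2$mu0, betaFlower = p2$betaFlower,
      habitatEffects = p2$habitatEffects, corridorEffect = p2$corridorEffect,
      sdSite = p2$sdSite, sdTransect = p2$sdTransect, sigma = p2$sigma,
      seed = seed + i)
    fit <- fitLmm(dat, includeHabitat = includeHabitat,
                  includeCorridor = includeCorridor, engine = engine)
    if (!fit@converged) {
      bad <- bad + 1L
      next
    }
    at <- anovaTable(fit, alpha = alpha)
    row <- at[at$term == term, , drop = FALSE]
    if (nrow(row) != 1L) stop("focal term '", term, "' absent from fit")
    if (row$p < alpha) rejected <- rejected + 1L
  }
  nOk <- nSims - bad
  if (nOk == 0L) stop("all replicates failed to converge")
  if (bad > 0L)
    warning(bad, " replicate(s) failed to converge and were dropped")
  ci <- .wilson(rejected, nOk)
  new("PowerResult", power = rejected / nOk, ciLow = unname(ci["low"]),
      ciHigh = unname(ci["high"]), nSims = as.integer(nSims),
      nonConverged = as.integer(bad), alpha = alpha,
      effectPct = as.numeric(effectPct), term = term)
}

#' Power across a grid of effect sizes
#'
#' @inheritParams estimatePower
#' @param effects numeric vector of percentage differences.
#' @return data.frame with one row per effect size (`effect_pct`, `power`,
#'   `ci_low`, `ci_high`, `non_converged`).
#' @export
powerCurve <- function(design, params = gaussianTruth(), effects = c(0, 20, 50),
                       term = "corridor", nSims = 200L, alpha = 0.05, seed,
                       engine = "lme", includeHabitat = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  rows <- lapply(seq_along(effects), function(k) {
    pr <- estimatePower(design, params, term, effects[k], nSims, alpha,
                        seed = seed + 10000L * k, engine = engine,
                        includeHabitat = includeHabitat)
    data.frame(effect_pct = effects[k], power = pr@power, ci_low = pr@ciLow,
               ci_high = pr@ciHigh, non_converged = pr@nonConverged)
  })
  do.call(rbind, rows)
}
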