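## Gaussian linear mixed models for per-observation abundance/richness with
## transect nested in site as random intercepts, fitted by REML through
## nlme::lme. Sequential (type-I) F-tests use level-based denominator
## degrees of freedom: a term constant within sites (corridor status) is
## tested in the site stratum (n_sites - 1 - other site-level parameters),
## terms varying within sites in the stratum where they vary.

.mfNeed <- c("y", "flower", "habitat", "corridor", "site", "transect")

#' Fit a Gaussian linear mixed model on a survey model frame
#'
#' Low-level fitter shared by the abundance/richness models and the power
#' simulation. Fixed effects are entered sequentially in the order flower,
#' habitat, corridor; random intercepts are transect nested within site
#' (site only, when each transect contributes a single observation). With
#' `engine = "lm"` an ordinary least-squares fit is returned instead (no
#' random effects), which the mixed fit must match when the random-effect
#' variances are zero.
#'
#' @param data data.frame with columns `y`, `flower`, `habitat`,
#'   `corridor`, `site`, `transect`.
#' @param includeFlower,includeHabitat,includeCorridor include these fixed
#'   terms? Factor terms with fewer than two observed levels are dropped
#'   automatically.
#' @param varStruct `"homoscedastic"` or `"habitat"` for per-habitat
#'   variance weights (`nlme::varIdent`); with equal weights the latter
#'   reduces to the former.
#' @param engine `"lme"` (REML mixed model) or `"lm"` (ordinary least
#'   squares).
#' @param response label stored in the result.
#' @return a \linkS4class{ModelFit}; non-convergence and degenerate inputs
#'   (constant response, single site with a corridor term) are flagged, not
#'   silent.
#' @export
fitLmm <- function(data, includeFlower = TRUE, includeHabitat = TRUE,
                   includeCorridor = TRUE,
                   varStruct = c("homoscedastic", "habitat"),
                   engine = c("lme", "lm"), response = "y") {
  varStruct <- match.arg(varStruct)
  engine <- match.arg(engine)
  miss <- setdiff(.mfNeed, names(data))
  if (length(miss))
    stop("model frame lacks column(s): ", paste(miss, collapse = ", "))
  data$habitat <- factor(data$habitat)
  data$corridor <- factor(data$corridor)
  data$site <- factor(data$site)
  data$transect <- factor(data$transect)
  if (includeCorridor && nlevels(data$corridor) < 2L)
    stop("corridor term requires both site types in the data")
  if (includeCorridor && nlevels(data$site) < 2L)
    stop("corridor term requires at least two sites")
  terms <- c(if (includeFlower) "flower",
             if (includeHabitat && nlevels(data$habitat) > 1L) "habitat",
             if (includeCorridor) "corridor")
  if (!length(terms)) terms <- "1"
  fixed <- as.formula(paste("y ~", paste(terms, collapse = " + ")))
  nested <- any(table(data$transect) > 1L)
  randomDesc <- if (nested) "~1 | site/transect" else "~1 | site"
  if (sd(data$y) == 0)
    return(new("ModelFit", fit = NULL, response = response,
               formula = deparse(fixed[[3L]]), random = randomDesc,
               varStruct = varStruct, converged = FALSE,
               message = "degenerate: constant response", data = data))
  fit <- NULL
  msg <- ""
  if (engine == "lm") {
    fit <- lm(fixed, data = data)
    conv <- TRUE
  } else {
    random <- if (nested) ~1 | site / transect else ~1 | site
    weights <- if (varStruct == "habitat")
      nlme::varIdent(form = ~1 | habitat) else NULL
    fit <- tryCatch(
      nlme::lme(fixed, random = random, data = data, weights = weights,
                method = "REML",
                control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                           returnObject = FALSE)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      msg <- conditionMessage(fit)
      fit <- NULL
      conv <- FALSE
    } else conv <- TRUE
  }
  new("ModelFit", fit = fit, response = response,
      formula = deparse(fixed[[3L]]), random = randomDesc,
      varStruct = varStruct, converged = conv, message = msg, data = data)
}

#' Build the model frame of a survey
#'
#' @param abund a \linkS4class{BeeAbundance}.
#' @param response one of `"abundance"`, `"richness"`,
#'   `"provider_abundance"`, `"threatened_abundance"`.
#' @param groups \linkS4class{SpeciesGroups} for the group responses.
#' @param flowerEncoding passed to [flowerScores()].
#' @param logTransform model `log(y + 1)` instead of `y`?
#' @return data.frame ready for [fitLmm()].
#' @export
modelFrame <- function(abund,
                       response = c("abundance", "richness",
                                    "provider_abundance",
                                    "threatened_abundance"),
                       groups = speciesGroups(),
                       flowerEncoding = "ordinal", logTransform = FALSE) {
  response <- match.arg(response)
  cts <- beeCounts(abund)
  od <- observationData(abund)
  y <- switch(response,
    abundance = colSums(cts),
    richness = colSums(cts > 0),
    provider_abundance =
      colSums(cts[rownames(cts) %in% providerSpecies(groups), ,
                  drop = FALSE]),
    threatened_abundance =
      colSums(cts[rownames(cts) %in% threatenedSpecies(groups), ,
                  drop = FALSE]))
  if (logTransform) y <- log1p(y)
  fc <- od$flower_class
  flower <- if (all(fc == round(fc))) flowerScores(fc, flowerEncoding)
            else as.numeric(fc) # round-aggregated designs carry mean classes
  data.frame(
    y = as.numeric(y), flower = flower, habitat = od$habitat,
    corridor = ifelse(od$has_corridor, "corridor", "no_corridor"),
    site = od$site_id, transect = od$transect_id,
    stringsAsFactors = FALSE)
}

#' Fit the standard abundance or richness model
#'
#' Species abundance (or richness) per observation as a function of flower
#' density, habitat type and corridor status, with transect nested within
#' site as random intercepts — the two whole-survey models. Group responses
#' (`provider_abundance`, `threatened_abundance`) drop the corridor term and
#' keep flower + habitat.
#'
#' @inheritParams modelFrame
#' @param varStruct,includeCorridor see [fitLmm()]; `includeCorridor`
#'   defaults to TRUE for the whole-survey responses and FALSE for the
#'   group responses.
#' @return a \linkS4class{ModelFit}.
#' @export
fitAbundanceModel <- function(abund,
                              response = c("abundance", "richness",
                                           "provider_abundance",
                                           "threatened_abundance"),
                              groups = speciesGroups(),
                              flowerEncoding = "ordinal",
                              logTransform = FALSE,
                              varStruct = "homoscedastic",
                              includeCorridor = !grepl("_", response[1L])) {
  response <- match.arg(response)
  mf <- modelFrame(abund, response, groups, flowerEncoding, logTransform)
  fitLmm(mf, includeCorridor = includeCorridor, varStruct = varStruct,
         response = response)
}

#' Sequential F-test table of a fitted model
#'
#' Type-I (sequential) tests in the entry order flower, habitat, corridor.
#' Denominator degrees of freedom follow the grouping-level rule: corridor
#' status, constant within sites, is tested against the site stratum
#' (`n_sites - 1 - 1` with no other site-level fixed terms), habitat against
#' the transect stratum, and the flower covariate, varying between rounds
#' within a transect, against the observation stratum.
#'
#' @param fit a converged \linkS4class{ModelFit}.
#' @param alpha significance threshold used for the `significant` column.
#' @param holm apply a Holm correction across the terms? Off by default.
#' @return data.frame with columns `term`, `df_num`, `df_den`, `F`, `p`,
#'   `significant`.
#' @export
anovaTable <- function(fit, alpha = 0.05, holm = FALSE) {
  stopifnot(is(fit, "ModelFit"))
  if (!fit@converged)
    stop("model did not converge: ", fit@message)
  if (inherits(fit@fit, "lm")) {
    at <- anova(fit@fit)
    k <- nrow(at)
    out <- data.frame(term = rownames(at)[-k], df_num = at$Df[-k],
                      df_den = at$Df[k], F = at$`F value`[-k],
                      p = at$`Pr(>F)`[-k], stringsAsFactors = FALSE)
  } else {
    at <- anova(fit@fit, type = "sequential")
    keep <- rownames(at) != "(Intercept)"
    out <- data.frame(term = rownames(at)[keep],
                      df_num = as.integer(round(at$numDF[keep])),
                      df_den = as.integer(round(at$denDF[keep])),
                      F = at$`F-value`[keep],
                      p = at$`p-value`[keep], stringsAsFactors = FALSE)
  }
  p <- if (holm) stats::p.adjust(out$p, "holm") else out$p
  out$significant <- p < alpha
  rownames(out) <- NULL
  out
}

#' Fixed-effect estimates with standard errors and intervals
#'
#' @param fit a converged \linkS4class{ModelFit}.
#' @param level confidence level.
#' @return data.frame with `term`, `estimate`, `se`, `df`, `lower`,
#'   `upper`.
#' @export
fixedEffects <- function(fit, level = 0.95) {
  stopifnot(is(fit, "ModelFit"))
  if (!fit@converged) stop("model did not converge: ", fit@message)
  if (inherits(fit@fit, "lm")) {
    est <- coef(fit@fit)
    se <- sqrt(diag(vcov(fit@fit)))
    df <- fit@fit$df.residual
  } else {
    tt <- summary(fit@fit)$tTable
    est <- tt[, "Value"]
    se <- tt[, "Std.Error"]
    df <- tt[, "DF"]
  }
  q <- qt(1 - (1 - level) / 2, df)
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             df = unname(df), lower = unname(est - q * se),
             upper = unname(est + q * se), stringsAsFactors = FALSE)
}

#' Random-effect variance components
#'
#' @param fit a converged mixed \linkS4class{ModelFit}.
#' @return named numeric vector of standard deviations (site, transect
#'   where present, residual).
#' @export
varianceComponents <- function(fit) {
  stopifnot(is(fit, "ModelFit"))
  if (!fit@converged) stop("model did not converge: ", fit@message)
  if (inherits(fit@fit, "lm"))
    return(c(residual = summary(fit@fit)$sigma))
  vc <- nlme::VarCorr(fit@fit)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  nm <- rownames(vc)
  keep <- !is.na(sds)
  setNames(sds[keep], tolower(gsub(" =.*", "", nm[keep])))
}

#' Fit the provider- and threatened-species abundance models
#'
#' Per-observation total abundance of each species group as a function of
#' habitat and flower density, with transect nested in site as random
#' intercepts and no corridor term. A group that was never recorded yields a
#' flagged degenerate fit instead of an error.
#'
#' @param abund a \linkS4class{BeeAbundance}.
#' @param groups a \linkS4class{SpeciesGroups}.
#' @param ... passed to [fitAbundanceModel()].
#' @return named list with elements `providers` and `threatened`, each a
#'   \linkS4class{ModelFit}.
#' @export
groupModels <- function(abund, groups = speciesGroups(), ...) {
  list(
    providers = fitAbundanceModel(abund, "provider_abundance",
                                  groups = groups, ...),
    threatened = fitAbundanceModel(abund, "threatened_abundance",
                                   groups = groups, ...))
}
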