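# shared builders for hand-made designs and independent oracles

fixtureDesignPath <- function()
  system.file("extdata", "survey_design_table1.csv", package = "corridorbees")

# two sites, three transects, two rounds: small enough to hand-tabulate
tinyDesign <- function() {
  tr <- data.frame(
    site_id = c("A", "A", "A", "A", "B", "B"),
    has_corridor = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    habitat = c("transmission_corridor", "transmission_corridor",
                "seminatural_grassland", "seminatural_grassland",
                "forest", "forest"),
    transect_id = c("t1", "t1", "t2", "t2", "t3", "t3"),
    round = c(1L, 2L, 1L, 2L, 1L, 2L),
    flower_class = c(4L, 5L, 5L, 5L, 2L, 1L),
    stringsAsFactors = FALSE)
  surveyDesign(tr)
}

# balanced Latin-square design: every site holds one transect of each of the
# six non-corridor habitats, one round, flower classes 1..6 once per site
balancedDesign <- function(nSites = 10L) {
  habs <- setdiff(habitatLevels(), "transmission_corridor")
  tr <- expand.grid(site_id = sprintf("S%02d", seq_len(nSites)),
                    habitat = habs, stringsAsFactors = FALSE)
  tr$transect_id <- sprintf("T%03d", seq_len(nrow(tr)))
  tr$round <- 1L
  si <- as.integer(factor(tr$site_id))
  hj <- as.integer(factor(tr$habitat))
  tr$flower_class <- ((si + hj) %% 6L) + 1L
  tr$has_corridor <- si <= nSites %/% 2L
  surveyDesign(tr)
}

# two-group design for the analytic power oracle: one observation per site,
# half the sites corridor-bisected, no habitat or flower variation
twoGroupDesign <- function(nPerGroup = 12L) {
  n <- 2L * nPerGroup
  tr <- data.frame(
    site_id = sprintf("G%03d", seq_len(n)),
    has_corridor = rep(c(TRUE, FALSE), each = nPerGroup),
    habitat = "seminatural_grassland",
    transect_id = sprintf("T%03d", seq_len(n)),
    round = 1L, flower_class = 4L, stringsAsFactors = FALSE)
  surveyDesign(tr)
}

# Monte-Carlo rarefaction oracle: mean richness of `reps` uniform
# subsamples of m individuals, with its standard error
mcRarefy <- function(counts, m, reps) {
  labels <- rep.int(seq_along(counts), counts)
  n <- length(labels)
  draws <- vapply(seq_len(reps), function(i)
    length(unique(labels[sample.int(n, m)])), numeric(1))
  list(mean = mean(draws), se = stats::sd(draws) / sqrt(reps))
}

# explicit one-way ANOVA F from sums of squares
oneWayF <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1L
  dfw <- length(y) - nlevels(g)
  list(F = (ssb / dfb) / (ssw / dfw), df = c(dfb, dfw))
}
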