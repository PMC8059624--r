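#' @include AllClasses.R AllGenerics.R survey.R traitTable.R
NULL

#' Default trait specification for the two species pools
#'
#' Fifteen functional traits in five groups (habitat affinity, life
#' history, body size, feeding ecology, foodweb characteristics), with
#' pool-specific generating distributions. The boreal pool is built as
#' motile, large, piscivorous generalists — larger body size and growth
#' capacity, higher temperature affinity, later maturity, more trophic
#' links to fish prey and to bird/mammal predators — while the Arctic pool
#' is smaller, benthivorous and specialized. Quantitative (and rank-coded
#' ordinal) traits are drawn from pool-specific normals; the two fuzzy
#' traits (diet and habitat zone) draw category memberships from
#' pool-specific Dirichlet parameters.
#'
#' `contrast` scales the whole between-pool difference: 1 gives the
#' default contrasted pools (mean gaps of 1 to 2 pooled standard
#' deviations on the boreal-syndrome traits, and a narrower Arctic
#' within-pool spread, 0.6 versus 1.2, reflecting specialists versus
#' generalists); 0 gives identical pools (the null configuration).
#'
#' @param contrast non-negative scalar scaling the between-pool contrast.
#' @return data.frame with one row per trait: `trait`, `group`, `type`,
#'   `arcticMean`, `borealMean`, `arcticSD`, `borealSD`, and list-columns
#'   `categories`, `arcticAlpha`, `borealAlpha` for the fuzzy traits.
#' @export
defaultTraitSpec <- function(contrast = 1) {
  q <- function(trait, group, gap, type = "quantitative")
    data.frame(trait = trait, group = group, type = type,
               arcticMean = 0, borealMean = gap * contrast,
               arcticSD = 1 - 0.4 * contrast, borealSD = 1 + 0.2 * contrast,
               stringsAsFactors = FALSE)
  spec <- rbind(
    q("depth_preference",     "habitat",  -0.8),
    q("temperature_affinity", "habitat",   2.0),
    q("age_maturity",         "life_history", 1.5),
    q("fecundity",            "life_history", 1.0),
    q("lifespan",             "life_history", 1.0),
    q("offspring_size",       "life_history", -0.5),
    q("max_length",           "body_size", 1.8),
    q("growth_rate",          "body_size", 1.5),
    q("trophic_level",        "feeding",   1.5),
    q("prey_size_range",      "feeding",   1.2, type = "ordinal"),
    q("links_fish_prey",      "foodweb",   1.8),
    q("links_bird_mammal_predators", "foodweb", 1.2),
    q("prey_diversity",       "foodweb",   1.5)
  )
  spec$categories <- vector("list", nrow(spec))
  spec$arcticAlpha <- vector("list", nrow(spec))
  spec$borealAlpha <- vector("list", nrow(spec))
  fuzzy <- data.frame(
    trait = c("diet", "habitat_zone"),
    group = c("feeding", "habitat"),
    type = "fuzzy", arcticMean = NA, borealMean = NA,
    arcticSD = NA, borealSD = NA, stringsAsFactors = FALSE)
  fuzzy$categories <- list(c("benthivore", "piscivore", "planktivore"),
                           c("benthic", "demersal", "pelagic"))
  base <- list(c(4, 4, 4), c(4, 4, 4))
  shiftA <- list(c(8, -3, -1), c(6, 0, -2))   # Arctic: benthivorous, benthic
  shiftB <- list(c(-2, 8, 0), c(-2, 4, 1))    # boreal: piscivorous, demersal
  fuzzy$arcticAlpha <- lapply(1:2, function(i)
    pmax(base[[i]] + contrast * shiftA[[i]], 0.2))
  fuzzy$borealAlpha <- lapply(1:2, function(i)
    pmax(base[[i]] + contrast * shiftB[[i]], 0.2))
  rbind(spec, fuzzy)
}

#' Configuration of the synthetic borealization survey
#'
#' Parameterizes the two-pool generator emulating a two-region bottom-trawl
#' survey of an Arctic shelf sea undergoing boreal intrusion: an Arctic
#' species pool of 20 small benthivorous specialists and a boreal pool of
#' 29 large piscivorous generalists (49 species in total), sampled yearly
#' 2004-2017 in an Arctic and a boreal region. Species presence is
#' Bernoulli in occupancy; boreal species' occupancy at Arctic stations
#' increases by `beta` per year from `awayOccupancy`; abundances of
#' present species are lognormal. All randomness flows from `seed`;
#' identical configurations give bit-identical surveys.
#'
#' @param nArcticSpecies,nBorealSpecies pool sizes (default 20 and 29).
#' @param years inclusive survey years (default `2004:2017`).
#' @param nStationsPerRegionYear stations sampled in each region each year
#'   (default 15).
#' @param beta yearly increase of boreal occupancy probability at Arctic
#'   stations (default 0.05; 0 gives stationary null dynamics).
#' @param homeOccupancy occupancy of a species in its home region
#'   (default 0.6).
#' @param awayOccupancy baseline occupancy outside the home region
#'   (default 0.08 for boreal species in the Arctic, and fixed at
#'   `arcticAwayOccupancy = 0.05` for Arctic species in the boreal
#'   region).
#' @param arcticAwayOccupancy see above.
#' @param arcticDecline yearly decrease of Arctic species' occupancy in
#'   their own region (local-extinction knob, default 0 = off).
#' @param meanlog,sdlog lognormal abundance parameters (default 1 and
#'   0.75).
#' @param traitSpec per-trait generating distributions, see
#'   [defaultTraitSpec()].
#' @param yearStationOverride optional named integer vector
#'   (`"<region>:<year>"` = station count) overriding
#'   `nStationsPerRegionYear`, e.g. to mimic under-sampled years.
#' @param seed integer random seed.
#' @return A validated configuration list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nArcticSpecies = 20L, nBorealSpecies = 29L,
                            years = 2004:2017,
                            nStationsPerRegionYear = 15L,
                            beta = 0.05,
                            homeOccupancy = 0.6,
                            awayOccupancy = 0.08,
                            arcticAwayOccupancy = 0.05,
                            arcticDecline = 0,
                            meanlog = 1, sdlog = 0.75,
                            traitSpec = defaultTraitSpec(),
                            yearStationOverride = NULL,
                            seed = 1L) {
  cfg <- list(nArcticSpecies = as.integer(nArcticSpecies),
              nBorealSpecies = as.integer(nBorealSpecies),
              years = as.integer(years),
              nStationsPerRegionYear = as.integer(nStationsPerRegionYear),
              beta = beta, homeOccupancy = homeOccupancy,
              awayOccupancy = awayOccupancy,
              arcticAwayOccupancy = arcticAwayOccupancy,
              arcticDecline = arcticDecline,
              meanlog = meanlog, sdlog = sdlog,
              traitSpec = traitSpec,
              yearStationOverride = yearStationOverride,
              seed = as.integer(seed))
  counts <- c(cfg$nArcticSpecies, cfg$nBorealSpecies,
              cfg$nStationsPerRegionYear, length(cfg$years))
  if (any(counts <= 0)) stop("all counts must be positive")
  probs <- c(beta, homeOccupancy, awayOccupancy, arcticAwayOccupancy,
             arcticDecline)
  if (any(probs < 0) || any(probs > 1))
    stop("rates and occupancies must lie in [0, 1]")
  class(cfg) <- "SyntheticConfig"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate the two-pool species trait table
#'
#' Draws the species pool from the configured pool-specific trait
#' distributions; see [defaultTraitSpec()] for what the pools emulate.
#'
#' @param cfg a [syntheticConfig()].
#' @return A list with `traits` (\linkS4class{TraitTable}) and `pool`
#'   (named character vector, `"arctic"` or `"boreal"` per species).
#' @export
generateSpeciesPool <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  nA <- cfg$nArcticSpecies; nB <- cfg$nBorealSpecies
  ids <- c(sprintf("arc_%02d", seq_len(nA)), sprintf("bor_%02d", seq_len(nB)))
  pool <- stats::setNames(rep(c("arctic", "boreal"), c(nA, nB)), ids)
  ts <- cfg$traitSpec
  if (all(ts$type == "fuzzy") ||
      (all(is.na(ts$arcticSD[ts$type != "fuzzy"])) &&
       all(is.na(ts$borealSD[ts$type != "fuzzy"]))))
    stop("degenerate trait spec: no non-fuzzy trait with a distribution")
  cols <- list()
  meta <- list()
  for (i in seq_len(nrow(ts))) {
    if (ts$type[i] == "fuzzy") {
      cats <- ts$categories[[i]]
      m <- rbind(
        t(vapply(seq_len(nA), function(k) rdirichlet1(ts$arcticAlpha[[i]]),
                 numeric(length(cats)))),
        t(vapply(seq_len(nB), function(k) rdirichlet1(ts$borealAlpha[[i]]),
                 numeric(length(cats)))))
      colnames(m) <- fuzzyColName(ts$trait[i], cats)
      cols[[i]] <- m
      meta[[i]] <- list(name = ts$trait[i], type = "fuzzy",
                        categories = cats, weight = 1)
    } else {
      x <- c(stats::rnorm(nA, ts$arcticMean[i], ts$arcticSD[i]),
             stats::rnorm(nB, ts$borealMean[i], ts$borealSD[i]))
      cols[[i]] <- matrix(x, ncol = 1, dimnames = list(NULL, ts$trait[i]))
      meta[[i]] <- list(name = ts$trait[i], type = ts$type[i], weight = 1)
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- ids
  list(traits = traitTable(vals, meta), pool = pool)
}

# occupancy probability of one species group at one region in year index t
# (t = 0 for the first survey year)
occupancyProb <- function(cfg, pool, region, t) {
  home <- cfg$homeOccupancy
  if (region == "arctic") {
    if (pool == "arctic") pmin(pmax(home - cfg$arcticDecline * t, 0), 1)
    else pmin(pmax(cfg$awayOccupancy + cfg$beta * t, 0), 1)
  } else {
    if (pool == "boreal") home else cfg$arcticAwayOccupancy
  }
}

#' Generate a two-region survey
#'
#' Places stations on a latitude/longitude grid split into an Arctic
#' (latitudes 76-80) and a boreal (70-74) band, draws species presence
#' Bernoulli in occupancy — with boreal species' occupancy at Arctic
#' stations increasing by `beta` per year — and gives present species
#' lognormal abundances. A station that draws no species is redrawn up to
#' 100 times, after which a minimal one-species station is emitted with a
#' warning.
#'
#' @param cfg a [syntheticConfig()].
#' @param pool result of [generateSpeciesPool()] (its `pool` element, or
#'   the whole list).
#' @return A \linkS4class{CommunitySurvey}.
#' @export
generateSurvey <- function(cfg, pool) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (is.list(pool)) pool <- pool$pool
  set.seed(cfg$seed + 1L)
  ids <- names(pool)
  years <- cfg$years
  regions <- c("arctic", "boreal")
  latBand <- list(arctic = c(76, 80), boreal = c(70, 74))
  rows <- list()
  meta <- list()
  k <- 0L
  for (yi in seq_along(years)) {
    for (rg in regions) {
      nSt <- cfg$nStationsPerRegionYear
      if (!is.null(cfg$yearStationOverride)) {
        key <- sprintf("%s:%d", rg, years[yi])
        if (key %in% names(cfg$yearStationOverride))
          nSt <- as.integer(cfg$yearStationOverride[[key]])
      }
      occ <- vapply(ids, function(s)
        occupancyProb(cfg, pool[[s]], rg, yi - 1L), numeric(1))
      # approximate 60 km station spacing on a grid spanning the band
      grid <- expand.grid(
        lat = seq(latBand[[rg]][1], latBand[[rg]][2], length.out = 8),
        lon = seq(20, 50, length.out = 12))
      pts <- grid[(seq_len(nSt) - 1L) %% nrow(grid) + 1L, ]
      for (st in seq_len(nSt)) {
        ab <- numeric(length(ids))
        for (attempt in seq_len(100L)) {
          present <- stats::rbinom(length(ids), 1L, occ) == 1L
          if (any(present)) break
        }
        if (!any(present)) {
          warning("station with no species after 100 redraws; forcing one species")
          present <- seq_along(ids) == which.max(occ)
        }
        ab[present] <- stats::rlnorm(sum(present), cfg$meanlog, cfg$sdlog)
        k <- k + 1L
        rows[[k]] <- ab
        meta[[k]] <- data.frame(
          station_id = sprintf("%s_%d_%03d", rg, years[yi], st),
          region = rg, year = years[yi],
          lat = pts$lat[st], lon = pts$lon[st],
          stringsAsFactors = FALSE)
      }
    }
  }
  abundance <- do.call(rbind, rows)
  stations <- do.call(rbind, meta)
  dimnames(abundance) <- list(stations$station_id, ids)
  communitySurvey(abundance, stations)
}

#' Ground-truth trend descriptors of a configuration
#'
#' Returns the constructed expectations implied by a configuration —
#' expected between-pool trait gaps, the boreal occupancy trajectory at
#' Arctic stations, and the qualitative trend direction of Arctic
#' functional variance — for use by validation harnesses.
#'
#' @param cfg a [syntheticConfig()].
#' @return A list: `traitGaps` (expected boreal - Arctic mean per
#'   non-fuzzy trait, in pooled-SD units), `borealOccupancyArctic`
#'   (per-year occupancy probability), `arcticTrend` (`"increasing"`,
#'   `"flat"`, or `"peak_then_decline"`).
#' @export
groundTruth <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  ts <- cfg$traitSpec
  qn <- ts$type != "fuzzy"
  pooledSD <- sqrt((ts$arcticSD[qn]^2 + ts$borealSD[qn]^2) / 2)
  gaps <- stats::setNames(
    (ts$borealMean[qn] - ts$arcticMean[qn]) / pooledSD, ts$trait[qn])
  t <- seq_along(cfg$years) - 1L
  occ <- pmin(pmax(cfg$awayOccupancy + cfg$beta * t, 0), 1)
  names(occ) <- cfg$years
  trend <- if (cfg$beta > 0 && cfg$arcticDecline > 0) "peak_then_decline"
           else if (cfg$beta > 0 && any(gaps != 0)) "increasing"
           else "flat"
  list(traitGaps = gaps, borealOccupancyArctic = occ, arcticTrend = trend)
}
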