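# Independent brute-force oracles: naive per-pair / per-element loops kept
# deliberately separate from the vectorized implementations they check.

# naive Gower: explicit per-pair, per-trait double loop on TraitTable slots
oracleGower <- function(tt) {
  vals <- traitValues(tt)
  tm <- traitMeta(tt)
  colTrait <- tt@columnTrait
  n <- nrow(vals)
  d <- matrix(0, n, n)
  ranges <- list()
  for (ti in seq_len(nrow(tm))) {
    if (tm$type[ti] == "fuzzy") next
    x <- vals[, which(colTrait == tm$trait[ti])]
    if (tm$type[ti] == "ordinal")
      x[!is.na(x)] <- rank(x[!is.na(x)], ties.method = "average")
    ranges[[tm$trait[ti]]] <- list(x = x, rng = diff(range(x, na.rm = TRUE)))
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (ti in seq_len(nrow(tm))) {
      w <- tm$weight[ti]
      if (tm$type[ti] == "fuzzy") {
        cols <- which(colTrait == tm$trait[ti])
        mi <- vals[i, cols]; mj <- vals[j, cols]
        if (anyNA(mi) || anyNA(mj)) next
        num <- num + w * sum(abs(mi - mj)) / 2
        den <- den + w
      } else {
        r <- ranges[[tm$trait[ti]]]
        xi <- r$x[i]; xj <- r$x[j]
        if (is.na(xi) || is.na(xj)) next
        delta <- if (r$rng > 0) abs(xi - xj) / r$rng else 0
        num <- num + w * delta
        den <- den + w
      }
    }
    d[i, j] <- num / den
  }
  d
}

# naive Rao's Q: explicit double loop
oracleRao <- function(p, d) {
  q <- 0
  for (i in seq_along(p)) for (j in seq_along(p))
    q <- q + p[i] * p[j] * d[i, j]
  q
}

# naive community-weighted mean / variance: per-species loops
oracleCWM <- function(p, x) {
  m <- 0
  for (i in seq_along(p)) m <- m + p[i] * x[i]
  m
}

oracleCWV <- function(p, x) {
  m <- oracleCWM(p, x)
  v <- 0
  for (i in seq_along(p)) v <- v + p[i] * (x[i] - m)^2
  v
}

# functional richness by explicit edge marking: walk every present leaf up
# to the root with parent pointers, count traversals, keep edges traversed
# by some but not all present leaves
oracleFRic <- function(present, tree) {
  merge <- tree@merge
  n <- length(tree@labels)
  nodeOf <- function(entry) if (entry < 0) -entry else n + entry
  parent <- integer(2 * n - 1)  # 0 = root
  edgeLen <- numeric(2 * n - 1)
  for (k in seq_len(n - 1)) {
    for (s in 1:2) {
      child <- nodeOf(merge[k, s])
      parent[child] <- n + k
      childH <- if (merge[k, s] < 0) 0 else tree@heights[merge[k, s]]
      edgeLen[child] <- tree@heights[k] - childH
    }
  }
  leaves <- which(tree@labels %in% present)
  traversed <- integer(2 * n - 1)
  for (lf in leaves) {
    node <- lf
    while (parent[node] != 0) {
      traversed[node] <- traversed[node] + 1
      node <- parent[node]
    }
  }
  sum(edgeLen[traversed >= 1 & traversed < length(leaves)])
}

# random mixed-type trait table on n species (quantitative + ordinal +
# one fuzzy trait with 3 categories), optional missingness
randomTraitTable <- function(n, missing = FALSE, weights = FALSE) {
  ids <- sprintf("sp%02d", seq_len(n))
  q1 <- stats::rnorm(n)
  q2 <- stats::runif(n, 0, 10)
  o1 <- sample(1:4, n, replace = TRUE)
  m <- t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(3, 1)
    g / sum(g)
  }, numeric(3)))
  if (missing) {
    q1[sample(n, 1)] <- NA
    o1[sample(n, 1)] <- NA
  }
  vals <- cbind(q1 = q1, q2 = q2, o1 = o1,
                fz_a = m[, 1], fz_b = m[, 2], fz_c = m[, 3])
  rownames(vals) <- ids
  w <- function(x) if (weights) stats::runif(1, 0.5, 3) else 1
  traitTable(vals, list(
    list(name = "q1", type = "quantitative", weight = w()),
    list(name = "q2", type = "quantitative", weight = w()),
    list(name = "o1", type = "ordinal", weight = w()),
    list(name = "fz", type = "fuzzy", categories = c("a", "b", "c"),
         weight = w())))
}

# random abundance row with a controllable number of present species
randomAbundance <- function(nSpecies, nPresent = NULL) {
  ab <- numeric(nSpecies)
  if (is.null(nPresent)) nPresent <- sample(seq_len(nSpecies), 1)
  idx <- sample(nSpecies, nPresent)
  ab[idx] <- stats::rlnorm(nPresent)
  ab
}

# tiny fully worked survey for pipeline tests: 3 species, 4 stations,
# 2 regions x 2 years
tinySurvey <- function() {
  ab <- rbind(a1 = c(2, 1, 0), a2 = c(1, 1, 1), b1 = c(0, 2, 3),
              b2 = c(1, 0, 4))
  colnames(ab) <- c("sp01", "sp02", "sp03")
  st <- data.frame(station_id = rownames(ab),
                   region = c("arctic", "arctic", "boreal", "boreal"),
                   year = c(2004L, 2005L, 2004L, 2005L),
                   lat = c(77, 78, 71, 72), lon = c(30, 31, 30, 31))
  communitySurvey(ab, st)
}

tinyTraits <- function() {
  vals <- cbind(size = c(1, 2, 4), depth = c(100, 50, 200),
                diet_benthivore = c(1, 0.5, 0), diet_piscivore = c(0, 0.5, 1))
  rownames(vals) <- c("sp01", "sp02", "sp03")
  traitTable(vals, list(
    list(name = "size", type = "quantitative"),
    list(name = "depth", type = "quantitative"),
    list(name = "diet", type = "fuzzy",
         categories = c("benthivore", "piscivore"))))
}
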