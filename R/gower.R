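#' @include AllClasses.R AllGenerics.R traitTable.R
NULL

#' Gower distance over mixed trait types
#'
#' Pairwise species dissimilarity accommodating quantitative, ordinal and
#' fuzzy-coded traits, scaled to `[0, 1]`:
#' \deqn{d_{ij} = \frac{\sum_t w_t \delta_t(i,j)}{\sum_t w_t}}
#' summing over traits `t` for which both species have values. For a
#' quantitative or ordinal trait, \eqn{\delta_t = |x_i - x_j| /
#' \mathrm{range}_t} (ordinal values are rank-coded first; a zero-range
#' trait contributes 0). For a fuzzy trait, \eqn{\delta_t = \frac12 \sum_c
#' |m_{ic} - m_{jc}|}, the total-variation distance between membership
#' vectors, and all category columns jointly carry the trait's single
#' weight. Missing values are handled by pairwise deletion: a trait missing
#' in either species is dropped from both numerator and denominator for
#' that pair.
#'
#' @param tt a \linkS4class{TraitTable}.
#' @return A \linkS4class{TraitDistance}.
#' @export
#' @examples
#' vals <- cbind(size = c(a = 1, b = 2, c = 4))
#' d <- gowerDistance(traitTable(vals, list(list(name = "size",
#'                                               type = "quantitative"))))
#' distanceMatrix(d)
gowerDistance <- function(tt) {
  stopifnot(is(tt, "TraitTable"))
  vals <- tt@values
  tm <- tt@traitMeta
  n <- nrow(vals)
  if (n < 1) stop("empty trait table")

  # per-trait dissimilarity stacks: delta[[t]] is n x n, NA where undefined
  deltas <- vector("list", nrow(tm))
  for (i in seq_len(nrow(tm))) {
    cols <- which(tt@columnTrait == tm$trait[i])
    if (tm$type[i] == "fuzzy") {
      m <- vals[, cols, drop = FALSE]
      ok <- stats::complete.cases(m)
      m[!ok, ] <- NA
      # total variation: 0.5 * sum_c |m_ic - m_jc|
      dd <- matrix(0, n, n)
      for (cc in seq_along(cols))
        dd <- dd + abs(outer(m[, cc], m[, cc], "-"))
      deltas[[i]] <- dd / 2
    } else {
      x <- vals[, cols]
      if (tm$type[i] == "ordinal")
        x[!is.na(x)] <- rank(x[!is.na(x)], ties.method = "average")
      rng <- diff(range(x, na.rm = TRUE))
      dd <- abs(outer(x, x, "-"))
      if (is.finite(rng) && rng > 0) dd <- dd / rng else dd[!is.na(dd)] <- 0
      deltas[[i]] <- dd
    }
  }

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (i in seq_len(nrow(tm))) {
    dd <- deltas[[i]]
    ok <- !is.na(dd)
    num[ok] <- num[ok] + tm$weight[i] * dd[ok]
    den[ok] <- den[ok] + tm$weight[i]
  }
  if (any(den == 0 & upper.tri(den))) {
    bad <- which(den == 0 & upper.tri(den), arr.ind = TRUE)[1, ]
    stop(sprintf("species '%s' and '%s' share no non-missing trait",
                 tt@speciesIds[bad[1]], tt@speciesIds[bad[2]]))
  }
  d <- num / den
  diag(d) <- 0
  d <- pmin(pmax((d + t(d)) / 2, 0), 1)  # enforce symmetry/bounds against fp noise
  dimnames(d) <- list(tt@speciesIds, tt@speciesIds)
  new("TraitDistance", d = d, speciesIds = tt@speciesIds)
}

#' Write / read a distance matrix as square CSV
#'
#' The CSV carries a `species_id` header column and one column per species.
#'
#' @param x a \linkS4class{TraitDistance}.
#' @param path CSV path.
#' @return `writeDistanceCSV` invisibly returns `path`; `readDistanceCSV`
#'   returns a \linkS4class{TraitDistance}.
#' @export
writeDistanceCSV <- function(x, path) {
  df <- data.frame(species_id = x@speciesIds, x@d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDistanceCSV
#' @export
readDistanceCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species_id
  new("TraitDistance", d = m, speciesIds = df$species_id)
}

#' Coerce a TraitDistance to 'dist'
#'
#' @param m a \linkS4class{TraitDistance}.
#' @return A base [stats::dist] object.
#' @export
asDist <- function(m) stats::as.dist(m@d)
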