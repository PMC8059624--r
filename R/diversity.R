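#' @include AllClasses.R AllGenerics.R upgma.R
NULL

#' Relative abundances of a station
#'
#' Converts a station's abundance vector to the probability vector
#' \eqn{p_i = a_i / \sum_j a_j} over the species present (positive
#' abundance); zero-abundance species are dropped.
#'
#' @param row named non-negative numeric vector with at least one positive
#'   entry.
#' @return Named probability vector over present species, summing to 1.
#' @export
relativeAbundance <- function(row) {
  if (any(row < 0)) stop("negative abundance")
  total <- sum(row)
  if (total <= 0) stop("all-zero station: no present species")
  p <- row[row > 0]
  p / sum(p)
}

#' Taxonomic diversity of a station
#'
#' `speciesRichness()` counts species with strictly positive abundance.
#' `shannonIndex()` is the Shannon entropy \eqn{H = -\sum_i p_i \log p_i}
#' (natural log by default). `pielouEvenness()` is the regularized evenness
#' \eqn{J = H / (\log S + 1)}: note the `+ 1` in the denominator, which
#' differs from the classical Pielou \eqn{H/\log S} and makes the
#' single-species value 0 rather than 0/0.
#'
#' @param row non-negative abundance vector with at least one positive
#'   entry.
#' @param base logarithm base (default `exp(1)`, the convention of the
#'   ecological toolchain; the same base is used in the evenness
#'   denominator).
#' @return A single number.
#' @name taxonomicDiversity
#' @export
speciesRichness <- function(row) {
  if (any(row < 0)) stop("negative abundance")
  sum(row > 0)
}

#' @rdname taxonomicDiversity
#' @export
shannonIndex <- function(row, base = exp(1)) {
  p <- relativeAbundance(row)
  -sum(p * log(p, base = base))
}

#' @rdname taxonomicDiversity
#' @export
pielouEvenness <- function(row, base = exp(1)) {
  s <- speciesRichness(row)
  shannonIndex(row, base = base) / (log(s, base = base) + 1)
}

#' Rao's quadratic entropy (functional dispersion)
#'
#' \deqn{Q = \sum_i \sum_j p_i p_j d_{ij}}
#' the abundance-weighted expected functional distance between two randomly
#' drawn individuals (full double-sum convention, no division by 2). `p`
#' is matched to the distance matrix by names when available.
#'
#' @param p probability vector over present species (sums to 1).
#' @param d a \linkS4class{TraitDistance} over a superset of those species,
#'   or a plain square matrix aligned with `p`.
#' @return Non-negative dispersion in Gower units; 0 for a single species.
#' @export
raoQ <- function(p, d) {
  dm <- if (is(d, "TraitDistance")) d@d else as.matrix(d)
  if (!is.null(names(p)) && !is.null(rownames(dm))) {
    unknown <- setdiff(names(p), rownames(dm))
    if (length(unknown))
      stop("species absent from distance matrix: ",
           paste(unknown, collapse = ", "))
    dm <- dm[names(p), names(p), drop = FALSE]
  } else if (length(p) != nrow(dm)) {
    stop("length of p does not match distance matrix dimension")
  }
  drop(crossprod(p, dm %*% p))
}

#' Per-station diversity table
#'
#' Computes, for every station of a survey, species richness `S`, Shannon
#' entropy `H`, evenness `J`, dendrogram functional richness `FRic` and
#' Rao's Q functional dispersion `Q`, all on the full-pool Gower distance
#' and UPGMA dendrogram (computed once, so stations are comparable).
#' Stations with zero total abundance are dropped with a message reporting
#' the count.
#'
#' @param survey a \linkS4class{CommunitySurvey}.
#' @param tt the \linkS4class{TraitTable} of the species pool (must cover
#'   all survey species).
#' @param base logarithm base for `H` and `J`.
#' @return A data.frame with one row per station: `station_id`, `region`,
#'   `year`, `lat`, `lon`, `S`, `H`, `J`, `FRic`, `Q`.
#' @seealso [regionalMeans()] for per-region-per-year pooling.
#' @export
computeDiversity <- function(survey, tt, base = exp(1)) {
  stopifnot(is(survey, "CommunitySurvey"), is(tt, "TraitTable"))
  A <- communityMatrix(survey)        # stations x species
  unknown <- setdiff(colnames(A), tt@speciesIds)
  if (length(unknown))
    stop("survey species missing from trait table: ",
         paste(unknown, collapse = ", "))
  keep <- rowSums(A) > 0
  if (!all(keep)) {
    message(sum(!keep), " station(s) with zero total abundance dropped")
    A <- A[keep, , drop = FALSE]
  }
  d <- gowerDistance(tt)
  tree <- upgmaTree(d)
  meta <- stationData(survey)
  meta <- meta[match(rownames(A), meta$station_id), ]
  out <- meta
  out$S <- apply(A, 1, speciesRichness)
  out$H <- apply(A, 1, shannonIndex, base = base)
  out$J <- apply(A, 1, pielouEvenness, base = base)
  out$FRic <- apply(A, 1, function(row)
    functionalRichness(colnames(A)[row > 0], tree))
  out$Q <- apply(A, 1, function(row) raoQ(relativeAbundance(row), d))
  rownames(out) <- NULL
  out
}

#' Regional yearly means of station-level values
#'
#' Pools all stations of each region and year and averages each value
#' column — the aggregation behind the regional time-trend panels.
#'
#' @param table data.frame with `region` and `year` columns plus numeric
#'   value columns.
#' @param cols character, value columns to average (default: all numeric
#'   columns other than `year`, `lat`, `lon`).
#' @return data.frame keyed by `region`, `year`, sorted, with the mean of
#'   each value column and `n_stations`.
#' @export
regionalMeans <- function(table, cols = NULL) {
  if (is.null(cols)) {
    num <- vapply(table, is.numeric, logical(1))
    cols <- setdiff(names(table)[num], c("year", "lat", "lon"))
  }
  agg <- stats::aggregate(table[cols],
                          by = list(region = table$region, year = table$year),
                          FUN = mean)
  nst <- stats::aggregate(list(n_stations = seq_len(nrow(table))),
                          by = list(region = table$region, year = table$year),
                          FUN = length)
  out <- merge(agg, nst, by = c("region", "year"))
  out[order(out$region, out$year), , drop = FALSE]
}
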