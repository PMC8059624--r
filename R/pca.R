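#' @include AllClasses.R AllGenerics.R cwv.R diversity.R
NULL

#' PCA of a community-weighted variance (or mean) matrix
#'
#' Centers the station x expanded-trait matrix column-wise (optionally also
#' scaling columns to unit variance — off by default, since the trait
#' columns are already commensurate after species-level standardization)
#' and eigendecomposes its covariance. Scores are the projections of the
#' stations, loadings the orthonormal eigenvectors, and the explained
#' fractions are \eqn{\lambda_k / \sum_k \lambda_k}. When a dispersion
#' vector is supplied, the sign of PC1 (scores and loading column jointly)
#' is oriented so that PC1 scores correlate non-negatively with it —
#' functional variance PC1 is reported as a positive indicator of
#' functional dispersion.
#'
#' @param V numeric matrix, stations x expanded trait columns (>= 2 rows).
#' @param scaleColumns scale columns to unit variance before the
#'   decomposition (default `FALSE`).
#' @param dispersion optional per-station dispersion values (Rao's Q) used
#'   to fix the PC1 sign.
#' @return A \linkS4class{TraitPCA}.
#' @export
cwvPCA <- function(V, scaleColumns = FALSE, dispersion = NULL) {
  V <- as.matrix(V)
  if (nrow(V) < 2) stop("PCA needs at least 2 stations")
  if (ncol(V) < 2) stop("PCA needs at least 2 trait columns")
  sds <- apply(V, 2, stats::sd)
  if (all(sds < 1e-14)) stop("no variance to decompose")
  if (scaleColumns && any(sds == 0))
    stop("cannot unit-scale constant column(s): ",
         paste(colnames(V)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(V, center = TRUE, scale. = scaleColumns)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  loadings <- pc$rotation
  flipped <- FALSE
  if (!is.null(dispersion)) {
    if (length(dispersion) != nrow(V))
      stop("dispersion must have one value per station")
    r <- suppressWarnings(stats::cor(scores[, 1], dispersion))
    if (is.finite(r) && r < 0) {
      scores[, 1] <- -scores[, 1]
      loadings[, 1] <- -loadings[, 1]
      flipped <- TRUE
    }
  }
  scl <- if (isTRUE(scaleColumns)) pc$scale else rep(1, ncol(V))
  names(scl) <- colnames(V)
  new("TraitPCA", scores = scores, loadings = loadings, explained = expl,
      center = pc$center, scale = scl, signFlipped = flipped)
}

#' Squared Pearson correlation between PC1 scores and dispersion
#'
#' @param scores per-station PC1 scores.
#' @param q per-station Rao's Q values, aligned with `scores`.
#' @return r-squared in `[0, 1]`.
#' @export
pc1DispersionR2 <- function(scores, q) {
  if (length(scores) != length(q)) stop("misaligned station vectors")
  if (stats::sd(scores) == 0 || stats::sd(q) == 0)
    stop("zero variance in scores or dispersion")
  stats::cor(scores, q)^2
}

#' Functional variance PC1 pipeline
#'
#' Convenience composition of the full multi-trait functional variance
#' analysis: expand and standardize the traits, build the station x trait
#' CWV matrix, run the PCA (PC1 sign oriented by Rao's Q), and summarize.
#' Returns per-station functional variance PC1 scores, their per-region
#' yearly means, the trait loading ranking that characterizes PC1, and the
#' squared correlation between PC1 and functional dispersion.
#'
#' @param survey a \linkS4class{CommunitySurvey}.
#' @param tt the species pool \linkS4class{TraitTable}.
#' @param scaleColumns passed to [cwvPCA()].
#' @return A list with elements `pca` (\linkS4class{TraitPCA}), `stations`
#'   (data.frame: station metadata + `PC1` + `Q`), `regional` (data.frame
#'   of per-region-per-year mean `PC1` and `Q`), `loadingRanking`
#'   (data.frame of expanded traits ordered by `|loading|` on PC1) and
#'   `r2` (PC1 vs Q).
#' @export
functionalVariancePC1 <- function(survey, tt, scaleColumns = FALSE) {
  stopifnot(is(survey, "CommunitySurvey"), is(tt, "TraitTable"))
  traits <- expandTraits(tt)
  V <- cwvMatrix(survey, traits)
  d <- gowerDistance(tt)
  A <- communityMatrix(survey)
  q <- apply(A, 1, function(row) raoQ(relativeAbundance(row), d))
  pca <- cwvPCA(V, scaleColumns = scaleColumns, dispersion = q)
  meta <- stationData(survey)
  stations <- cbind(meta, PC1 = pca@scores[, 1], Q = q)
  rownames(stations) <- NULL
  regional <- regionalMeans(stations, cols = c("PC1", "Q"))
  l1 <- pca@loadings[, 1]
  ranking <- data.frame(column = rownames(pca@loadings), loading = l1,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-abs(ranking$loading)), ]
  rownames(ranking) <- NULL
  list(pca = pca, stations = stations, regional = regional,
       loadingRanking = ranking, r2 = pc1DispersionR2(stations$PC1, q))
}
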