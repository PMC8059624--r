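#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Species-by-trait table with per-trait metadata
#'
#' Holds raw trait values for a species pool together with the metadata
#' needed to interpret them: each trait is quantitative, ordinal, or fuzzy
#' (a categorical trait coded as graded category memberships that sum to one
#' per species). Fuzzy traits occupy one column per category in `values`;
#' all category columns of one fuzzy trait jointly carry that trait's single
#' weight in downstream distance computations.
#'
#' @slot values numeric matrix, species x value-columns (fuzzy traits
#'   contribute one column per category); `NA` marks a missing value.
#' @slot speciesIds character, ordered species identifiers (rownames of
#'   `values`).
#' @slot traitMeta data.frame with one row per *trait* (not per column):
#'   `trait`, `type` (one of `"quantitative"`, `"ordinal"`, `"fuzzy"`),
#'   `weight` (strictly positive), and list-column `categories` (character
#'   vector of category labels for fuzzy traits, `NA` otherwise).
#' @slot columnTrait character, parent trait of each column of `values`.
#'
#' @export
setClass("TraitTable",
  representation(
    values = "matrix",
    speciesIds = "character",
    traitMeta = "data.frame",
    columnTrait = "character"
  )
)

setValidity("TraitTable", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != length(object@speciesIds))
    msg <- c(msg, "number of rows of 'values' must equal length of 'speciesIds'")
  if (anyDuplicated(object@speciesIds))
    msg <- c(msg, "duplicated species ids")
  if (ncol(v) != length(object@columnTrait))
    msg <- c(msg, "'columnTrait' must name the parent trait of every column")
  tm <- object@traitMeta
  need <- c("trait", "type", "weight")
  if (!all(need %in% names(tm)))
    msg <- c(msg, "traitMeta must have columns trait, type, weight")
  else {
    if (!all(tm$type %in% c("quantitative", "ordinal", "fuzzy")))
      msg <- c(msg, "trait type must be quantitative, ordinal or fuzzy")
    if (any(!is.finite(tm$weight)) || any(tm$weight <= 0))
      msg <- c(msg, "trait weights must be strictly positive")
    if (!all(object@columnTrait %in% tm$trait))
      msg <- c(msg, "every column must map to a declared trait")
    # fuzzy memberships: non-negative, sum to 1 per species (NA rows allowed)
    for (tr in tm$trait[tm$type == "fuzzy"]) {
      cols <- which(object@columnTrait == tr)
      if (length(cols) < 2) {
        msg <- c(msg, sprintf("fuzzy trait '%s' needs >= 2 category columns", tr))
        next
      }
      m <- v[, cols, drop = FALSE]
      complete <- stats::complete.cases(m)
      if (any(m[complete, ] < 0))
        msg <- c(msg, sprintf("fuzzy trait '%s' has negative memberships", tr))
      s <- rowSums(m[complete, , drop = FALSE])
      if (any(abs(s - 1) > 1e-6))
        msg <- c(msg, sprintf(
          "fuzzy trait '%s' memberships do not sum to 1 (max |sum-1| = %.3g)",
          tr, max(abs(s - 1))))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Expanded and standardized trait matrix
#'
#' Species-level trait matrix ready for community-weighted statistics:
#' quantitative and ordinal traits are z-scored over the full species pool
#' (one column each), fuzzy category memberships are carried unchanged (one
#' column per category; already commensurate on `[0, 1]`). The scaling
#' parameters are frozen so every station/year is standardized identically.
#'
#' @slot values numeric matrix, species x expanded columns.
#' @slot columnMap data.frame per expanded column: `column`, `trait`,
#'   `category` (`NA` for non-fuzzy), `type`, `weight`.
#' @slot scaling data.frame per expanded column: `column`, `center`, `scale`
#'   (fuzzy columns have center 0, scale 1).
#'
#' @export
setClass("ExpandedTraits",
  representation(
    values = "matrix",
    columnMap = "data.frame",
    scaling = "data.frame"
  )
)

setValidity("ExpandedTraits", function(object) {
  msg <- character()
  if (ncol(object@values) != nrow(object@columnMap))
    msg <- c(msg, "columnMap must describe every column")
  if (ncol(object@values) != nrow(object@scaling))
    msg <- c(msg, "scaling must describe every column")
  if (length(msg)) msg else TRUE
})

#' Pairwise functional distance matrix
#'
#' Square symmetric matrix of Gower distances between species, in `[0, 1]`.
#'
#' @slot d numeric matrix with zero diagonal.
#' @slot speciesIds character.
#'
#' @export
setClass("TraitDistance",
  representation(d = "matrix", speciesIds = "character")
)

setValidity("TraitDistance", function(object) {
  d <- object@d
  msg <- character()
  if (nrow(d) != ncol(d)) msg <- c(msg, "distance matrix must be square")
  if (nrow(d) != length(object@speciesIds))
    msg <- c(msg, "speciesIds must label every row")
  if (any(!is.finite(d))) msg <- c(msg, "non-finite distances")
  else {
    if (max(abs(d - t(d))) > 1e-12) msg <- c(msg, "distance matrix not symmetric")
    if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "nonzero diagonal")
    if (min(d) < -1e-12 || max(d) > 1 + 1e-12)
      msg <- c(msg, "distances must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Ultrametric trait dendrogram
#'
#' Rooted binary merge tree over the species pool produced by UPGMA
#' (average linkage) on functional distances. Node heights are half the
#' linkage distance, so the leaf-to-leaf cophenetic distance through an
#' ancestor equals the linkage distance at which the two clades merged.
#'
#' @slot merge integer matrix (n-1 x 2), `hclust` convention: negative
#'   entries are leaves, positive entries earlier merges.
#' @slot heights numeric, node height of each merge (non-decreasing).
#' @slot labels character, leaf labels (species ids).
#'
#' @export
setClass("TraitDendrogram",
  representation(merge = "matrix", heights = "numeric", labels = "character")
)

setValidity("TraitDendrogram", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L)
    msg <- c(msg, "merge must have n-1 rows")
  if (length(object@heights) != n - 1L)
    msg <- c(msg, "one height per merge")
  if (any(object@heights < -1e-12))
    msg <- c(msg, "negative node height")
  if (is.unsorted(object@heights + 1e-12))
    msg <- c(msg, "heights must be non-decreasing toward the root")
  if (length(msg)) msg else TRUE
})

#' Two-region community survey
#'
#' Station x species abundance data with per-station metadata, stored as a
#' \linkS4class{SummarizedExperiment} with species as rows (features) and
#' stations as columns (samples); `colData` carries `region`, `year`,
#' `lat`, `lon`. Use [communityMatrix()] for the stations x species
#' orientation used by the community-weighted statistics.
#'
#' @export
setClass("CommunitySurvey", contains = "SummarizedExperiment")

setValidity("CommunitySurvey", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assay(object)
  cd <- SummarizedExperiment::colData(object)
  need <- c("region", "year", "lat", "lon")
  if (!all(need %in% names(cd)))
    msg <- c(msg, "colData must contain region, year, lat, lon")
  if (any(!is.finite(a)) || any(a < 0))
    msg <- c(msg, "abundances must be finite and non-negative")
  else if (ncol(a) > 0 && any(colSums(a) <= 0))
    msg <- c(msg, "every retained station needs at least one positive abundance")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    msg <- c(msg, "species and station ids are required as dimnames")
  if (length(msg)) msg else TRUE
})

#' PCA of a community-weighted trait matrix
#'
#' Principal components of the station x expanded-trait CWV (or CWM) matrix.
#' The first component of the CWV PCA is the *functional variance PC1*; its
#' sign is oriented so that PC1 scores correlate non-negatively with Rao's Q
#' when dispersion values are supplied.
#'
#' @slot scores numeric matrix, stations x components.
#' @slot loadings numeric matrix, expanded traits x components (orthonormal
#'   columns).
#' @slot explained numeric, per-component fraction of variance (sums to 1).
#' @slot center,scale numeric, column centering/scaling applied before the
#'   eigendecomposition (`scale` is all ones when column scaling is off).
#' @slot signFlipped logical, whether the PC1 sign convention flipped the
#'   raw eigenvector.
#'
#' @export
setClass("TraitPCA",
  representation(
    scores = "matrix",
    loadings = "matrix",
    explained = "numeric",
    center = "numeric",
    scale = "numeric",
    signFlipped = "logical"
  )
)

setValidity("TraitPCA", function(object) {
  msg <- character()
  if (ncol(object@scores) != ncol(object@loadings))
    msg <- c(msg, "scores and loadings must agree on component count")
  if (length(object@explained) != ncol(object@scores))
    msg <- c(msg, "one explained fraction per component")
  if (abs(sum(object@explained) - 1) > 1e-10)
    msg <- c(msg, "explained fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Mixed-model fit of functional dispersion
#'
#' Result of regressing Rao's Q on species richness, evenness and
#' functional richness with a random year intercept (optionally with an
#' exponential spatial correlation structure nested by region).
#'
#' @slot coefficients data.frame: `term`, `estimate`, `se`, `z`, `p`.
#' @slot r2 squared correlation between fitted and observed responses.
#' @slot yearVariance random-intercept (year) variance; `NA` when the fit
#'   degraded to a fixed-intercept model.
#' @slot residVariance residual variance.
#' @slot scope `"all"` or a region label.
#' @slot spatial logical, whether the spatial correlation structure was on.
#' @slot nStations,nYears integer problem sizes.
#' @slot fitted,observed numeric vectors (fitted + residuals reproduce
#'   observed).
#'
#' @export
setClass("DispersionFit",
  representation(
    coefficients = "data.frame",
    r2 = "numeric",
    yearVariance = "numeric",
    residVariance = "numeric",
    scope = "character",
    spatial = "logical",
    nStations = "integer",
    nYears = "integer",
    fitted = "numeric",
    observed = "numeric"
  )
)

setValidity("DispersionFit", function(object) {
  msg <- character()
  if (length(object@r2) != 1 || object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(object@fitted) != length(object@observed))
    msg <- c(msg, "fitted and observed lengths differ")
  if (length(msg)) msg else TRUE
})
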