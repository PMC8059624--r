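#' @include AllClasses.R AllGenerics.R survey.R traitTable.R
NULL

#' Community-weighted mean and variance of trait values
#'
#' For relative abundances \eqn{p_i} and species trait values
#' \eqn{x_{i,t}}:
#' \deqn{CWM_t = \sum_i p_i x_{i,t}, \qquad
#'       CWV_t = \sum_i p_i (x_{i,t} - CWM_t)^2
#'             = \sum_i p_i x_{i,t}^2 - CWM_t^2.}
#' The variance uses the population convention (relative abundances are
#' weights, not sample counts, so no small-sample correction applies). A
#' single-species community has zero CWV for every trait.
#'
#' @param p probability vector over present species (sums to 1).
#' @param X numeric matrix of trait values, rows aligned with `p` (e.g.
#'   the present-species rows of an \linkS4class{ExpandedTraits} matrix),
#'   or a vector for a single trait.
#' @return Named numeric vector, one entry per trait column.
#' @name communityWeighted
#' @export
cwm <- function(p, X) {
  X <- as.matrix(X)
  if (length(p) != nrow(X)) stop("p and trait rows are misaligned")
  drop(crossprod(p, X))
}

#' @rdname communityWeighted
#' @export
cwv <- function(p, X) {
  X <- as.matrix(X)
  if (length(p) != nrow(X)) stop("p and trait rows are misaligned")
  m <- drop(crossprod(p, X))
  v <- drop(crossprod(p, X^2)) - m^2
  pmax(v, 0)  # clip fp negatives of exactly-zero variances
}

# shared station x expanded-trait machinery
communityWeightedMatrix <- function(survey, traits, statistic = c("cwv", "cwm")) {
  statistic <- match.arg(statistic)
  stopifnot(is(survey, "CommunitySurvey"), is(traits, "ExpandedTraits"))
  A <- communityMatrix(survey)
  unknown <- setdiff(colnames(A), speciesIds(traits))
  if (length(unknown))
    stop("survey species missing from trait matrix: ",
         paste(unknown, collapse = ", "))
  X <- traits@values[colnames(A), , drop = FALSE]
  X0 <- X
  X0[is.na(X0)] <- 0
  hasVal <- !is.na(X) + 0
  # per-station renormalization over species with a value for each column
  P <- A / rowSums(A)
  denom <- P %*% hasVal
  if (any(denom == 0))
    stop("some station has no present species with a value for some trait column")
  M <- (P %*% X0) / denom
  if (statistic == "cwm") return(M)
  V <- (P %*% (X0^2)) / denom - M^2
  pmax(V, 0)
}

#' Station x trait matrices of community-weighted statistics
#'
#' Applies [cwm()] / [cwv()] across all stations of a survey and all
#' expanded trait columns, using each station's relative abundances.
#' Missing trait values are handled by renormalizing the abundance weights
#' over the species that carry a value for that column.
#'
#' @param survey a \linkS4class{CommunitySurvey}.
#' @param traits an \linkS4class{ExpandedTraits} covering the survey
#'   species.
#' @return Numeric matrix, stations x expanded trait columns.
#' @name cwMatrices
#' @export
cwvMatrix <- function(survey, traits)
  communityWeightedMatrix(survey, traits, "cwv")

#' @rdname cwMatrices
#' @export
cwmMatrix <- function(survey, traits)
  communityWeightedMatrix(survey, traits, "cwm")
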