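#' @include AllClasses.R
NULL

#' Theil-Sen slope
#'
#' Median of all pairwise slopes — a robust trend estimate for short
#' regional yearly-mean series.
#'
#' @param x,y numeric vectors (e.g. years and yearly means).
#' @return The median pairwise slope.
#' @export
theilSenSlope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    slopes <- c(slopes, (dy / dx)[dx != 0])
  }
  stats::median(slopes)
}

#' Regional gap trajectory and half-life
#'
#' For two aligned yearly-mean series (Arctic and boreal), `regionGap()`
#' returns the absolute between-region gap per year; `gapHalfLife()`
#' returns the first year index (1-based) at which the gap falls to half
#' its first-year value or less (`Inf` if it never does); and
#' `finalGapFraction()` the final-year gap as a fraction of the first-year
#' gap — the convergence diagnostics used to compare how early the
#' community-weighted variance signal moves relative to the
#' community-weighted mean.
#'
#' @param arctic,boreal aligned numeric yearly-mean series.
#' @return See above.
#' @name gapDiagnostics
#' @export
regionGap <- function(arctic, boreal) {
  stopifnot(length(arctic) == length(boreal))
  abs(arctic - boreal)
}

#' @rdname gapDiagnostics
#' @export
gapHalfLife <- function(arctic, boreal) {
  gap <- regionGap(arctic, boreal)
  if (gap[1] == 0) return(1)
  hit <- which(gap <= gap[1] / 2)
  if (length(hit)) hit[1] else Inf
}

#' @rdname gapDiagnostics
#' @export
finalGapFraction <- function(arctic, boreal) {
  gap <- regionGap(arctic, boreal)
  if (gap[1] == 0) stop("zero initial gap")
  gap[length(gap)] / gap[1]
}

# yearly-mean series of one column for one region, sorted by year
regionSeries <- function(regional, region, col) {
  sub <- regional[regional$region == region, ]
  sub <- sub[order(sub$year), ]
  stats::setNames(sub[[col]], sub$year)
}
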