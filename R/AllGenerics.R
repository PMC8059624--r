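#' @include AllClasses.R
NULL

#' Accessors for traitvar objects
#'
#' Small accessor family: `speciesIds()` returns the ordered species
#' identifiers of an object; `traitMeta()` the per-trait metadata;
#' `traitValues()` the raw or expanded species x column matrix;
#' `columnMap()` the expanded-column bookkeeping; `distanceMatrix()` the
#' square Gower matrix; `communityMatrix()` the stations x species
#' abundance matrix; `stationData()` the per-station metadata;
#' `pcaScores()`, `pcaLoadings()` and `explainedVariance()` the PCA pieces;
#' `totalBranchLength()` the summed edge length of a dendrogram.
#'
#' @param x a traitvar object.
#' @return The component named by the accessor.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname accessors
#' @export
setGeneric("traitMeta", function(x) standardGeneric("traitMeta"))

#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' @rdname accessors
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))

#' @rdname accessors
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname accessors
#' @export
setGeneric("communityMatrix", function(x) standardGeneric("communityMatrix"))

#' @rdname accessors
#' @export
setGeneric("stationData", function(x) standardGeneric("stationData"))

#' @rdname accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("totalBranchLength", function(x) standardGeneric("totalBranchLength"))

setMethod("speciesIds", "TraitTable", function(x) x@speciesIds)
setMethod("speciesIds", "ExpandedTraits", function(x) rownames(x@values))
setMethod("speciesIds", "TraitDistance", function(x) x@speciesIds)
setMethod("speciesIds", "TraitDendrogram", function(x) x@labels)
setMethod("speciesIds", "CommunitySurvey", function(x) rownames(x))

setMethod("traitMeta", "TraitTable", function(x) x@traitMeta)
setMethod("traitValues", "TraitTable", function(x) x@values)
setMethod("traitValues", "ExpandedTraits", function(x) x@values)
setMethod("columnMap", "ExpandedTraits", function(x) x@columnMap)
setMethod("distanceMatrix", "TraitDistance", function(x) x@d)

setMethod("communityMatrix", "CommunitySurvey", function(x)
  t(SummarizedExperiment::assay(x, "abundance")))
setMethod("stationData", "CommunitySurvey", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  df$station_id <- colnames(x)
  df[, c("station_id", "region", "year", "lat", "lon")]
})

setMethod("pcaScores", "TraitPCA", function(x) x@scores)
setMethod("pcaLoadings", "TraitPCA", function(x) x@loadings)
setMethod("explainedVariance", "TraitPCA", function(x) x@explained)

setMethod("show", "TraitTable", function(object) {
  tm <- object@traitMeta
  cat(sprintf("TraitTable: %d species, %d traits (%d quantitative, %d ordinal, %d fuzzy), %d columns\n",
    length(object@speciesIds), nrow(tm),
    sum(tm$type == "quantitative"), sum(tm$type == "ordinal"),
    sum(tm$type == "fuzzy"), ncol(object@values)))
})

setMethod("show", "ExpandedTraits", function(object) {
  cat(sprintf("ExpandedTraits: %d species x %d standardized columns\n",
    nrow(object@values), ncol(object@values)))
})

setMethod("show", "TraitDistance", function(object) {
  d <- object@d[upper.tri(object@d)]
  cat(sprintf("TraitDistance: %d species; Gower d in [%.3f, %.3f]\n",
    length(object@speciesIds),
    if (length(d)) min(d) else 0, if (length(d)) max(d) else 0))
})

setMethod("show", "TraitDendrogram", function(object) {
  cat(sprintf("TraitDendrogram (UPGMA): %d leaves, root height %.4f, total branch length %.4f\n",
    length(object@labels), max(object@heights), totalBranchLength(object)))
})

setMethod("show", "CommunitySurvey", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("CommunitySurvey: %d species x %d stations; regions: %s; years %s-%s\n",
    nrow(object), ncol(object),
    paste(sort(unique(cd$region)), collapse = ", "),
    min(cd$year), max(cd$year)))
})

setMethod("show", "TraitPCA", function(object) {
  cat(sprintf("TraitPCA: %d stations x %d components; PC1 explains %.1f%%%s\n",
    nrow(object@scores), ncol(object@scores), 100 * object@explained[1],
    if (object@signFlipped) " (PC1 sign flipped to align with dispersion)" else ""))
})

setMethod("show", "DispersionFit", function(object) {
  cat(sprintf("DispersionFit [%s]%s: n = %d stations, %d years, r2 = %.3f\n",
    object@scope, if (object@spatial) " + spatial corExp" else "",
    object@nStations, object@nYears, object@r2))
  print(object@coefficients, row.names = FALSE, digits = 4)
})
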