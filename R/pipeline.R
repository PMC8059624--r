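#' @include AllClasses.R AllGenerics.R pca.R trends.R synthetic.R
NULL

#' Pipeline run configuration
#'
#' Bundles the input paths, column conventions and switches of a full
#' analysis run. All randomness in a run flows from `seed`.
#'
#' @param abundance wide abundance CSV (see [readCommunityCSV()]).
#' @param traits trait CSV and `traitMeta` YAML (see [readTraitTable()]).
#' @param traitMeta see above.
#' @param outDir output directory (created if absent).
#' @param scaleColumns unit-scale CWV columns before the PCA.
#' @param spatial switch on the spatial correlation structure in the
#'   mixed models.
#' @param seed integer seed.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(abundance, traits, traitMeta, outDir,
                      scaleColumns = FALSE, spatial = FALSE, seed = 1L) {
  cfg <- list(abundance = abundance, traits = traits, traitMeta = traitMeta,
              outDir = outDir, scaleColumns = isTRUE(scaleColumns),
              spatial = isTRUE(spatial), seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a RunConfig from YAML
#'
#' Keys: `abundance`, `traits`, `trait_meta`, `out_dir`, optional
#' `scale_columns`, `spatial`, `seed`.
#'
#' @param path YAML path.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  runConfig(y$abundance, y$traits, y$trait_meta, y$out_dir,
            scaleColumns = isTRUE(y$scale_columns),
            spatial = isTRUE(y$spatial),
            seed = if (is.null(y$seed)) 1L else y$seed)
}

writeCsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

matrixToDf <- function(m, idCol = "station_id") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idCol
  rownames(df) <- NULL
  df
}

# manifest helpers: a JSON record of the run configuration and the md5
# checksum of every file read or written, so stale intermediates are
# detectable and a run is auditable from the manifest alone
manifestPath <- function(dir) file.path(dir, "run_manifest.json")

readManifest <- function(dir) {
  p <- manifestPath(dir)
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p, simplifyVector = TRUE)
}

writeManifest <- function(dir, config, checksums, dropped = 0L) {
  m <- list(
    package = "traitvar",
    version = as.character(utils::packageVersion("traitvar")),
    config = config,
    checksums = as.list(checksums),
    stations_dropped = dropped)
  jsonlite::write_json(m, manifestPath(dir), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(m)
}

checkFresh <- function(dir, files) {
  man <- readManifest(dir)
  if (is.null(man)) return(invisible(TRUE))
  for (f in files) {
    rec <- man$checksums[[basename(f)]]
    if (is.null(rec)) next
    if (!file.exists(f) || unname(tools::md5sum(f)) != rec)
      stop("stale or missing intermediate: ", basename(f),
           " does not match the run manifest; rerun the upstream stage")
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes trait ingestion, diversity indices, community-weighted
#' mean/variance matrices, the functional variance PCA, and the
#' mixed-effect trend models, writing all tabular outputs plus a JSON run
#' manifest to `cfg$outDir`:
#' `indices.csv`, `cwm.csv`, `cwv.csv`, `pca_scores.csv`,
#' `pca_loadings.csv`, `explained.csv`, `regional_trends.csv`,
#' `model_summary.csv`, `run_manifest.json`.
#'
#' @param cfg a [runConfig()].
#' @return Invisibly, a list with the in-memory results (`indices`, `fv`
#'   functional-variance pipeline output, `fits`, `files`).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  for (p in c(cfg$abundance, cfg$traits, cfg$traitMeta))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  tt <- readTraitTable(cfg$traits, cfg$traitMeta)
  survey <- readCommunityCSV(cfg$abundance)

  indices <- computeDiversity(survey, tt)
  traits <- expandTraits(tt)
  M <- cwmMatrix(survey, traits)
  V <- cwvMatrix(survey, traits)
  fv <- functionalVariancePC1(survey, tt, scaleColumns = cfg$scaleColumns)

  cwmPca <- cwvPCA(M, scaleColumns = cfg$scaleColumns)
  fits <- c(list(all = fitDispersionModel(indices, "all", spatial = cfg$spatial)),
            regionSpecificFits(indices, spatial = cfg$spatial)$fits)

  trends <- merge(
    regionalMeans(indices, cols = c("S", "H", "J", "FRic", "Q")),
    regionalMeans(fv$stations, cols = c("PC1"))[c("region", "year", "PC1")],
    by = c("region", "year"))
  trends <- trends[order(trends$region, trends$year), ]

  pca <- fv$pca
  files <- c(
    writeCsv(indices, cfg$outDir, "indices.csv"),
    writeCsv(matrixToDf(M), cfg$outDir, "cwm.csv"),
    writeCsv(matrixToDf(V), cfg$outDir, "cwv.csv"),
    writeCsv(matrixToDf(pca@scores), cfg$outDir, "pca_scores.csv"),
    writeCsv(matrixToDf(pca@loadings, "column"), cfg$outDir, "pca_loadings.csv"),
    writeCsv(data.frame(component = seq_along(pca@explained),
                        explained = pca@explained), cfg$outDir, "explained.csv"),
    writeCsv(trends, cfg$outDir, "regional_trends.csv"),
    writeCsv(modelSummaryTable(fits), cfg$outDir, "model_summary.csv"))

  inputs <- c(cfg$abundance, cfg$traits, cfg$traitMeta)
  sums <- vapply(c(inputs, files), function(f) unname(tools::md5sum(f)),
                 character(1))
  names(sums) <- basename(c(inputs, files))
  writeManifest(cfg$outDir, unclass(cfg), sums)

  invisible(list(indices = indices, fv = fv, cwmPca = cwmPca, fits = fits,
                 trends = trends, files = files))
}

#' Emit a synthetic survey to disk
#'
#' Runs the generator and writes `abundance.csv`, `traits.csv`,
#' `traits.yml`, `stations.csv` and `ground_truth.json` to a directory —
#' the input set the pipeline consumes.
#'
#' @param cfg a [syntheticConfig()].
#' @param dir output directory.
#' @return Invisibly, the named file paths.
#' @export
writeSyntheticSurvey <- function(cfg, dir) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  poolObj <- generateSpeciesPool(cfg)
  survey <- generateSurvey(cfg, poolObj)
  paths <- c(abundance = file.path(dir, "abundance.csv"),
             traits = file.path(dir, "traits.csv"),
             traitMeta = file.path(dir, "traits.yml"),
             stations = file.path(dir, "stations.csv"),
             groundTruth = file.path(dir, "ground_truth.json"))
  writeCommunityCSV(survey, paths[["abundance"]])
  writeTraitTable(poolObj$traits, paths[["traits"]], paths[["traitMeta"]])
  utils::write.csv(stationData(survey), paths[["stations"]],
                   row.names = FALSE, quote = FALSE)
  gt <- groundTruth(cfg)
  gt$pool <- as.list(poolObj$pool)
  jsonlite::write_json(gt, paths[["groundTruth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
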