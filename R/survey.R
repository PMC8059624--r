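#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a community survey
#'
#' Wraps a stations x species abundance matrix and per-station metadata in
#' a \linkS4class{CommunitySurvey} (a `SummarizedExperiment` with species
#' as rows and stations as columns).
#'
#' @param abundance numeric matrix, stations x species, with station ids as
#'   rownames and species ids as colnames.
#' @param stations data.frame with `station_id`, `region`, `year`, `lat`,
#'   `lon` (one row per station).
#' @param dropEmpty drop stations whose total abundance is zero (with a
#'   message) instead of failing validity.
#' @return A \linkS4class{CommunitySurvey}.
#' @export
communitySurvey <- function(abundance, stations, dropEmpty = TRUE) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance needs station rownames and species colnames")
  stations <- as.data.frame(stations)
  need <- c("station_id", "region", "year", "lat", "lon")
  if (!all(need %in% names(stations)))
    stop("stations must have columns: ", paste(need, collapse = ", "))
  if (!setequal(stations$station_id, rownames(abundance)))
    stop("station ids of abundance and metadata do not match")
  stations <- stations[match(rownames(abundance), stations$station_id), ]
  if (dropEmpty) {
    keep <- rowSums(abundance) > 0
    if (!all(keep)) {
      message(sum(!keep), " empty station(s) dropped")
      abundance <- abundance[keep, , drop = FALSE]
      stations <- stations[keep, , drop = FALSE]
    }
  }
  cd <- S4Vectors::DataFrame(
    region = as.character(stations$region),
    year = as.integer(stations$year),
    lat = as.numeric(stations$lat),
    lon = as.numeric(stations$lon),
    row.names = stations$station_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = t(abundance)), colData = cd)
  new("CommunitySurvey", se)
}

#' Read / write a community survey as wide CSV
#'
#' The wide CSV has one row per station with columns `station_id`,
#' `region`, `year`, `lat`, `lon` followed by one abundance column per
#' species. `readCommunityLong()` reads the long alternative
#' (`station_id`, `species_id`, `abundance`) together with a station
#' metadata CSV.
#'
#' @param path CSV path.
#' @param survey a \linkS4class{CommunitySurvey} (for the writer).
#' @param stationPath station metadata CSV (long reader only).
#' @return A \linkS4class{CommunitySurvey}; the writer invisibly returns
#'   `path`.
#' @name communityIO
#' @export
readCommunityCSV <- function(path) {
  if (!file.exists(path)) stop("abundance CSV not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  metaCols <- c("station_id", "region", "year", "lat", "lon")
  if (!all(metaCols %in% names(df)))
    stop("abundance CSV must contain columns: ",
         paste(metaCols, collapse = ", "))
  spCols <- setdiff(names(df), metaCols)
  ab <- as.matrix(df[, spCols, drop = FALSE])
  rownames(ab) <- df$station_id
  communitySurvey(ab, df[metaCols])
}

#' @rdname communityIO
#' @export
writeCommunityCSV <- function(survey, path) {
  meta <- stationData(survey)
  df <- cbind(meta, as.data.frame(communityMatrix(survey)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname communityIO
#' @export
readCommunityLong <- function(path, stationPath) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "species_id", "abundance")
  if (!all(need %in% names(long)))
    stop("long abundance CSV must contain: ", paste(need, collapse = ", "))
  stations <- utils::read.csv(stationPath, stringsAsFactors = FALSE)
  wide <- stats::xtabs(abundance ~ station_id + species_id, data = long)
  ab <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
               dimnames = list(rownames(wide), colnames(wide)))
  ab <- ab[match(stations$station_id, rownames(ab)), , drop = FALSE]
  rownames(ab) <- stations$station_id
  ab[is.na(ab)] <- 0
  communitySurvey(ab, stations)
}
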