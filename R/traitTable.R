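#' @include AllClasses.R AllGenerics.R
NULL

# column name of a fuzzy category: "<trait>_<category>"
fuzzyColName <- function(trait, category) paste(trait, category, sep = "_")

#' Construct a trait table
#'
#' Builds a validated \linkS4class{TraitTable} from a species x column value
#' matrix and per-trait metadata. Fuzzy traits occupy one column per
#' category, named `<trait>_<category>`; their memberships must be
#' non-negative and are renormalized to sum to exactly 1 when the raw sum is
#' within `1e-6` of 1 (anything further off is an error, as is a negative
#' trait weight).
#'
#' @param values numeric matrix or data.frame (species x columns) with
#'   species ids as rownames.
#' @param meta list of per-trait descriptors, each a list with `name`,
#'   `type` (`"quantitative"`, `"ordinal"` or `"fuzzy"`), optional
#'   `categories` (required for fuzzy) and optional `weight` (default 1).
#' @return A \linkS4class{TraitTable}.
#' @seealso [readTraitTable()] for the CSV + YAML reader.
#' @export
#' @examples
#' vals <- cbind(length_cm = c(a = 10, b = 30),
#'               diet_benthivore = c(1, 0), diet_piscivore = c(0, 1))
#' tt <- traitTable(vals, list(
#'   list(name = "length_cm", type = "quantitative"),
#'   list(name = "diet", type = "fuzzy",
#'        categories = c("benthivore", "piscivore"))))
#' tt
traitTable <- function(values, meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    stop("trait values need species ids as rownames")
  tm <- do.call(rbind, lapply(meta, function(m) {
    if (is.null(m$name) || is.null(m$type))
      stop("every trait descriptor needs 'name' and 'type'")
    w <- if (is.null(m$weight)) 1 else as.numeric(m$weight)
    if (!is.finite(w) || w <= 0)
      stop(sprintf("trait '%s': weight must be strictly positive", m$name))
    data.frame(trait = m$name, type = m$type, weight = w,
               stringsAsFactors = FALSE)
  }))
  tm$categories <- lapply(meta, function(m)
    if (identical(m$type, "fuzzy")) as.character(m$categories) else NA_character_)

  # expected columns, in trait declaration order
  expected <- unlist(lapply(meta, function(m) {
    if (identical(m$type, "fuzzy")) {
      if (length(m$categories) < 2)
        stop(sprintf("fuzzy trait '%s' needs >= 2 categories", m$name))
      fuzzyColName(m$name, m$categories)
    } else m$name
  }))
  missing <- setdiff(expected, colnames(values))
  if (length(missing))
    stop("declared columns absent from trait values: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(colnames(values), expected)
  if (length(extra))
    stop("unknown column(s) in trait table: ", paste(extra, collapse = ", "))
  values <- values[, expected, drop = FALSE]
  columnTrait <- unlist(lapply(meta, function(m)
    rep(m$name, if (identical(m$type, "fuzzy")) length(m$categories) else 1L)))

  # renormalize fuzzy memberships whose sum is within tolerance of 1
  for (i in which(tm$type == "fuzzy")) {
    cols <- which(columnTrait == tm$trait[i])
    m <- values[, cols, drop = FALSE]
    complete <- stats::complete.cases(m)
    if (any(m[complete, ] < 0))
      stop(sprintf("fuzzy trait '%s': negative membership", tm$trait[i]))
    s <- rowSums(m[, , drop = FALSE])
    bad <- complete & abs(s - 1) > 1e-6
    if (any(bad))
      stop(sprintf(
        "fuzzy trait '%s': memberships of species %s sum to %.6g, not 1",
        tm$trait[i], rownames(values)[which(bad)[1]], s[which(bad)[1]]))
    values[complete, cols] <- m[complete, , drop = FALSE] / s[complete]
  }

  new("TraitTable", values = values, speciesIds = rownames(values),
      traitMeta = tm, columnTrait = columnTrait)
}

#' Read a trait table from CSV plus YAML metadata
#'
#' The CSV has one row per species with a `species_id` first column; the
#' remaining columns are declared by the YAML sidecar, a `traits:` list of
#' `name`/`type`/`categories`/`weight` entries. Fuzzy trait categories map
#' to columns named `<trait>_<category>`.
#'
#' @param path CSV path.
#' @param metaPath YAML metadata path.
#' @return A \linkS4class{TraitTable}.
#' @export
readTraitTable <- function(path, metaPath) {
  if (!file.exists(path)) stop("trait CSV not found: ", path)
  if (!file.exists(metaPath)) stop("trait metadata file not found: ", metaPath)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "species_id")
    stop("first column of the trait CSV must be 'species_id'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$species_id
  meta <- yaml::read_yaml(metaPath)
  if (is.null(meta$traits)) stop("trait metadata must have a top-level 'traits' list")
  traitTable(vals, meta$traits)
}

#' Write a trait table to CSV plus YAML metadata
#'
#' Inverse of [readTraitTable()]: emits the species x column CSV and the
#' `traits:` YAML sidecar describing each column.
#'
#' @param tt a \linkS4class{TraitTable}.
#' @param path CSV path to write.
#' @param metaPath YAML path to write.
#' @return Invisibly, `c(path, metaPath)`.
#' @export
writeTraitTable <- function(tt, path, metaPath) {
  df <- data.frame(species_id = tt@speciesIds, tt@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  tm <- tt@traitMeta
  traits <- lapply(seq_len(nrow(tm)), function(i) {
    out <- list(name = tm$trait[i], type = tm$type[i], weight = tm$weight[i])
    if (tm$type[i] == "fuzzy") out$categories <- tm$categories[[i]]
    out
  })
  yaml::write_yaml(list(traits = traits), metaPath)
  invisible(c(path, metaPath))
}

#' Expand and standardize a trait table
#'
#' Produces the species-level matrix consumed by the community-weighted
#' statistics: quantitative and ordinal traits are z-scored over the full
#' species pool (ordinal values are rank-coded first); fuzzy category
#' memberships are carried unchanged, since memberships are already
#' commensurate on `[0, 1]`. A zero-variance quantitative column is retained
#' as all zeros (its sd is treated as 1) with a warning. The per-column
#' centering and scaling parameters are recorded so that the
#' standardization is frozen at the species-pool level and reused for every
#' station and year.
#'
#' @param tt a \linkS4class{TraitTable}.
#' @return An \linkS4class{ExpandedTraits}.
#' @export
expandTraits <- function(tt) {
  stopifnot(is(tt, "TraitTable"))
  vals <- tt@values
  tm <- tt@traitMeta
  center <- numeric(ncol(vals))
  scale <- rep(1, ncol(vals))
  type <- character(ncol(vals))
  weight <- numeric(ncol(vals))
  category <- rep(NA_character_, ncol(vals))
  for (i in seq_len(nrow(tm))) {
    cols <- which(tt@columnTrait == tm$trait[i])
    type[cols] <- tm$type[i]
    weight[cols] <- tm$weight[i]
    if (tm$type[i] == "fuzzy") {
      category[cols] <- tm$categories[[i]]
      next
    }
    x <- vals[, cols]
    if (tm$type[i] == "ordinal")
      x[!is.na(x)] <- rank(x[!is.na(x)], ties.method = "average")
    mu <- mean(x, na.rm = TRUE)
    sdv <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      warning(sprintf("trait '%s' has zero variance; standardized to all zeros",
                      tm$trait[i]))
      sdv <- 1
    }
    vals[, cols] <- (x - mu) / sdv
    center[cols] <- mu
    scale[cols] <- sdv
  }
  cm <- data.frame(column = colnames(vals), trait = tt@columnTrait,
                   category = category, type = type, weight = weight,
                   stringsAsFactors = FALSE)
  sc <- data.frame(column = colnames(vals), center = center, scale = scale,
                   stringsAsFactors = FALSE)
  new("ExpandedTraits", values = vals, columnMap = cm, scaling = sc)
}
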