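#' @include AllClasses.R AllGenerics.R gower.R
NULL

#' UPGMA dendrogram of a species pool
#'
#' Average-linkage agglomerative clustering of the Gower distance matrix,
#' producing the ultrametric trait dendrogram on which functional richness
#' is measured. Node heights are half the average-linkage distance at each
#' merge, so the path length from a leaf up to an ancestor and back down to
#' another leaf equals the linkage distance between their clades. Ties in
#' the minimum linkage distance are broken deterministically by merging the
#' pair of clusters whose smallest original species indices are
#' lexicographically lowest.
#'
#' @param m a \linkS4class{TraitDistance} (>= 2 species).
#' @return A \linkS4class{TraitDendrogram}.
#' @export
upgmaTree <- function(m) {
  stopifnot(is(m, "TraitDistance"))
  n <- length(m@speciesIds)
  if (n < 2) stop("UPGMA needs at least 2 species")
  D <- m@d
  active <- seq_len(n)                      # indices into bookkeeping vectors
  id <- -seq_len(n)                         # hclust-style ids
  size <- rep(1L, n)
  minLeaf <- seq_len(n)
  # working distance matrix indexed like the bookkeeping vectors; grows as
  # merged clusters are appended
  W <- matrix(NA_real_, 2 * n - 1, 2 * n - 1)
  W[seq_len(n), seq_len(n)] <- D

  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    best <- NULL
    bestD <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        i <- active[a]; j <- active[b]
        dij <- W[i, j]
        key <- sort(c(minLeaf[i], minLeaf[j]))
        if (dij < bestD - 1e-15 ||
            (abs(dij - bestD) <= 1e-15 && !is.null(best) &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, key = key)
          bestD <- dij
        }
      }
    }
    i <- best$i; j <- best$j
    if (minLeaf[j] < minLeaf[i]) { tmp <- i; i <- j; j <- tmp }
    new <- n + k
    heights[k] <- bestD / 2
    merge[k, ] <- c(id[i], id[j])
    id[new] <- k
    size[new] <- size[i] + size[j]
    minLeaf[new] <- min(minLeaf[i], minLeaf[j])
    rest <- setdiff(active, c(i, j))
    for (r in rest)
      W[new, r] <- W[r, new] <-
        (size[i] * W[i, r] + size[j] * W[j, r]) / size[new]
    active <- c(rest, new)
  }
  # guard against fp non-monotonicity (UPGMA is monotone in exact arithmetic)
  heights <- cummax(heights)
  new("TraitDendrogram", merge = merge, heights = heights,
      labels = m@speciesIds)
}

# height of a merge-matrix entry's node: 0 for leaves
nodeHeight <- function(tree, entry) {
  ifelse(entry < 0, 0, tree@heights[pmax(entry, 1)])
}

#' @rdname accessors
#' @export
setMethod("totalBranchLength", "TraitDendrogram", function(x) {
  sum(x@heights - nodeHeight(x, x@merge[, 1])) +
    sum(x@heights - nodeHeight(x, x@merge[, 2]))
})

#' Functional richness of a community on the pool dendrogram
#'
#' Total branch length of the minimal subtree of the full-pool dendrogram
#' spanning the species present in a community — an abundance-free measure
#' of trait-space coverage that grows as species with differing trait
#' values are added. A single-species community has richness 0 (degenerate
#' spanning subtree).
#'
#' @param present character vector of present species ids (or logical/
#'   integer index into the tree's leaves).
#' @param tree a \linkS4class{TraitDendrogram} over the full species pool.
#' @return Summed branch length (Gower units).
#' @export
functionalRichness <- function(present, tree) {
  stopifnot(is(tree, "TraitDendrogram"))
  n <- length(tree@labels)
  if (is.character(present)) {
    unknown <- setdiff(present, tree@labels)
    if (length(unknown))
      stop("species not in dendrogram: ", paste(unknown, collapse = ", "))
    presentLeaf <- tree@labels %in% present
  } else if (is.logical(present)) {
    stopifnot(length(present) == n)
    presentLeaf <- present
  } else {
    presentLeaf <- rep(FALSE, n)
    presentLeaf[present] <- TRUE
  }
  P <- sum(presentLeaf)
  if (P == 0) stop("no present species")
  if (P == 1) return(0)
  # present-leaf count below each merge node, bottom-up
  cnt <- numeric(n - 1L)
  countOf <- function(entry)
    ifelse(entry < 0, as.numeric(presentLeaf[-entry]), cnt[pmax(entry, 1)])
  for (k in seq_len(n - 1L))
    cnt[k] <- countOf(tree@merge[k, 1]) + countOf(tree@merge[k, 2])
  # an edge belongs to the minimal spanning subtree iff its child clade
  # holds at least one but not all present species
  total <- 0
  for (k in seq_len(n - 1L)) {
    for (s in 1:2) {
      child <- tree@merge[k, s]
      c_cnt <- countOf(child)
      if (c_cnt >= 1 && c_cnt < P)
        total <- total + (tree@heights[k] - nodeHeight(tree, child))
    }
  }
  total
}

#' Coerce a TraitDendrogram to 'hclust'
#'
#' The returned heights follow the `hclust` convention (the average-linkage
#' distance itself, i.e. twice the ultrametric node height).
#'
#' @param x a \linkS4class{TraitDendrogram}.
#' @return An object of class [stats::hclust].
#' @export
asHclust <- function(x) {
  stopifnot(is(x, "TraitDendrogram"))
  leafOrder <- function(entry) {
    if (entry < 0) return(-entry)
    c(leafOrder(x@merge[entry, 1]), leafOrder(x@merge[entry, 2]))
  }
  structure(list(
    merge = x@merge, height = 2 * x@heights,
    order = leafOrder(nrow(x@merge)),
    labels = x@labels, method = "average"),
    class = "hclust")
}
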