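# Trait ingestion, fuzzy coding, standardization, Gower distance, UPGMA.

test_that("trait tables load from CSV + YAML, with fuzzy sum-to-one policing", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "traits.csv")
  yml <- file.path(dir, "traits.yml")
  writeLines(c("species_id,size,diet_a,diet_b",
               "sp1,10,0.5,0.5",
               "sp2,20,1,0"), csv)
  writeLines(c("traits:",
               "- name: size", "  type: quantitative",
               "- name: diet", "  type: fuzzy",
               "  categories: [a, b]"), yml)
  tt <- readTraitTable(csv, yml)
  expect_s4_class(tt, "TraitTable")
  expect_equal(speciesIds(tt), c("sp1", "sp2"))
  expect_equal(unname(traitValues(tt)[, "size"]), c(10, 20))
  expect_equal(unname(traitValues(tt)["sp1", c("diet_a", "diet_b")]),
               c(0.5, 0.5))

  # memberships within 1e-6 of 1 are renormalized to exactly 1
  vals <- cbind(diet_a = c(0.3 + 2e-7, 0.6), diet_b = c(0.7, 0.4))
  rownames(vals) <- c("x", "y")
  meta <- list(list(name = "diet", type = "fuzzy", categories = c("a", "b")))
  tt2 <- traitTable(vals, meta)
  expect_equal(unname(rowSums(traitValues(tt2))), c(1, 1))

  # memberships far from 1 are an error, as are negative weights and
  # undeclared columns
  bad <- cbind(diet_a = c(0.7, 0.5), diet_b = c(0.7, 0.5))
  rownames(bad) <- c("x", "y")
  expect_error(traitTable(bad, meta), "sum to")
  expect_error(traitTable(vals, list(list(name = "diet", type = "fuzzy",
                                          categories = c("a", "b"),
                                          weight = -1))), "positive")
  vals3 <- cbind(vals, junk = c(1, 2))
  rownames(vals3) <- c("x", "y")
  expect_error(traitTable(vals3, meta), "unknown column")
})

test_that("expansion z-scores quantitative traits and carries fuzzy memberships", {
  vals <- cbind(size = c(10, 20, 30), flat = c(5, 5, 5),
                fz_a = c(1, 0, 0.5), fz_b = c(0, 1, 0.5))
  rownames(vals) <- c("s1", "s2", "s3")
  meta <- list(list(name = "size", type = "quantitative"),
               list(name = "flat", type = "quantitative"),
               list(name = "fz", type = "fuzzy", categories = c("a", "b")))
  expect_warning(ex <- expandTraits(traitTable(vals, meta)), "zero variance")
  X <- traitValues(ex)
  expect_equal(unname(X[, "size"]), c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(mean(X[, "size"]), 0, tolerance = 1e-10)
  expect_equal(sd(X[, "size"]), 1, tolerance = 1e-10)
  expect_equal(unname(X[, "flat"]), c(0, 0, 0))
  expect_equal(unname(X[, c("fz_a", "fz_b")]), unname(vals[, c("fz_a", "fz_b")]))
  # scaling parameters frozen for reproducibility
  expect_equal(ex@scaling$center[ex@scaling$column == "size"], 20)
  expect_equal(ex@scaling$scale[ex@scaling$column == "size"], 10)
  # column map covers every expanded column exactly once
  expect_equal(columnMap(ex)$column, colnames(X))
  expect_equal(sum(columnMap(ex)$trait == "fz"), 2)
})

test_that("the arithmetic-sequence z-score matches its closed form", {
  vals <- cbind(x = c(10, 20, 30))
  rownames(vals) <- letters[1:3]
  ex <- expandTraits(traitTable(vals, list(list(name = "x",
                                                type = "quantitative"))))
  expect_equal(unname(traitValues(ex)[, 1]), c(-1, 0, 1), tolerance = 1e-12)
})

test_that("Gower distance handles the degenerate and maximal cases", {
  # identical species -> d = 0
  vals <- cbind(a = c(1, 1), b = c(3, 3))
  rownames(vals) <- c("s1", "s2")
  tt <- traitTable(vals, list(list(name = "a", type = "quantitative"),
                              list(name = "b", type = "quantitative")))
  expect_equal(distanceMatrix(gowerDistance(tt))[1, 2], 0)

  # opposite binary fuzzy memberships -> d = 1
  vals <- cbind(fz_a = c(1, 0), fz_b = c(0, 1))
  rownames(vals) <- c("s1", "s2")
  tt <- traitTable(vals, list(list(name = "fz", type = "fuzzy",
                                   categories = c("a", "b"))))
  expect_equal(distanceMatrix(gowerDistance(tt))[1, 2], 1)
})

test_that("Gower matches hand-computed per-pair arithmetic on 3 x 2 traits", {
  vals <- cbind(t1 = c(0, 5, 10), t2 = c(2, 2, 6))
  rownames(vals) <- c("A", "B", "C")
  tt <- traitTable(vals, list(list(name = "t1", type = "quantitative"),
                              list(name = "t2", type = "quantitative")))
  d <- distanceMatrix(gowerDistance(tt))
  # ranges: t1 = 10, t2 = 4; d = mean of |diff|/range
  expect_equal(d["A", "B"], (5 / 10 + 0 / 4) / 2, tolerance = 1e-12)
  expect_equal(d["A", "C"], (10 / 10 + 4 / 4) / 2, tolerance = 1e-12)
  expect_equal(d["B", "C"], (5 / 10 + 4 / 4) / 2, tolerance = 1e-12)
})

test_that("Gower equals the naive double loop on random mixed tables", {
  set.seed(42)
  for (rep in 1:25) {
    tt <- randomTraitTable(sample(3:8, 1), missing = rep %% 3 == 0,
                           weights = rep %% 2 == 0)
    d <- distanceMatrix(gowerDistance(tt))
    expect_lt(max(abs(d - oracleGower(tt))), 1e-12)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
  }
})

test_that("Gower agrees with cluster::daisy on quantitative-only tables", {
  skip_if_not_installed("cluster")
  set.seed(7)
  vals <- cbind(a = rnorm(6), b = runif(6, 0, 5), c = rnorm(6, 10, 3))
  rownames(vals) <- sprintf("sp%d", 1:6)
  tt <- traitTable(vals, list(list(name = "a", type = "quantitative"),
                              list(name = "b", type = "quantitative"),
                              list(name = "c", type = "quantitative")))
  d <- distanceMatrix(gowerDistance(tt))
  ref <- as.matrix(cluster::daisy(as.data.frame(vals), metric = "gower"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-10)
})

test_that("species with no shared non-missing trait raise a named error", {
  vals <- cbind(a = c(1, NA, 2), b = c(NA, 3, 4))
  rownames(vals) <- c("s1", "s2", "s3")
  tt <- traitTable(vals, list(list(name = "a", type = "quantitative"),
                              list(name = "b", type = "quantitative")))
  expect_error(gowerDistance(tt), "s1.*s2")
})

test_that("permuting species permutes the distance matrix and preserves the tree", {
  set.seed(11)
  tt <- randomTraitTable(7)
  d1 <- gowerDistance(tt)
  perm <- sample(7)
  vals <- traitValues(tt)[perm, ]
  tm <- traitMeta(tt)
  meta <- lapply(seq_len(nrow(tm)), function(i) {
    m <- list(name = tm$trait[i], type = tm$type[i], weight = tm$weight[i])
    if (tm$type[i] == "fuzzy") m$categories <- tm$categories[[i]]
    m
  })
  d2 <- gowerDistance(traitTable(vals, meta))
  ids <- speciesIds(tt)
  expect_equal(distanceMatrix(d2)[ids, ids], distanceMatrix(d1)[ids, ids],
               tolerance = 1e-12)
  expect_equal(totalBranchLength(upgmaTree(d2)),
               totalBranchLength(upgmaTree(d1)), tolerance = 1e-12)
})

test_that("UPGMA reproduces forced topologies and hand computations", {
  mk <- function(m, ids) {
    dimnames(m) <- list(ids, ids)
    new("TraitDistance", d = m, speciesIds = ids)
  }
  # 2 species, d = 0.6: one merge at height 0.3, total branch length 0.6
  tr2 <- upgmaTree(mk(matrix(c(0, .6, .6, 0), 2), c("A", "B")))
  expect_equal(tr2@heights, 0.3)
  expect_equal(totalBranchLength(tr2), 0.6)

  # hand UPGMA: d(A,B)=0.2, d(A,C)=d(B,C)=0.8
  # merge (A,B) at h=0.1; then (AB,C) at h=0.4
  # edges: A->AB 0.1, B->AB 0.1, AB->root 0.3, C->root 0.4 => total 0.9
  m3 <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3)
  tr3 <- upgmaTree(mk(m3, c("A", "B", "C")))
  expect_equal(tr3@heights, c(0.1, 0.4))
  expect_equal(tr3@merge[1, ], c(-1L, -2L))
  expect_equal(totalBranchLength(tr3), 0.9)
  expect_error(upgmaTree(mk(matrix(0, 1, 1), "A")), "at least 2")
})

test_that("equidistant ties break by index and leave total length invariant", {
  ids <- c("A", "B", "C")
  m <- matrix(0.5, 3, 3); diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  tr <- upgmaTree(new("TraitDistance", d = m, speciesIds = ids))
  expect_equal(tr@merge[1, ], c(-1L, -2L))  # lowest index pair first
  total1 <- totalBranchLength(tr)
  # every permutation of an equidistant triple has the same total length
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    mp <- m[perm, perm]
    trp <- upgmaTree(new("TraitDistance", d = mp, speciesIds = ids[perm]))
    expect_equal(totalBranchLength(trp), total1, tolerance = 1e-12)
  }
})

test_that("UPGMA heights are monotone and match stats::hclust linkage", {
  set.seed(5)
  for (rep in 1:10) {
    tt <- randomTraitTable(sample(4:8, 1))
    d <- gowerDistance(tt)
    tr <- upgmaTree(d)
    expect_false(is.unsorted(tr@heights))
    ref <- stats::hclust(asDist(d), method = "average")
    # ultrametric node heights are half the average-linkage distances
    expect_equal(sort(2 * tr@heights), sort(ref$height), tolerance = 1e-10)
  }
})

test_that("distance matrices round-trip through square CSV", {
  set.seed(3)
  d <- gowerDistance(randomTraitTable(5))
  path <- withr::local_tempfile(fileext = ".csv")
  writeDistanceCSV(d, path)
  d2 <- readDistanceCSV(path)
  expect_equal(speciesIds(d2), speciesIds(d))
  expect_equal(distanceMatrix(d2), distanceMatrix(d), tolerance = 1e-12)
})
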