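# Community-weighted mean/variance and the functional variance PCA.

test_that("scalar CWM/CWV reproduce their closed forms", {
  expect_equal(unname(cwm(1, matrix(c(3, -2), 1))), c(3, -2))
  expect_equal(unname(cwm(c(0.5, 0.5), cbind(x = c(0, 1)))), 0.5)
  expect_equal(unname(cwv(1, matrix(c(3, -2), 1))), c(0, 0))
  expect_equal(unname(cwv(c(0.5, 0.5), cbind(x = c(0, 1)))), 0.25)
  expect_equal(unname(cwv(c(0.9, 0.1), cbind(x = c(0, 1)))), 0.09,
               tolerance = 1e-12)
  expect_error(cwm(c(0.5, 0.5), matrix(0, 3, 2)), "misaligned")
})

test_that("CWM/CWV match brute-force loops and the algebraic identity", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    p <- unname(relativeAbundance(randomAbundance(n, n)))
    x <- rnorm(n, sd = 3)
    expect_lt(abs(cwm(p, cbind(x)) - oracleCWM(p, x)), 1e-12)
    expect_lt(abs(cwv(p, cbind(x)) - oracleCWV(p, x)), 1e-12)
    # sum p (x - m)^2 == sum p x^2 - (sum p x)^2
    expect_lt(abs(cwv(p, cbind(x)) - (sum(p * x^2) - sum(p * x)^2)), 1e-10)
    expect_gte(cwv(p, cbind(x)), 0)
  }
  # CWV = 0 iff all present species share the value
  p <- c(0.3, 0.7)
  expect_equal(unname(cwv(p, cbind(c(2, 2)))), 0)
  expect_gt(cwv(p, cbind(c(2, 2.1))), 0)
})

test_that("CWM stays within the span of present species values", {
  set.seed(22)
  for (rep in 1:15) {
    n <- sample(2:8, 1)
    p <- unname(relativeAbundance(randomAbundance(n, n)))
    x <- runif(n, -5, 5)
    m <- cwm(p, cbind(x))
    expect_gte(m, min(x) - 1e-12)
    expect_lte(m, max(x) + 1e-12)
  }
})

test_that("a {0,1}-membership fuzzy column has Bernoulli variance q(1-q)", {
  ab <- rbind(st1 = c(9, 1), st2 = c(2, 2))
  colnames(ab) <- c("sp1", "sp2")
  st <- data.frame(station_id = c("st1", "st2"), region = "arctic",
                   year = 2004L, lat = 77, lon = c(30, 31))
  vals <- cbind(fz_a = c(1, 0), fz_b = c(0, 1))
  rownames(vals) <- c("sp1", "sp2")
  tt <- traitTable(vals, list(list(name = "fz", type = "fuzzy",
                                   categories = c("a", "b"))))
  V <- cwvMatrix(communitySurvey(ab, st), expandTraits(tt))
  expect_equal(unname(V["st1", "fz_a"]), 0.9 * 0.1, tolerance = 1e-12)
  expect_equal(unname(V["st2", "fz_a"]), 0.25, tolerance = 1e-12)
})

test_that("station x trait matrices match the scalar oracle cell-wise", {
  cfg <- syntheticConfig(seed = 5, nStationsPerRegionYear = 3L,
                         years = 2004:2005)
  pool <- generateSpeciesPool(cfg)
  sv <- generateSurvey(cfg, pool)
  traits <- expandTraits(pool$traits)
  V <- cwvMatrix(sv, traits)
  M <- cwmMatrix(sv, traits)
  A <- communityMatrix(sv)
  X <- traitValues(traits)
  for (i in seq_len(nrow(A))) {
    p <- relativeAbundance(A[i, ])
    Xi <- X[names(p), , drop = FALSE]
    for (j in sample(ncol(V), 4)) {
      expect_lt(abs(V[i, j] - oracleCWV(unname(p), Xi[, j])), 1e-12)
      expect_lt(abs(M[i, j] - oracleCWM(unname(p), Xi[, j])), 1e-12)
    }
  }
  expect_true(all(V >= 0))

  # all abundance on one species -> zero CWV row; identical compositions ->
  # identical rows
  ab <- rbind(one = c(5, 0, 0), dupA = c(1, 2, 3), dupB = c(2, 4, 6))
  colnames(ab) <- speciesIds(tinyTraits())
  st <- data.frame(station_id = rownames(ab), region = "arctic",
                   year = 2004L, lat = 77, lon = c(30, 31, 32))
  V2 <- cwvMatrix(communitySurvey(ab, st), expandTraits(tinyTraits()))
  expect_equal(unname(V2["one", ]), rep(0, ncol(V2)))
  expect_equal(V2["dupA", ], V2["dupB", ], tolerance = 1e-12)
})

test_that("the CWV PCA satisfies its spectral contract", {
  # only one varying column -> PC1 explains everything, loading on it
  V <- cbind(a = c(1, 2, 3, 4), b = 1, c = 2)
  pca <- cwvPCA(V)
  expect_equal(pca@explained[1], 1, tolerance = 1e-12)
  expect_equal(abs(pca@loadings["a", 1]), 1, tolerance = 1e-12)

  # two perfectly correlated columns -> PC1 explains all, equal |loading|
  V2 <- cbind(a = c(1, 2, 3, 5), b = 2 * c(1, 2, 3, 5))
  pca2 <- cwvPCA(V2, scaleColumns = TRUE)
  expect_equal(pca2@explained[1], 1, tolerance = 1e-12)
  expect_equal(abs(pca2@loadings["a", 1]), abs(pca2@loadings["b", 1]),
               tolerance = 1e-12)

  expect_error(cwvPCA(matrix(1, 3, 3)), "no variance")
  expect_error(cwvPCA(matrix(1, 1, 3)), "at least 2")
})

test_that("random matrices reconstruct from scores and loadings", {
  set.seed(30)
  V <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("st%02d", 1:20), letters[1:6]))
  pca <- cwvPCA(V)
  rec <- pca@scores %*% t(pca@loadings) +
    matrix(pca@center, 20, 6, byrow = TRUE)
  expect_lt(max(abs(rec - V)), 1e-10)
  expect_equal(sum(pca@explained), 1, tolerance = 1e-10)
  # loadings orthonormal, scores uncorrelated across components
  expect_lt(max(abs(crossprod(pca@loadings) - diag(6))), 1e-10)
  cors <- cor(pca@scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  # score variances proportional to eigenvalues
  expect_equal(apply(pca@scores, 2, var) / sum(apply(pca@scores, 2, var)),
               pca@explained, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PC1 sign is oriented by dispersion and r2 is computed directly", {
  set.seed(31)
  V <- matrix(rnorm(30 * 4), 30, 4)
  q <- rnorm(30)
  pca <- cwvPCA(V, dispersion = q)
  expect_gte(cor(pca@scores[, 1], q), 0)
  # flipping the dispersion flips the orientation decision consistently
  pca2 <- cwvPCA(V, dispersion = -q)
  expect_gte(cor(pca2@scores[, 1], -q), 0)

  x <- rnorm(25)
  expect_equal(pc1DispersionR2(x, x), 1)
  y <- rnorm(25)
  resid <- residuals(lm(y ~ x))
  expect_equal(pc1DispersionR2(x, resid), 0, tolerance = 1e-10)
  z <- rnorm(25)
  num <- sum((x - mean(x)) * (z - mean(z)))
  r2direct <- num^2 / (sum((x - mean(x))^2) * sum((z - mean(z))^2))
  expect_equal(pc1DispersionR2(x, z), r2direct, tolerance = 1e-12)
  expect_error(pc1DispersionR2(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("the functional variance pipeline summarizes the survey", {
  cfg <- syntheticConfig(seed = 1)
  pool <- generateSpeciesPool(cfg)
  sv <- generateSurvey(cfg, pool)
  fv <- functionalVariancePC1(sv, pool$traits)
  expect_s4_class(fv$pca, "TraitPCA")
  expect_equal(nrow(fv$stations), ncol(sv))
  expect_setequal(unique(fv$regional$region), c("arctic", "boreal"))
  # loading ranking is sorted by |loading| and covers all expanded columns
  expect_false(is.unsorted(rev(abs(fv$loadingRanking$loading))))
  expect_equal(nrow(fv$loadingRanking), nrow(fv$pca@loadings))
  # PC1 is a positive indicator of functional dispersion on this survey
  expect_gt(cor(fv$stations$PC1, fv$stations$Q), 0)
  expect_gt(fv$r2, 0.5)
  # degenerate survey of identical stations has no variance to decompose
  ab <- matrix(rep(c(1, 2, 3), each = 3), 3, byrow = FALSE,
               dimnames = list(c("s1", "s2", "s3"), speciesIds(tinyTraits())))
  st <- data.frame(station_id = c("s1", "s2", "s3"), region = "arctic",
                   year = 2004L, lat = 77, lon = 30)
  expect_error(functionalVariancePC1(communitySurvey(ab, st), tinyTraits()),
               "no variance")
})

test_that("the pipeline is invariant to station and species permutations", {
  cfg <- syntheticConfig(seed = 8, nStationsPerRegionYear = 4L,
                         years = 2004:2006)
  pool <- generateSpeciesPool(cfg)
  sv <- generateSurvey(cfg, pool)
  A <- communityMatrix(sv)
  st <- stationData(sv)
  set.seed(99)
  pr <- sample(nrow(A)); pc <- sample(ncol(A))
  sv2 <- communitySurvey(A[pr, pc], st[pr, ])
  f1 <- functionalVariancePC1(sv, pool$traits)
  f2 <- functionalVariancePC1(sv2, pool$traits)
  m1 <- f1$stations[order(f1$stations$station_id), ]
  m2 <- f2$stations[order(f2$stations$station_id), ]
  expect_equal(m2$Q, m1$Q, tolerance = 1e-10)
  expect_equal(abs(m2$PC1), abs(m1$PC1), tolerance = 1e-8)
  expect_equal(f2$pca@explained, f1$pca@explained, tolerance = 1e-10)
})
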