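test_that("biomarker counts map verbatim onto distances", {
  cnt <- matrix(c(0, 5, 2, 5, 0, 0, 2, 0, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  pcm <- new("PairCountMatrix", counts = cnt)
  d <- biomarkerDistance(pcm)
  expect_s3_class(d, "dist")
  dm <- as.matrix(d)
  expect_equal(dm["A", "B"], 5)
  expect_equal(dm["B", "C"], 0)
  expect_true(isSymmetric(dm))
  expect_equal(unname(diag(dm)), rep(0, 3))
  bad <- cnt; bad[1, 2] <- 4
  expect_error(biomarkerDistance(bad), "symmetric")
  expect_error(new("PairCountMatrix", counts = bad), "symmetric")
})

test_that("Ward.D2 reproduces the hand-worked three-label merge", {
  two <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"),
                                                  c("A", "B")))
  t2 <- wardD2(two)
  expect_equal(t2$height, 3)

  m <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- wardD2(m)
  expect_equal(tr$height, c(1, sqrt(33)), tolerance = 1e-12)
  expect_equal(tr$merge[1, ], c(-2L, -1L))  # A and B merge first
  expect_error(wardD2(m[1, 1, drop = FALSE]), "two labels")
})

test_that("Ward.D2 agrees with the naive agglomeration oracle and hclust", {
  for (seed in c(1, 2, 3, 4, 5)) {
    m <- randomDistMatrix(seed, n = 8)
    tr <- wardD2(m)
    orc <- wardOracle(m)
    expect_equal(tr$height, orc$heights, tolerance = 1e-9)
    expect_equal(as.matrix(stats::cophenetic(tr))[rownames(orc$coph),
                                                  colnames(orc$coph)],
                 orc$coph, tolerance = 1e-9)
    # independent cross-check: stats::hclust on tie-free distances
    hc <- stats::hclust(stats::as.dist(m), method = "ward.D2")
    expect_equal(tr$height, hc$height, tolerance = 1e-9)
    expect_equal(as.matrix(stats::cophenetic(tr)),
                 as.matrix(stats::cophenetic(hc))[rownames(m),
                                                  colnames(m)],
                 tolerance = 1e-9)
  }
})

test_that("Ward.D2 heights are monotone and the tree is permutation-invariant", {
  for (seed in c(11, 12)) {
    m <- randomDistMatrix(seed, n = 7)
    tr <- wardD2(m)
    expect_true(all(diff(tr$height) >= -1e-12))
    perm <- sample(nrow(m))
    mp <- m[perm, perm]
    trp <- wardD2(mp)
    expect_equal(trp$height, tr$height, tolerance = 1e-12)
    expect_equal(as.matrix(stats::cophenetic(trp))[rownames(m),
                                                   colnames(m)],
                 as.matrix(stats::cophenetic(tr)), tolerance = 1e-12)
  }
  # integer tied distances: permutation invariance via lexicographic ties
  cnt <- matrix(0L, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                          c("A", "B", "C", "D")))
  cnt["A", "B"] <- cnt["B", "A"] <- 2L
  cnt["C", "D"] <- cnt["D", "C"] <- 2L
  cnt["A", "C"] <- cnt["C", "A"] <- 9L
  cnt["A", "D"] <- cnt["D", "A"] <- 9L
  cnt["B", "C"] <- cnt["C", "B"] <- 9L
  cnt["B", "D"] <- cnt["D", "B"] <- 9L
  tr1 <- wardD2(cnt)
  perm <- c(4, 2, 1, 3)
  tr2 <- wardD2(cnt[perm, perm])
  expect_equal(as.matrix(stats::cophenetic(tr2))[rownames(cnt),
                                                 colnames(cnt)],
               as.matrix(stats::cophenetic(tr1)))
})

test_that("PCA reports covariance-based variance fractions", {
  # rank-1 data: first component carries everything
  m <- matrix(c(1, 1, 3, 3), 2, dimnames = list(c("f1", "f2"),
                                                c("s1", "s2")))
  sm <- ScoreMatrix(m, setNames(c("a", "b"), c("s1", "s2")), "PI")
  p <- pcaScores(sm, 1)
  expect_equal(p$varianceExplained, 1.0)

  set.seed(9)
  m2 <- matrix(abs(rnorm(20 * 50)), nrow = 50,
               dimnames = list(sprintf("f%02d", 1:50),
                               sprintf("s%02d", 1:20)))
  sm2 <- ScoreMatrix(m2, setNames(rep(c("a", "b"), 10), colnames(m2)),
                     "PI")
  p2 <- pcaScores(sm2, 5)
  expect_true(all(diff(p2$varianceExplained) <= 1e-12))
  expect_true(all(p2$varianceExplained >= 0 & p2$varianceExplained <= 1))

  # oracle: eigenvalues of the directly computed covariance matrix
  X <- t(m2)
  ev <- sort(eigen(stats::cov(X), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(p2$varianceExplained, (ev / sum(ev))[1:5],
               tolerance = 1e-9)

  # reconstruction from all components returns the centered data
  pa <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(pa$x %*% t(pa$rotation),
               scale(X, center = TRUE, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-9)

  # sample reordering leaves variance fractions unchanged
  sm3 <- ScoreMatrix(m2[, 20:1], setNames(rep(c("a", "b"), 10),
                                          colnames(m2)[20:1]), "PI")
  expect_equal(pcaScores(sm3, 5)$varianceExplained,
               p2$varianceExplained, tolerance = 1e-9)

  expect_error(pcaScores(sm2, 21), "nComponents")
})
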