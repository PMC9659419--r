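test_that("Bray-Curtis matches the direct formula and stays in [0, 1]", {
  m <- cbind(u = c(1, 1, 0), v = c(0, 1, 1))
  rownames(m) <- paste0("t", 1:3)
  expect_equal(as.numeric(brayCurtis(m)), 0.5)  # sum|u-v|=2, sum(u+v)=4

  same <- cbind(a = c(1, 2), b = c(1, 2)); rownames(same) <- c("x", "y")
  expect_equal(as.numeric(brayCurtis(same)), 0)
  disj <- cbind(a = c(1, 0), b = c(0, 3)); rownames(disj) <- c("x", "y")
  expect_equal(as.numeric(brayCurtis(disj)), 1)

  set.seed(1)
  rnd <- matrix(rexp(60), 6, dimnames = list(paste0("v", 1:6),
                                             paste0("s", 1:10)))
  d <- as.numeric(brayCurtis(rnd))
  expect_true(all(d >= 0 & d <= 1))

  zz <- cbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  rownames(zz) <- c("x", "y")
  expect_error(brayCurtis(zz), "all-zero")
})

test_that("spatial distance is the Euclidean plot-center distance", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     x = c(0, 3, 0), y = c(0, 4, 0))
  d <- as.matrix(spatialDistance(meta))
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)

  fl <- generateFieldLayout(1, 1, 7.5, 1.8, seed = 1)
  d2 <- as.matrix(spatialDistance(fl@samples))
  crossBlock <- outer(fl@samples$block, fl@samples$block, "!=")
  expect_true(all(d2[crossBlock] == 7.5))
})

test_that("distance decay recovers a perfect linear relationship", {
  n <- 8
  meta <- data.frame(sample_id = paste0("s", 1:n), x = seq_len(n), y = 0,
                     timepoint = "T1")
  sp <- spatialDistance(meta)
  sim <- 1 - 0.05 * as.matrix(sp)   # similarity falls linearly
  dis <- as.dist(1 - sim)
  fit <- distanceDecay(dis, sp, meta)
  expect_equal(fit@r, -1, tolerance = 1e-12)
  expect_equal(fit@slope, -0.05, tolerance = 1e-12)
  expect_lt(fit@pValue, 1e-10)
  expect_equal(fit@nPairs, choose(n, 2))
})

test_that("cross-timepoint pairs are excluded with the exact pair count", {
  fl <- generateFieldLayout(seed = 2)
  sim <- simulateAbundanceTable(fl, nVotus = 60, seed = 2)
  ve <- sim$experiment
  meta <- sampleMetadata(ve)
  bc <- brayCurtis(logTransform(relativeAbundance(abundances(ve))))
  fit <- distanceDecay(bc, spatialDistance(meta), meta)
  n1 <- sum(meta$timepoint == "T1"); n2 <- sum(meta$timepoint == "T2")
  expect_equal(fit@nPairs, choose(n1, 2) + choose(n2, 2))
})

test_that("degenerate spatial variance is an explicit error", {
  meta <- data.frame(sample_id = paste0("s", 1:4), x = 1, y = 1,
                     timepoint = "T1")
  sp <- spatialDistance(meta)
  d <- as.dist(matrix(c(0, .1, .2, .3, .1, 0, .1, .2,
                        .2, .1, 0, .1, .3, .2, .1, 0), 4,
                      dimnames = list(meta$sample_id, meta$sample_id)))
  expect_error(distanceDecay(d, sp, meta), "degenerate")
})

test_that("community overlap is the Jaccard percentage of detection sets", {
  m <- matrix(0, 4, 3, dimnames = list(c("a", "b", "c", "d"),
                                       c("s1", "s2", "s3")))
  m[c("a", "b", "c"), "s1"] <- 1
  m[c("b", "c", "d"), "s2"] <- 1
  m["a", "s3"] <- 0; m["d", "s3"] <- 1
  ov <- communityOverlap(m)
  expect_equal(ov["s1", "s2"], 50)       # 2 shared / 4 union
  expect_equal(ov["s1", "s1"], 100)
  expect_equal(ov["s1", "s3"], 0)        # disjoint
})

test_that("environmental distance z-scores variables before Euclid", {
  chem <- data.frame(v1 = c(0, 2)); rownames(chem) <- c("a", "b")
  expect_equal(as.numeric(environmentalDistance(chem)), sqrt(2),
               tolerance = 1e-12)   # z = -/+ 1/sqrt(2)

  set.seed(3)
  chem2 <- as.data.frame(matrix(runif(20), 5))
  rownames(chem2) <- paste0("s", 1:5)
  expect_equal(as.numeric(environmentalDistance(chem2)),
               as.numeric(environmentalDistance(chem2 * 2)),
               tolerance = 1e-12)
  chem3 <- chem2; chem3$V2 <- 7
  expect_error(environmentalDistance(chem3), "V2")
  ident <- data.frame(v1 = c(1, 1, 2)); rownames(ident) <- c("a", "b", "c")
  expect_equal(as.matrix(environmentalDistance(ident))["a", "b"], 0)
})

test_that("matrix correlation handles identity, masks, and degeneracy", {
  set.seed(4)
  pts <- matrix(runif(20), 10)
  rownames(pts) <- paste0("s", 1:10)
  d <- dist(pts)
  r <- matrixCorrelation(d, d)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$nPairs, 45)

  const <- as.dist(matrix(1, 10, 10,
                          dimnames = list(rownames(pts), rownames(pts))))
  expect_error(matrixCorrelation(d, const), "degenerate")

  mask <- matrix(FALSE, 10, 10)
  mask[1:5, 1:5] <- TRUE
  expect_equal(matrixCorrelation(d, d, mask)$nPairs, 10)
})

test_that("null matrix correlations give uniform two-sided p-values", {
  ps <- vapply(1:60, function(s) {
    set.seed(s)
    a <- dist(matrix(rnorm(30), 15)); b <- dist(matrix(rnorm(30), 15))
    attr(a, "Labels") <- attr(b, "Labels") <- paste0("s", 1:15)
    matrixCorrelation(a, b)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("PCoA recovers 1-D and 2-D configurations", {
  x <- c(0, 1, 3)
  d <- dist(x)
  attr(d, "Labels") <- c("a", "b", "c")
  ord <- suppressWarnings(runPCoA(d, nAxes = 2))
  expect_true(ord@truncated)
  expect_equal(ord@percentVariance[1], 100)
  rec <- dist(ord@coordinates[, 1])
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-9)

  set.seed(5)
  pts <- matrix(runif(16), 8)
  rownames(pts) <- paste0("s", 1:8)
  d2 <- dist(pts)
  ord2 <- runPCoA(d2, nAxes = 2)
  expect_false(ord2@truncated)
  expect_equal(as.numeric(dist(ord2@coordinates)), as.numeric(d2),
               tolerance = 1e-8)
  # sign canonicalization: largest-magnitude coordinate positive
  for (j in 1:2) expect_gt(max(ord2@coordinates[, j]),
                           -min(ord2@coordinates[, j]))
})

test_that("PCoA percent variance agrees with the ape implementation", {
  skip_if_not_installed("ape")
  set.seed(6)
  m <- matrix(rexp(80), 8, dimnames = list(paste0("v", 1:8),
                                           paste0("s", 1:10)))
  d <- brayCurtis(m)
  ours <- runPCoA(d, nAxes = 3)
  theirs <- ape::pcoa(d)
  nPos <- length(ours@percentVariance)
  expect_equal(ours@eigenvalues[1:nPos],
               theirs$values$Eigenvalues[1:nPos], tolerance = 1e-8)
  expect_equal(unname(abs(ours@coordinates[, 1])),
               unname(abs(theirs$vectors[, 1])), tolerance = 1e-8)
})

test_that("two identical samples land on identical coordinates", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(3, 1, 0),
             s4 = c(0, 4, 1))
  rownames(m) <- paste0("v", 1:3)
  ord <- runPCoA(brayCurtis(m), nAxes = 2)
  expect_equal(ord@coordinates["s1", ], ord@coordinates["s2", ],
               tolerance = 1e-10)
})

test_that("PERMANOVA pseudo-F matches the hand partition of squared distances", {
  set.seed(7)
  m <- matrix(rexp(60), 6, dimnames = list(paste0("v", 1:6),
                                           paste0("s", 1:10)))
  d <- brayCurtis(m)
  grp <- rep(c("A", "B"), each = 5)
  fit <- permanovaTest(d, grp, nPerm = 99, seed = 1)
  expect_equal(fit$pseudoF, pseudoF(d, grp), tolerance = 1e-10)
})

test_that("well-separated clusters reach the minimal permutation p", {
  # 12+12 samples: the chance a random label permutation regenerates the
  # observed partition (and so ties the observed F) is ~7e-7, so the
  # minimal attainable p = 1/(nPerm + 1) is reached.
  set.seed(8)
  pts <- rbind(matrix(rnorm(24, 0), 12), matrix(rnorm(24, 50), 12))
  rownames(pts) <- paste0("s", 1:24)
  d <- dist(pts)
  fit <- permanovaTest(d, rep(c("A", "B"), each = 12), nPerm = 999, seed = 2)
  expect_equal(fit$p, 1 / 1000)
  expect_error(permanovaTest(d, c("A", rep("B", 23)), nPerm = 999),
               "at least 2")
})

test_that("slope ratio mirrors the viral-vs-prokaryote comparison", {
  mk <- function(s) new("DecayFit", r = -0.5, slope = s, intercept = 1,
                        pValue = 0.01, nPairs = 10L)
  expect_equal(slopeRatio(mk(-5.8e-3), mk(-1.0e-3)), 5.8)
  expect_equal(slopeRatio(mk(-2e-3), mk(-2e-3)), 1)
  expect_error(slopeRatio(mk(-1e-3), mk(0)), "negative")
})
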