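#' Bray-Curtis dissimilarity between samples
#'
#' Computes `d(u, v) = sum|u - v| / sum(u + v)` over vOTUs, for every pair
#' of samples, via [vegan::vegdist()]. Callers are expected to pass
#' log-transformed relative abundances (see [relativeAbundance()] and
#' [logTransform()]); the function itself only requires non-negative input.
#' Bray-Curtis is a semimetric: values lie in \[0, 1\] but the triangle
#' inequality is not guaranteed.
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param ... unused.
#' @return a `dist` object over samples.
#' @export
setMethod("brayCurtis", "matrix", function(x, ...) {
  empty <- colSums(x) == 0
  if (sum(empty) >= 2)
    stop("Bray-Curtis undefined for pairs of all-zero samples: ",
         paste(colnames(x)[empty], collapse = ", "))
  vegan::vegdist(t(x), method = "bray")
})

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "ViromeExperiment",
          function(x, ...) brayCurtis(abundances(x)))

#' Pairwise spatial distance between samples
#'
#' Euclidean distance between the plot centers of the samples' plots; two
#' samples from the same plot are 0 m apart.
#'
#' @param meta data.frame with `sample_id`, `x`, `y` columns (meters), or a
#'   [ViromeExperiment-class] with those columns in its metadata.
#' @return a `dist` object over samples, meters.
#' @export
spatialDistance <- function(meta) {
  if (is(meta, "ViromeExperiment")) meta <- sampleMetadata(meta)
  if (!all(c("x", "y") %in% colnames(meta)) ||
      any(!is.finite(meta$x)) || any(!is.finite(meta$y)))
    stop("metadata must provide finite x and y coordinates")
  xy <- as.matrix(meta[, c("x", "y")])
  rownames(xy) <- meta$sample_id
  stats::dist(xy)
}

#' Pairwise percentage of shared vOTUs (Jaccard %)
#'
#' `overlap(u, v) = 100 * |detected(u) & detected(v)| / |detected(u) |
#' detected(v)|`, i.e. the Jaccard index of the detection sets as a
#' percentage. Returned as a similarity: identical detection sets give 100,
#' disjoint sets 0.
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param ... unused.
#' @return symmetric sample x sample matrix of percentages (diagonal 100).
#' @export
setMethod("communityOverlap", "matrix", function(x, ...) {
  det <- x > 0
  if (sum(colSums(det) == 0) >= 2)
    stop("overlap undefined for pairs of samples with no detections")
  inter <- crossprod(det)
  n <- colSums(det)
  union <- outer(n, n, "+") - inter
  100 * inter / union
})

#' @rdname communityOverlap
#' @export
setMethod("communityOverlap", "ViromeExperiment",
          function(x, ...) communityOverlap(abundances(x)))

#' Environmental distance from soil-chemistry variables
#'
#' Standardizes each variable to a z-score (mean 0, sd 1, n-1 denominator)
#' and returns Euclidean distances between samples, so all variables weigh
#' equally regardless of units.
#'
#' @param chem data.frame or matrix, samples in rows (rownames = sample
#'   ids), numeric variables in columns.
#' @return a `dist` object over samples.
#' @export
environmentalDistance <- function(chem) {
  m <- as.matrix(chem)
  if (nrow(m) < 2) stop("need at least 2 samples")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  stats::dist(scale(m))
}

#' Mask of same-timepoint sample pairs
#'
#' @param meta data.frame with `sample_id` and `timepoint`.
#' @param labels sample ids defining row/column order.
#' @return logical matrix, `TRUE` where both samples share a timepoint.
#' @export
sameTimepointMask <- function(meta, labels) {
  tp <- meta$timepoint[match(labels, meta$sample_id)]
  if (any(is.na(tp))) stop("metadata missing timepoint for some samples")
  outer(tp, tp, "==")
}

.pairVectors <- function(a, b, mask = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(rownames(a), rownames(b)))
    stop("distance matrices must share labels in the same order")
  keep <- lower.tri(a)
  if (!is.null(mask)) keep <- keep & as.matrix(mask)
  list(a = a[keep], b = b[keep])
}

#' Pearson correlation between two pairwise matrices
#'
#' Correlates the unordered off-diagonal pairs of two distance (or
#' similarity) matrices over the same samples, optionally restricted by a
#' pair mask such as [sameTimepointMask()]. Two-sided test.
#'
#' @param a,b `dist` objects or symmetric matrices with identical labels.
#' @param mask optional logical sample x sample matrix selecting pairs.
#' @return list with `r`, `p`, and `nPairs`.
#' @export
matrixCorrelation <- function(a, b, mask = NULL) {
  v <- .pairVectors(a, b, mask)
  if (length(v$a) < 3) stop("fewer than 3 pairs retained")
  if (stats::sd(v$a) == 0 || stats::sd(v$b) == 0)
    stop("degenerate variance: a matrix is constant over the retained pairs")
  ct <- stats::cor.test(v$a, v$b, alternative = "two.sided",
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, nPairs = length(v$a))
}

#' Distance-decay of community similarity
#'
#' Regresses pairwise community similarity (1 - Bray-Curtis) on pairwise
#' spatial distance over unordered sample pairs, reporting the Pearson
#' correlation (two-sided P) and the least-squares slope and intercept.
#' By default all pairs of samples collected at different timepoints are
#' excluded, so temporal turnover cannot masquerade as spatial turnover;
#' with `nT1` and `nT2` samples per timepoint this retains exactly
#' `nT1(nT1-1)/2 + nT2(nT2-1)/2` pairs.
#'
#' @param dissim Bray-Curtis `dist` (or symmetric matrix) over samples.
#' @param space spatial `dist` from [spatialDistance()], same labels.
#' @param meta sample metadata with `sample_id` and `timepoint` (needed when
#'   `sameTimepointOnly = TRUE`).
#' @param sameTimepointOnly exclude cross-timepoint pairs (default TRUE).
#' @return a [DecayFit-class].
#' @export
distanceDecay <- function(dissim, space, meta = NULL,
                          sameTimepointOnly = TRUE) {
  labels <- rownames(as.matrix(dissim))
  mask <- NULL
  if (sameTimepointOnly) {
    if (is.null(meta)) stop("meta is required when sameTimepointOnly = TRUE")
    mask <- sameTimepointMask(meta, labels)
  }
  v <- .pairVectors(dissim, space, mask)
  if (length(v$a) < 3) stop("fewer than 3 pairs retained")
  sim <- 1 - v$a
  d <- v$b
  if (stats::sd(d) == 0)
    stop("degenerate variance: spatial distances are constant")
  if (stats::sd(sim) == 0)
    stop("degenerate variance: similarities are constant")
  ct <- stats::cor.test(sim, d, alternative = "two.sided")
  fit <- stats::lm(sim ~ d)
  new("DecayFit", r = unname(ct$estimate),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      pValue = ct$p.value, nPairs = length(d))
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix (double-centered -D^2/2,
#' eigendecomposition). Axes with positive eigenvalues are retained, sorted
#' descending; percent variance is each positive eigenvalue over the sum of
#' positive eigenvalues. Negative eigenvalues (possible for semimetrics such
#' as Bray-Curtis) are reported but excluded, with no correction applied.
#' Axis signs are canonicalized so the largest-magnitude coordinate on each
#' axis is positive, making ordinations reproducible.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param nAxes number of axes to return; truncated (with the `truncated`
#'   flag set and a warning) when fewer positive axes exist.
#' @return an [Ordination-class].
#' @export
runPCoA <- function(d, nAxes = 2) {
  d <- stats::as.dist(as.matrix(d))
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- max(abs(eig)) * 1e-9
  nPos <- sum(eig > tol)
  truncated <- nAxes > nPos
  if (truncated)
    warning("only ", nPos, " positive-eigenvalue axes available")
  kept <- min(nAxes, nPos)
  coords <- fit$points[, seq_len(kept), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    peak <- which.max(abs(coords[, j]))
    if (coords[peak, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCo", seq_len(kept))
  pv <- 100 * eig[seq_len(nPos)] / sum(eig[seq_len(nPos)])
  new("Ordination", coordinates = coords, eigenvalues = eig,
      percentVariance = pv, truncated = truncated)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix for
#' a single grouping factor, via [vegan::adonis2()]: the total sum of
#' squared distances is partitioned into between- and within-group parts,
#' pseudo-F = (SS_between/(a-1)) / (SS_within/(n-a)), and significance is
#' assessed by seeded label permutations with the unbiased estimator
#' p = (1 + #\{permuted F >= observed\}) / (1 + nPerm).
#'
#' @param d a `dist` object over samples.
#' @param groups factor (or coercible) of group labels, one per sample; at
#'   least two groups, each with at least two samples.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return list with `pseudoF`, `R2`, `p`, `nPerm`.
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  if (nPerm < 99) stop("nPerm must be at least 99")
  df <- data.frame(groups = groups)
  set.seed(seed)
  fit <- vegan::adonis2(d ~ groups, data = df, permutations = nPerm)
  list(pseudoF = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
       nPerm = nPerm)
}

#' Ratio of distance-decay slopes
#'
#' Magnitude ratio of two (negative) distance-decay slopes, e.g. comparing
#' the spatial turnover rate of viral versus prokaryotic communities.
#'
#' @param a,b [DecayFit-class] objects; both slopes must be negative.
#' @return `abs(slope(a)) / abs(slope(b))`.
#' @export
slopeRatio <- function(a, b) {
  if (a@slope >= 0 || b@slope >= 0)
    stop("slopeRatio expects two negative decay slopes")
  if (b@slope == 0) stop("zero denominator slope")
  abs(a@slope) / abs(b@slope)
}
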