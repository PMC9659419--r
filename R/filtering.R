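#' Remove vOTUs detected in fewer than two samples
#'
#' Drops every vOTU with nonzero abundance in exactly one sample (and any
#' vOTU detected in none), matching the final-dataset rule that vOTUs
#' exclusively detected in single viromes are excluded. Idempotent.
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param ... unused.
#' @return object of the same class with singleton vOTUs removed.
#' @export
setMethod("filterSingletonVOTUs", "matrix", function(x, ...) {
  x[rowSums(x > 0) >= 2, , drop = FALSE]
})

#' @rdname filterSingletonVOTUs
#' @export
setMethod("filterSingletonVOTUs", "ViromeExperiment", function(x, ...) {
  x[rowSums(abundances(x) > 0) >= 2, ]
})

.lowRecovery <- function(m, minFractionOfMedian) {
  if (minFractionOfMedian <= 0 || minFractionOfMedian >= 1)
    stop("minFractionOfMedian must lie strictly between 0 and 1")
  counts <- colSums(m > 0)
  cut <- minFractionOfMedian * stats::median(counts)
  removed <- colnames(m)[counts < cut]
  if (length(removed) == ncol(m))
    stop("all samples fall below the recovery cutoff")
  removed
}

#' Remove viromes with poor vOTU recovery
#'
#' Computes the number of detected vOTUs per sample and removes samples whose
#' count falls below `minFractionOfMedian` times the median count. The
#' default 0.25 reproduces the removal of a 136-vOTU virome against a median
#' recovery of 1,562 vOTUs.
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param minFractionOfMedian fraction of the median detected-vOTU count
#'   below which a sample is dropped; strictly between 0 and 1.
#' @param ... unused.
#' @return list with `x` (the filtered object) and `removed` (sample ids).
#' @export
setMethod("filterLowRecoverySamples", "matrix",
  function(x, minFractionOfMedian = 0.25, ...) {
    removed <- .lowRecovery(x, minFractionOfMedian)
    list(x = x[, !colnames(x) %in% removed, drop = FALSE], removed = removed)
  })

#' @rdname filterLowRecoverySamples
#' @export
setMethod("filterLowRecoverySamples", "ViromeExperiment",
  function(x, minFractionOfMedian = 0.25, ...) {
    removed <- .lowRecovery(abundances(x), minFractionOfMedian)
    list(x = x[, !colnames(x) %in% removed], removed = removed)
  })

#' Convert abundances to per-sample relative abundances
#'
#' Divides each sample column by its sum, so every column sums to 1.
#' Idempotent up to numerical precision.
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param ... unused.
#' @return object of the same class on the relative-abundance scale.
#' @export
setMethod("relativeAbundance", "matrix", function(x, ...) {
  sums <- colSums(x)
  bad <- sums <= 0
  if (any(bad))
    stop("zero-sum sample(s): ", paste(colnames(x)[bad], collapse = ", "))
  sweep(x, 2, sums, "/")
})

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "ViromeExperiment", function(x, ...) {
  ViromeExperiment(relativeAbundance(abundances(x)),
                   metadata = as.data.frame(SummarizedExperiment::colData(x)),
                   kind = x@kind)
})

#' Log-transform relative abundances
#'
#' Applies `t(x) = ln(1 + scale * x)` elementwise. With the default
#' `scale = 100` the argument is a percentage, zeros map to zero, and the
#' transform is strictly monotone, so detection patterns and ranks are
#' preserved.
#'
#' @param x a relative-abundance matrix or [ViromeExperiment-class].
#' @param scale multiplier applied before `log1p`; default 100.
#' @param ... unused.
#' @return transformed object of the same class.
#' @export
setMethod("logTransform", "matrix", function(x, scale = 100, ...) {
  if (any(x < 0)) stop("logTransform requires non-negative input")
  log1p(scale * x)
})

#' @rdname logTransform
#' @export
setMethod("logTransform", "ViromeExperiment", function(x, scale = 100, ...) {
  ViromeExperiment(logTransform(abundances(x), scale),
                   metadata = as.data.frame(SummarizedExperiment::colData(x)),
                   kind = x@kind)
})

#' Per-vOTU occupancy
#'
#' Fraction of samples in which each vOTU is detected (nonzero abundance).
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param ... unused.
#' @return named numeric vector in \[0, 1\].
#' @export
setMethod("occupancy", "matrix", function(x, ...) rowMeans(x > 0))

#' @rdname occupancy
#' @export
setMethod("occupancy", "ViromeExperiment",
          function(x, ...) rowMeans(abundances(x) > 0))

#' Prevalent vOTUs
#'
#' vOTUs detected in at least `threshold` of the samples (inclusive bound:
#' an occupancy of exactly 0.9 qualifies at the default threshold).
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param threshold occupancy threshold in (0, 1\].
#' @param ... unused.
#' @return character vector of vOTU ids.
#' @export
setMethod("prevalentVOTUs", "ANY", function(x, threshold = 0.9, ...) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  occ <- occupancy(x)
  names(occ)[occ >= threshold]
})
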