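#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ViromeExperiment: vOTU abundances with sample metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' vOTU x sample abundance matrix (trimmed-mean coverage or raw mapped-read
#' counts) in the `"abundance"` assay, with per-sample field metadata
#' (plot id, plot-center coordinates in meters, block, timepoint, treatment,
#' optional gravimetric moisture) in `colData`.
#'
#' The validity method enforces the table contract: non-negative finite
#' abundances, unique vOTU and sample identifiers, `timepoint` in
#' \{T1, T2\} and `treatment` in \{100, 50\} when those columns are present.
#'
#' @slot kind character, `"trimmed_mean"` or `"count"`.
#' @export
setClass("ViromeExperiment",
  contains = "SummarizedExperiment",
  slots = c(kind = "character")
)

setValidity("ViromeExperiment", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(!is.finite(a))) msg <- c(msg, "abundances must be finite")
  else if (any(a < 0)) msg <- c(msg, "abundances must be non-negative")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate vOTU ids")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  if (!object@kind %in% c("trimmed_mean", "count"))
    msg <- c(msg, "kind must be 'trimmed_mean' or 'count'")
  cd <- SummarizedExperiment::colData(object)
  if ("timepoint" %in% colnames(cd) &&
      !all(cd$timepoint %in% c("T1", "T2")))
    msg <- c(msg, "timepoint must be 'T1' or 'T2'")
  if ("treatment" %in% colnames(cd) &&
      !all(as.character(cd$treatment) %in% c("100", "50")))
    msg <- c(msg, "treatment must be 100 or 50")
  if (length(msg)) msg else TRUE
})

#' Field layout of a plot-based rainfall-manipulation experiment
#'
#' Describes a two-block plot grid: an upper and a lower row of square plots
#' at fixed spacing, the rows separated by a block gap, with one or two
#' sampled subplots per plot and two collection timepoints. Mirrors the
#' geometry of rainfall-exclusion field trials (two precipitation regimes,
#' 100% and 50% of ambient).
#'
#' @slot plots data.frame with columns `plot_id`, `x`, `y` (meters, plot
#'   centers), `block`, `treatment`.
#' @slot samples data.frame with columns `sample_id`, `plot_id`, `x`, `y`,
#'   `block`, `timepoint`, `treatment`, `moisture`.
#' @slot blockGap numeric, meters between the two block rows.
#' @export
setClass("FieldLayout",
  slots = c(plots = "data.frame", samples = "data.frame", blockGap = "numeric")
)

setValidity("FieldLayout", function(object) {
  msg <- character()
  p <- object@plots; s <- object@samples
  if (anyDuplicated(p$plot_id)) msg <- c(msg, "plot ids must be unique")
  if (any(!is.finite(p$x)) || any(!is.finite(p$y)))
    msg <- c(msg, "plot coordinates must be finite")
  if (anyDuplicated(s$sample_id)) msg <- c(msg, "sample ids must be unique")
  if (!all(s$plot_id %in% p$plot_id))
    msg <- c(msg, "every sample must reference an existing plot")
  if (!all(s$timepoint %in% c("T1", "T2")))
    msg <- c(msg, "timepoint must be 'T1' or 'T2'")
  if (length(msg)) msg else TRUE
})

#' Ground truth planted by the synthetic-data generators
#'
#' Records the parameters used to plant structure in a simulated bundle so
#' recovery tests can compare estimates against them.
#'
#' @slot decayScale numeric, Gaussian spatial-kernel width sigma in meters.
#' @slot treatmentLogEffect numeric, log-scale abundance shift applied to
#'   indicator vOTUs in T2-50 samples (and its negative to depleted ones).
#' @slot indicatorIds character, vOTUs planted as enriched in T2-50.
#' @slot depletedIds character, vOTUs planted as depleted in T2-50.
#' @slot plantedModule character, network nodes forming the trait-enriched
#'   block (filled by [simulateGeneSharingNetwork()]).
#' @slot divergenceRate numeric, consensus-genotype flip rate per site per
#'   meter (filled by [simulateAlleleCounts()]).
#' @slot seed integer.
#' @export
setClass("SyntheticTruth",
  slots = c(decayScale = "numeric", treatmentLogEffect = "numeric",
            indicatorIds = "character", depletedIds = "character",
            plantedModule = "character", divergenceRate = "numeric",
            seed = "integer")
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (length(intersect(object@indicatorIds, object@depletedIds)))
    msg <- c(msg, "indicator and depleted sets must be disjoint")
  if (length(object@decayScale) && !is.na(object@decayScale) &&
      object@decayScale <= 0)
    msg <- c(msg, "decayScale must be positive")
  if (length(object@divergenceRate) && !is.na(object@divergenceRate) &&
      object@divergenceRate < 0)
    msg <- c(msg, "divergenceRate must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Gene-sharing network of viral genomes
#'
#' An undirected graph in which nodes are vOTUs (optionally joined by
#' reference genomes carrying a host-taxon label) and an edge indicates a
#' significant overlap in predicted protein content between two genomes. The
#' edge attribute `score` is the -log10 P value of the overlap, so larger
#' scores mean stronger evidence; [edgeWeights()] converts scores to path
#' weights by taking reciprocals.
#'
#' Vertex attributes used downstream: `trait` (`"enriched"`, `"depleted"` or
#' `"none"`), `is_reference` (logical), `host_taxon` (character, reference
#' nodes only).
#'
#' @slot graph an [igraph::igraph] object.
#' @export
setClass("GeneSharingNetwork", slots = c(graph = "ANY"))

setValidity("GeneSharingNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must be an igraph object")
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-edges are not allowed")
  if (igraph::ecount(g) > 0) {
    sc <- igraph::E(g)$score
    if (is.null(sc)) msg <- c(msg, "edges must carry a 'score' attribute")
    else if (any(!is.finite(sc)) || any(sc <= 0))
      msg <- c(msg, "edge scores must be finite and positive")
  }
  if (is.null(igraph::V(g)$name)) msg <- c(msg, "vertices must be named")
  if (length(msg)) msg else TRUE
})

#' Distance-decay regression fit
#'
#' Pearson correlation and ordinary least-squares fit of pairwise community
#' similarity (1 - Bray-Curtis) against pairwise spatial distance, over the
#' retained unordered sample pairs (by default only same-timepoint pairs).
#'
#' @slot r Pearson correlation coefficient.
#' @slot slope OLS slope, similarity units per meter.
#' @slot intercept OLS intercept.
#' @slot pValue two-sided P value of the correlation test.
#' @slot nPairs number of unordered pairs used.
#' @export
setClass("DecayFit",
  slots = c(r = "numeric", slope = "numeric", intercept = "numeric",
            pValue = "numeric", nPairs = "integer")
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "r must lie in [-1, 1]")
  if (object@nPairs < 3L) msg <- c(msg, "at least 3 pairs are required")
  if (length(msg)) msg else TRUE
})

#' Principal coordinates ordination
#'
#' Classical metric scaling of a distance matrix. Only positive-eigenvalue
#' axes are retained; `percentVariance` is each retained eigenvalue as a
#' percentage of the positive-eigenvalue total, so it sums to 100. Negative
#' eigenvalues (Bray-Curtis is a semimetric) are reported but excluded from
#' the variance decomposition, and no correction is applied.
#'
#' @slot coordinates sample x axis matrix.
#' @slot eigenvalues all eigenvalues, sorted descending.
#' @slot percentVariance percent variance per retained axis.
#' @slot truncated TRUE when fewer axes than requested were available.
#' @export
setClass("Ordination",
  slots = c(coordinates = "matrix", eigenvalues = "numeric",
            percentVariance = "numeric", truncated = "logical")
)

setValidity("Ordination", function(object) {
  if (length(object@percentVariance) &&
      abs(sum(object@percentVariance) - 100) > 1e-6)
    "percentVariance must sum to 100 over retained axes" else TRUE
})

#' Per-position allele counts of one vOTU in one sample
#'
#' Sparse pileup: only positions with at least one mapped read are stored.
#' Column order of `counts` is fixed to A, C, G, T; this order also breaks
#' consensus-allele ties deterministically in [callSites()].
#'
#' @slot votuId,sampleId identifiers.
#' @slot genomeLength genome length in bp.
#' @slot positions integer vector of 1-based positions with coverage.
#' @slot counts integer matrix, one row per position, columns A/C/G/T.
#' @export
setClass("AlleleCountProfile",
  slots = c(votuId = "character", sampleId = "character",
            genomeLength = "integer", positions = "integer",
            counts = "matrix")
)

setValidity("AlleleCountProfile", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@positions))
    msg <- c(msg, "counts must have one row per position")
  if (!identical(colnames(object@counts), c("A", "C", "G", "T")))
    msg <- c(msg, "counts columns must be A, C, G, T")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@positions) &&
      (min(object@positions) < 1L ||
       max(object@positions) > object@genomeLength))
    msg <- c(msg, "positions must lie in [1, genomeLength]")
  if (length(msg)) msg else TRUE
})

#' Per-sample consensus profile of one vOTU
#'
#' Positions covered by at least `min_cov` reads, the consensus (most common)
#' allele at each, and which covered positions are polymorphic. Produced by
#' [callSites()] from per-position allele counts.
#'
#' @slot votuId,sampleId identifiers.
#' @slot genomeLength genome length in bp.
#' @slot covered integer vector of covered positions (1-based).
#' @slot consensus character vector of consensus alleles, parallel to
#'   `covered`.
#' @slot polymorphic integer vector, subset of `covered`.
#' @export
setClass("ConsensusProfile",
  slots = c(votuId = "character", sampleId = "character",
            genomeLength = "integer", covered = "integer",
            consensus = "character", polymorphic = "integer")
)

setValidity("ConsensusProfile", function(object) {
  msg <- character()
  if (length(object@consensus) != length(object@covered))
    msg <- c(msg, "consensus and covered must be parallel")
  if (!all(object@polymorphic %in% object@covered))
    msg <- c(msg, "polymorphic sites must be covered")
  if (length(object@covered) &&
      (min(object@covered) < 1L || max(object@covered) > object@genomeLength))
    msg <- c(msg, "positions must lie in [1, genomeLength]")
  if (length(msg)) msg else TRUE
})
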