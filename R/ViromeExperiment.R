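#' Construct a ViromeExperiment
#'
#' @param abundance vOTU x sample numeric matrix with row and column names.
#' @param metadata data.frame of per-sample metadata (one row per sample;
#'   rownames or a `sample_id` column matching `colnames(abundance)`), or
#'   `NULL`.
#' @param kind `"trimmed_mean"` (default) or `"count"`.
#'
#' @return A [ViromeExperiment-class] object.
#' @examples
#' m <- matrix(c(1, 0, 2, 3, 0, 4), nrow = 3,
#'             dimnames = list(paste0("v", 1:3), c("s1", "s2")))
#' ve <- ViromeExperiment(m)
#' @export
ViromeExperiment <- function(abundance, metadata = NULL,
                             kind = c("trimmed_mean", "count")) {
  kind <- match.arg(kind)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have vOTU rownames and sample colnames")
  if (is.null(metadata)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(abundance))
  } else {
    metadata <- as.data.frame(metadata)
    if ("sample_id" %in% colnames(metadata))
      rownames(metadata) <- metadata$sample_id
    missing <- setdiff(colnames(abundance), rownames(metadata))
    if (length(missing))
      stop("metadata missing samples: ", paste(missing, collapse = ", "))
    cd <- S4Vectors::DataFrame(metadata[colnames(abundance), , drop = FALSE])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd)
  new("ViromeExperiment", se, kind = kind)
}

#' @describeIn ViromeExperiment abundance matrix accessor.
#' @param x,object a `ViromeExperiment`.
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn ViromeExperiment sample metadata as a plain data.frame.
#' @export
sampleMetadata <- function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  df$sample_id <- colnames(x)
  df
}

#' @describeIn ViromeExperiment table kind (`"trimmed_mean"` or `"count"`).
#' @export
tableKind <- function(x) x@kind

setMethod("show", "ViromeExperiment", function(object) {
  cat("ViromeExperiment (", object@kind, ")\n", sep = "")
  cat(" ", nrow(object), "vOTUs x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd)) cat("  metadata:", paste(colnames(cd), collapse = ", "), "\n")
})

#' Logical grouping of samples into T2-50 vs the rest
#'
#' The low-moisture contrast used throughout: samples collected at the second
#' timepoint under the 50% precipitation regime form one group, all other
#' samples the other. Computed from metadata, never hand-supplied, so labels
#' cannot drift.
#'
#' @param meta a data.frame with `timepoint` and `treatment` columns, or a
#'   [ViromeExperiment-class].
#' @return factor with levels `"T2-50"` and `"rest"`, one element per sample.
#' @export
t250Groups <- function(meta) {
  if (is(meta, "ViromeExperiment")) meta <- sampleMetadata(meta)
  if (!all(c("timepoint", "treatment") %in% colnames(meta)))
    stop("metadata must contain 'timepoint' and 'treatment' columns")
  grp <- ifelse(meta$timepoint == "T2" & as.character(meta$treatment) == "50",
                "T2-50", "rest")
  factor(grp, levels = c("T2-50", "rest"))
}

setMethod("show", "FieldLayout", function(object) {
  cat("FieldLayout:", nrow(object@plots), "plots in",
      length(unique(object@plots$block)), "blocks (gap",
      object@blockGap, "m);", nrow(object@samples), "samples\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: decayScale =", object@decayScale,
      "m; treatmentLogEffect =", object@treatmentLogEffect, "\n")
  cat(" ", length(object@indicatorIds), "planted indicators,",
      length(object@depletedIds), "planted depleted,",
      length(object@plantedModule), "module nodes\n")
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: r = %.4f, slope = %.6g per m, p = %.3g (n = %d pairs)\n",
              object@r, object@slope, object@pValue, object@nPairs))
})

setMethod("show", "Ordination", function(object) {
  cat("Ordination:", nrow(object@coordinates), "samples,",
      ncol(object@coordinates), "axes retained\n")
  pv <- utils::head(object@percentVariance, 3)
  cat("  % variance:", paste(sprintf("%.1f", pv), collapse = ", "),
      if (length(object@percentVariance) > 3) "..." else "", "\n")
})

setMethod("show", "GeneSharingNetwork", function(object) {
  g <- object@graph
  nref <- sum(igraph::V(g)$is_reference %||% logical(igraph::vcount(g)))
  cat("GeneSharingNetwork:", igraph::vcount(g), "nodes (",
      nref, "reference ),", igraph::ecount(g), "edges\n")
})

setMethod("show", "ConsensusProfile", function(object) {
  cat("ConsensusProfile", object@votuId, "/", object@sampleId, ":",
      length(object@covered), "covered,",
      length(object@polymorphic), "polymorphic of",
      object@genomeLength, "bp\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn GeneSharingNetwork underlying igraph object.
#' @param x a `GeneSharingNetwork`.
#' @export
networkGraph <- function(x) x@graph

#' @describeIn GeneSharingNetwork node names excluding reference genomes.
#' @export
votuNodes <- function(x) {
  g <- x@graph
  isref <- igraph::V(g)$is_reference %||% logical(igraph::vcount(g))
  igraph::V(g)$name[!isref]
}

#' @describeIn GeneSharingNetwork named vector of node trait labels
#'   (`"enriched"`, `"depleted"`, `"none"`).
#' @export
nodeTraits <- function(x) {
  g <- x@graph
  tr <- igraph::V(g)$trait %||% rep("none", igraph::vcount(g))
  stats::setNames(tr, igraph::V(g)$name)
}
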