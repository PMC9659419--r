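#' Convert edge significance scores to path weights
#'
#' Edge scores are -log10 P values of protein-content overlaps, so larger
#' means stronger; taking reciprocals turns strong overlaps into short
#' edges for the weighted shortest-path computation.
#'
#' @param score positive numeric vector of edge scores.
#' @return `1 / score`.
#' @export
edgeWeights <- function(score) {
  if (any(!is.finite(score)) || any(score <= 0))
    stop("edge scores must be finite and positive")
  1 / score
}

#' Weighted shortest-path distances between all node pairs
#'
#' Dijkstra from every node over reciprocal-score edge weights (via
#' [igraph::distances()]). Unreachable pairs come back as `Inf` and are
#' excluded downstream.
#'
#' @param network a [GeneSharingNetwork-class].
#' @return symmetric numeric node x node matrix (0 diagonal, `Inf` for
#'   unreachable pairs).
#' @export
allPairsDistances <- function(network) {
  g <- network@graph
  w <- if (igraph::ecount(g) > 0) edgeWeights(igraph::E(g)$score) else numeric()
  igraph::distances(g, weights = w, algorithm = "dijkstra")
}

#' Neighborhood distance threshold from a pairwise-distance percentile
#'
#' The given percentile (default the first) of all finite unordered pairwise
#' shortest-path distances, self-distances excluded, by linear interpolation
#' of order statistics: with `n` sorted distances, `h = (n-1)p/100 + 1` and
#' the threshold interpolates between the `floor(h)`-th and `ceiling(h)`-th
#' values. Unreachable (infinite) pairs are excluded so disconnected
#' components cannot dominate the distribution.
#'
#' @param distances node x node matrix from [allPairsDistances()].
#' @param percentile percentile in (0, 100\].
#' @return the threshold path length.
#' @export
neighborhoodThreshold <- function(distances, percentile = 1) {
  vals <- distances[lower.tri(distances)]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) stop("need at least 2 finite pairwise distances")
  stats::quantile(vals, percentile / 100, names = FALSE, type = 7)
}

#' Local neighborhoods below a path-length threshold
#'
#' For every focal node, the neighborhood is all nodes reachable by a
#' weighted shortest path strictly shorter than the threshold; the focal
#' node itself (distance 0) is always a member, which keeps membership
#' symmetric (`u` in N(`v`) iff `v` in N(`u`)). Neighborhoods smaller than
#' `minSize` are not tested but are returned in the `skipped` element.
#'
#' @param distances node x node matrix from [allPairsDistances()].
#' @param threshold path-length threshold (> 0), e.g. from
#'   [neighborhoodThreshold()].
#' @param minSize minimum neighborhood size to qualify for testing.
#' @return list with `neighborhoods` (named list of member-id vectors) and
#'   `skipped` (same structure for undersized ones).
#' @export
localNeighborhoods <- function(distances, threshold, minSize = 10) {
  if (!(threshold > 0)) stop("threshold must be positive")
  ids <- rownames(distances)
  members <- lapply(seq_along(ids),
                    function(i) ids[distances[i, ] < threshold])
  names(members) <- ids
  sizes <- lengths(members)
  list(neighborhoods = members[sizes >= minSize],
       skipped = members[sizes < minSize])
}

#' Upper-tail hypergeometric probability
#'
#' Exact `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` - drawing `n` nodes
#' from a universe of `N` containing `K` trait carriers - computed by direct
#' summation of the probability mass from `k` to `min(n, K)` on the
#' log-binomial scale. `tail = "gt"` gives the `P(X > k)` variant instead.
#'
#' @param k observed trait carriers in the draw.
#' @param n draw (neighborhood) size.
#' @param K trait carriers in the universe.
#' @param N universe size.
#' @param tail `"ge"` for `P(X >= k)` (default), `"gt"` for `P(X > k)`.
#' @return probability in \[0, 1\].
#' @examples
#' hypergeomUpper(4, 6, 5, 20)  # 540 / 38760
#' @export
hypergeomUpper <- function(k, n, K, N, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  if (any(c(k, n, K, N) < 0) || k > n || n > N || K > N || k > K)
    stop("inconsistent counts: need 0 <= k <= n <= N and k <= K <= N")
  lo <- if (tail == "ge") k else k + 1
  hi <- min(n, K)
  if (lo > hi) return(if (lo <= 0) 1 else 0)
  i <- lo:hi
  p <- sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
  min(1, max(0, p))
}

#' Local-neighborhood trait-enrichment scan
#'
#' The full overrepresentation analysis on a gene-sharing network: edge
#' scores are converted to reciprocal weights, all-pairs weighted shortest
#' paths computed, the neighborhood threshold set at the given percentile of
#' finite pairwise distances, local neighborhoods extracted, undersized ones
#' discarded, and each qualifying neighborhood tested for overrepresentation
#' of each trait with an upper-tail hypergeometric test (`N` = all vOTU
#' nodes in the network, `K` = trait carriers among them, `n` = neighborhood
#' size, `k` = carriers in the neighborhood). Holm correction is applied per
#' trait across the qualifying neighborhoods; a neighborhood is significant
#' when its Holm-adjusted P falls below `alpha`. Reference-genome nodes are
#' excluded from the scan universe.
#'
#' @param network a [GeneSharingNetwork-class].
#' @param traits optional named vector of `"enriched"`/`"depleted"`/`"none"`
#'   per node; defaults to the network's `trait` vertex attribute.
#' @param percentile pairwise-distance percentile for the threshold.
#' @param minSize minimum neighborhood size (default 10).
#' @param alpha family-wise significance level.
#' @param tail hypergeometric tail convention, see [hypergeomUpper()].
#' @return data.frame with one row per qualifying neighborhood and trait:
#'   `focal, trait, k, n, K, N, p_raw, p_holm, significant`, plus
#'   attributes `threshold`, `neighborhoods`, `skipped`.
#' @export
enrichmentScan <- function(network, traits = NULL, percentile = 1,
                           minSize = 10, alpha = 0.05,
                           tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  g <- network@graph
  isref <- igraph::V(g)$is_reference %||% logical(igraph::vcount(g))
  if (any(isref))
    g <- igraph::induced_subgraph(g, igraph::V(g)[!isref])
  net <- new("GeneSharingNetwork", graph = g)
  if (is.null(traits)) traits <- nodeTraits(net)
  ids <- igraph::V(g)$name
  if (!all(ids %in% names(traits)))
    stop("traits must be defined for every node")
  traits <- traits[ids]

  D <- allPairsDistances(net)
  thr <- neighborhoodThreshold(D, percentile)
  nb <- localNeighborhoods(D, thr, minSize)
  N <- length(ids)
  out <- list()
  for (trait in c("enriched", "depleted")) {
    carriers <- ids[traits == trait]
    K <- length(carriers)
    rows <- lapply(names(nb$neighborhoods), function(focal) {
      mem <- nb$neighborhoods[[focal]]
      k <- sum(mem %in% carriers)
      data.frame(focal = focal, trait = trait, k = k, n = length(mem),
                 K = K, N = N,
                 p_raw = hypergeomUpper(k, length(mem), K, N, tail),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(focal = character(), trait = character(),
                       k = integer(), n = integer(), K = integer(),
                       N = integer(), p_raw = numeric())
    df$p_holm <- stats::p.adjust(df$p_raw, method = "holm")
    df$significant <- df$p_holm < alpha
    out[[trait]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  attr(res, "neighborhoods") <- nb$neighborhoods
  attr(res, "skipped") <- nb$skipped
  res
}

#' Subnetwork induced by significant neighborhoods
#'
#' Union of the member sets of all neighborhoods significant for the given
#' trait, returned as the induced subgraph (with node trait labels carried
#' over). An empty scan yields an empty subnetwork, not an error.
#'
#' @param results data.frame from [enrichmentScan()] (with its
#'   `neighborhoods` attribute intact).
#' @param network the scanned [GeneSharingNetwork-class].
#' @param trait which trait's significant neighborhoods to merge.
#' @return list with `nodes` (character) and `subnetwork`
#'   (a [GeneSharingNetwork-class]).
#' @export
significantSubnetwork <- function(results, network, trait = "enriched") {
  nb <- attr(results, "neighborhoods")
  if (is.null(nb)) stop("results must carry the neighborhoods attribute")
  sig <- results$focal[results$trait == trait & results$significant]
  nodes <- unique(unlist(nb[sig], use.names = FALSE))
  if (is.null(nodes)) nodes <- character()
  g <- network@graph
  sub <- igraph::induced_subgraph(g, igraph::V(g)[igraph::V(g)$name %in% nodes])
  list(nodes = nodes, subnetwork = new("GeneSharingNetwork", graph = sub))
}

#' Host-taxon links of subnetwork vOTUs via adjacent reference genomes
#'
#' For each vOTU in a trait subnetwork, collects the host taxa of the
#' reference genomes directly adjacent to it in the full network, and
#' summarizes how exclusively the linked vOTUs point to a single taxon (the
#' pattern expected when a trait subnetwork is dominated by phages of one
#' host phylum).
#'
#' @param nodes character vector of subnetwork vOTU ids.
#' @param network the full [GeneSharingNetwork-class] including reference
#'   nodes with a `host_taxon` vertex attribute.
#' @return list with `perNode` (data.frame `votu_id, host_taxa, exclusive`),
#'   `fractionExclusive` (of reference-linked vOTUs), and `linkedTaxa`
#'   (table of taxa over all links).
#' @export
annotateReferenceLinks <- function(nodes, network) {
  g <- network@graph
  isref <- igraph::V(g)$is_reference %||% logical(igraph::vcount(g))
  refNames <- igraph::V(g)$name[isref]
  hostTaxa <- stats::setNames(igraph::V(g)$host_taxon[isref], refNames)
  perNode <- lapply(nodes, function(v) {
    if (!v %in% igraph::V(g)$name)
      return(data.frame(votu_id = v, host_taxa = "", exclusive = NA))
    nbrs <- igraph::neighbors(g, v)$name
    taxa <- sort(unique(hostTaxa[intersect(nbrs, refNames)]))
    data.frame(votu_id = v, host_taxa = paste(taxa, collapse = ";"),
               exclusive = if (length(taxa)) length(taxa) == 1 else NA,
               stringsAsFactors = FALSE)
  })
  perNode <- do.call(rbind, perNode)
  linked <- perNode[!is.na(perNode$exclusive), , drop = FALSE]
  allTaxa <- unlist(strsplit(linked$host_taxa, ";", fixed = TRUE))
  list(perNode = perNode,
       fractionExclusive = if (nrow(linked)) mean(linked$exclusive)
                           else NA_real_,
       linkedTaxa = table(allTaxa))
}
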