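#' Call covered and polymorphic sites and build a consensus profile
#'
#' A position is covered when its total read count reaches `minCov` (default
#' five reads, the variant-calling floor). A covered position is polymorphic
#' when the second-most-common allele reaches both `minMinorCount` reads and
#' a frequency of `minMinorFreq`. The consensus allele is the most common
#' allele; ties are broken by the fixed order A < C < G < T so results are
#' deterministic.
#'
#' @param p an [AlleleCountProfile-class].
#' @param minCov minimum total reads for a position to be covered.
#' @param minMinorFreq minimum minor-allele frequency.
#' @param minMinorCount minimum minor-allele read count.
#' @return a [ConsensusProfile-class].
#' @export
callSites <- function(p, minCov = 5, minMinorFreq = 0.05,
                      minMinorCount = 2) {
  stopifnot(is(p, "AlleleCountProfile"))
  if (minCov < 1) stop("minCov must be at least 1")
  counts <- p@counts
  total <- rowSums(counts)
  covered <- total >= minCov
  cc <- counts[covered, , drop = FALSE]
  if (nrow(cc)) {
    consIdx <- max.col(cc, ties.method = "first")
    rows <- seq_len(nrow(cc))
    rest <- cc
    rest[cbind(rows, consIdx)] <- -1L
    second <- rest[cbind(rows, max.col(rest, ties.method = "first"))]
    poly <- second >= minMinorCount & second / rowSums(cc) >= minMinorFreq
  } else {
    consIdx <- integer(0); poly <- logical(0)
  }
  new("ConsensusProfile", votuId = p@votuId, sampleId = p@sampleId,
      genomeLength = p@genomeLength,
      covered = p@positions[covered],
      consensus = c("A", "C", "G", "T")[consIdx],
      polymorphic = p@positions[covered][poly])
}

#' Percentage of polymorphic sites
#'
#' `100 * polymorphic / covered` positions of a consensus profile. The
#' denominator is the covered positions, not the genome length, so the
#' estimate is not biased downward for partially covered genomes.
#'
#' @param cp a [ConsensusProfile-class] with at least one covered position.
#' @return percentage in \[0, 100\].
#' @export
percentPolymorphic <- function(cp) {
  stopifnot(is(cp, "ConsensusProfile"))
  if (!length(cp@covered)) stop("no covered positions")
  100 * length(cp@polymorphic) / length(cp@covered)
}

#' Consensus ANI between two samples of one vOTU
#'
#' Compares the consensus alleles of the two profiles over their jointly
#' covered positions: `ani = matches / compared`. The record is reported
#' only when the compared fraction of the genome strictly exceeds
#' `minComparedFraction` (default 0.25, i.e. percent_genome_compared >
#' 0.25); otherwise `NULL` is returned. Symmetric in its arguments.
#'
#' @param a,b [ConsensusProfile-class] objects for the same vOTU.
#' @param minComparedFraction minimum (strict) fraction of the genome that
#'   must be jointly covered.
#' @return one-row data.frame with `votu_id, sample1, sample2, ani,
#'   compared_fraction, n_compared`, or `NULL` when suppressed.
#' @export
consensusANI <- function(a, b, minComparedFraction = 0.25) {
  stopifnot(is(a, "ConsensusProfile"), is(b, "ConsensusProfile"))
  if (a@votuId != b@votuId || a@genomeLength != b@genomeLength)
    stop("profiles must belong to the same vOTU")
  shared <- intersect(a@covered, b@covered)
  frac <- length(shared) / a@genomeLength
  if (!(frac > minComparedFraction)) return(NULL)
  matches <- sum(a@consensus[match(shared, a@covered)] ==
                 b@consensus[match(shared, b@covered)])
  data.frame(votu_id = a@votuId, sample1 = a@sampleId, sample2 = b@sampleId,
             ani = matches / length(shared), compared_fraction = frac,
             n_compared = length(shared), stringsAsFactors = FALSE)
}

#' All pairwise consensus-ANI records for a set of profiles
#'
#' Runs [callSites()] on every allele-count profile and [consensusANI()] on
#' every within-vOTU sample pair.
#'
#' @param profiles list of [AlleleCountProfile-class] (e.g. from
#'   [simulateAlleleCounts()] or [readPileups()]).
#' @param minCov,minMinorFreq,minMinorCount passed to [callSites()].
#' @param minComparedFraction passed to [consensusANI()].
#' @return data.frame of ANI records (possibly zero rows).
#' @export
pairwiseConsensusANI <- function(profiles, minCov = 5, minMinorFreq = 0.05,
                                 minMinorCount = 2,
                                 minComparedFraction = 0.25) {
  cps <- lapply(profiles, callSites, minCov = minCov,
                minMinorFreq = minMinorFreq, minMinorCount = minMinorCount)
  byVotu <- split(cps, vapply(cps, function(x) x@votuId, character(1)))
  out <- list()
  for (v in names(byVotu)) {
    ps <- byVotu[[v]]
    n <- length(ps)
    if (n < 2) next
    L <- ps[[1]]@genomeLength
    # consensus as integers over the full genome, 0 where not covered;
    # pairwise matches via one crossproduct per allele
    M <- matrix(0L, L, n)
    for (i in seq_len(n))
      M[ps[[i]]@covered, i] <- match(ps[[i]]@consensus, c("A", "C", "G", "T"))
    cov <- M > 0
    shared <- crossprod(cov)
    matches <- matrix(0, n, n)
    for (a in 1:4) matches <- matches + crossprod(M == a)
    frac <- shared / L
    samples <- vapply(ps, function(x) x@sampleId, character(1))
    keep <- which(lower.tri(shared) & frac > minComparedFraction,
                  arr.ind = TRUE)
    if (nrow(keep))
      out[[v]] <- data.frame(
        votu_id = v, sample1 = samples[keep[, 2]],
        sample2 = samples[keep[, 1]],
        ani = matches[keep] / shared[keep],
        compared_fraction = frac[keep], n_compared = shared[keep],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(votu_id = character(), sample1 = character(),
                      sample2 = character(), ani = numeric(),
                      compared_fraction = numeric(),
                      n_compared = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-vOTU correlation of consensus ANI with spatial distance
#'
#' For each vOTU of interest (typically the prevalent set), correlates the
#' pairwise consensus ANI values with the spatial distance between the
#' corresponding sample pairs, excluding cross-timepoint pairs (the same
#' masking rule as [distanceDecay()]). Pearson r with two-sided P, Holm
#' family-wise adjustment across all tested vOTUs. vOTUs whose ANI values
#' show no variation (all equal, e.g. all exactly 1) are reported with
#' status `"no_variation"` and are not tested; vOTUs with fewer than 3
#' usable pairs are reported as `"too_few_pairs"`.
#'
#' @param records ANI record data.frame from [pairwiseConsensusANI()].
#' @param space spatial `dist` over samples ([spatialDistance()]).
#' @param meta sample metadata with `sample_id` and `timepoint`.
#' @param votus vOTU ids to test (default: all in `records`).
#' @param sameTimepointOnly exclude cross-timepoint pairs (default TRUE).
#' @return data.frame with `votu_id, status, r, p_raw, p_holm, n_pairs`.
#' @export
aniDistanceScan <- function(records, space, meta, votus = NULL,
                            sameTimepointOnly = TRUE) {
  if (is.null(votus)) votus <- unique(records$votu_id)
  sp <- as.matrix(space)
  tp <- stats::setNames(meta$timepoint, meta$sample_id)
  rows <- lapply(votus, function(v) {
    rec <- records[records$votu_id == v, , drop = FALSE]
    if (sameTimepointOnly && nrow(rec))
      rec <- rec[tp[rec$sample1] == tp[rec$sample2], , drop = FALSE]
    if (nrow(rec) < 3)
      return(data.frame(votu_id = v, status = "too_few_pairs",
                        r = NA_real_, p_raw = NA_real_, n_pairs = nrow(rec)))
    if (stats::sd(rec$ani) == 0)
      return(data.frame(votu_id = v, status = "no_variation",
                        r = NA_real_, p_raw = NA_real_, n_pairs = nrow(rec)))
    d <- sp[cbind(rec$sample1, rec$sample2)]
    if (stats::sd(d) == 0)
      return(data.frame(votu_id = v, status = "degenerate_distance",
                        r = NA_real_, p_raw = NA_real_, n_pairs = nrow(rec)))
    ct <- stats::cor.test(rec$ani, d, alternative = "two.sided")
    data.frame(votu_id = v, status = "tested", r = unname(ct$estimate),
               p_raw = ct$p.value, n_pairs = nrow(rec))
  })
  res <- do.call(rbind, rows)
  res$p_holm <- NA_real_
  tested <- res$status == "tested"
  res$p_holm[tested] <- stats::p.adjust(res$p_raw[tested], method = "holm")
  res[, c("votu_id", "status", "r", "p_raw", "p_holm", "n_pairs")]
}

#' vOTUs with the most within-population variation
#'
#' vOTUs whose median pairwise consensus ANI falls strictly below the
#' threshold (default 0.995, i.e. median ANI < 99.5%).
#'
#' @param records ANI record data.frame from [pairwiseConsensusANI()].
#' @param medianAniThreshold strict upper bound on the median ANI.
#' @return character vector of vOTU ids.
#' @export
mostVariableVOTUs <- function(records, medianAniThreshold = 0.995) {
  med <- tapply(records$ani, records$votu_id, stats::median)
  names(med)[med < medianAniThreshold]
}
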