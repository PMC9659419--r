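#' Generate a two-block rainfall-manipulation field layout
#'
#' Builds the plot grid of a two-block field trial: an upper and a lower row
#' of square plots at fixed center-to-center spacing, rows separated by a
#' block gap. Defaults reproduce the geometry of a 16-plot site with a
#' nine-plot upper block and a seven-plot lower block of 1.8-m plots, blocks
#' 7.5 m apart. Half of the plots (rounded down) are assigned at random to
#' the 50% precipitation regime, the rest to 100%. Each plot receives one or
#' two sampled subplots (the same subplots at both timepoints T1 and T2), and
#' every sample gets a plausible gravimetric moisture value: wet at T1,
#' drier at T2, driest in T2 plots under the 50% regime.
#'
#' @param nUpper,nLower number of plots in the upper and lower rows.
#' @param blockGapM gap between the two rows, meters.
#' @param plotSpacingM center-to-center plot spacing, meters.
#' @param extraSampleProb probability that a plot carries a second subplot.
#' @param seed integer seed; the layout is deterministic given the seed.
#'
#' @return A [FieldLayout-class] object.
#' @examples
#' fl <- generateFieldLayout(9, 7, 7.5, 1.8, seed = 1)
#' @export
generateFieldLayout <- function(nUpper = 9, nLower = 7, blockGapM = 7.5,
                                plotSpacingM = 1.8, extraSampleProb = 0.45,
                                seed = 1) {
  if (nUpper < 1 || nLower < 1)
    stop("nUpper and nLower must be at least 1")
  if (blockGapM <= 0 || plotSpacingM <= 0)
    stop("blockGapM and plotSpacingM must be positive")
  set.seed(seed)
  nPlots <- nUpper + nLower
  plots <- data.frame(
    plot_id = sprintf("P%02d", seq_len(nPlots)),
    x = c(seq_len(nUpper) - 1, seq_len(nLower) - 1) * plotSpacingM,
    y = rep(c(blockGapM, 0), c(nUpper, nLower)),
    block = rep(c("upper", "lower"), c(nUpper, nLower)),
    stringsAsFactors = FALSE
  )
  treat <- rep("100", nPlots)
  treat[sample.int(nPlots, nPlots %/% 2)] <- "50"
  plots$treatment <- treat

  nSub <- 1L + stats::rbinom(nPlots, 1L, extraSampleProb)
  sub <- data.frame(
    plot_id = rep(plots$plot_id, nSub),
    sub = unlist(lapply(nSub, seq_len))
  )
  samples <- merge(
    data.frame(plot_id = rep(sub$plot_id, 2), sub = rep(sub$sub, 2),
               timepoint = rep(c("T1", "T2"), each = nrow(sub))),
    plots, by = "plot_id", sort = FALSE
  )
  samples <- samples[order(samples$timepoint, samples$plot_id, samples$sub), ]
  samples$sample_id <- sprintf("%s_%s_s%d", samples$plot_id,
                               samples$timepoint, samples$sub)
  base <- ifelse(samples$timepoint == "T1", 0.22,
                 ifelse(samples$treatment == "50", 0.06, 0.12))
  samples$moisture <- pmax(0.01, base + stats::rnorm(nrow(samples), 0, 0.01))
  samples <- samples[, c("sample_id", "plot_id", "x", "y", "block",
                         "timepoint", "treatment", "moisture")]
  rownames(samples) <- NULL
  new("FieldLayout", plots = plots, samples = samples, blockGap = blockGapM)
}

#' Simulate a vOTU abundance table with planted spatial and treatment structure
#'
#' Each vOTU is given a random preferred location inside the field's bounding
#' box and a lognormal baseline abundance. Its expected abundance in a sample
#' decays with the squared distance between the sample's plot center and the
#' preferred location under a Gaussian kernel of width `decayScale`,
#' multiplied by lognormal noise. A fraction of vOTUs are planted as
#' indicators: their abundance is multiplied by `exp(treatmentLogEffect)` in
#' T2-50 samples; an equally sized depleted set is multiplied by
#' `exp(-treatmentLogEffect)`. Finally, values below the `detectionQuantile`
#' quantile of the nonzero values are set to zero (the detection floor), so
#' per-vOTU occupancy spans a range as in real virome tables.
#'
#' @param layout a [FieldLayout-class].
#' @param nVotus number of vOTUs (at least 2).
#' @param decayScale Gaussian kernel width sigma, meters; `Inf` removes
#'   spatial structure.
#' @param treatmentLogEffect log-scale enrichment of indicator vOTUs in
#'   T2-50 samples.
#' @param fracIndicator fraction of vOTUs planted as indicators (and the
#'   same fraction as depleted); must lie in \[0, 0.5\].
#' @param noiseSd standard deviation of the lognormal cell noise (log scale).
#' @param detectionQuantile quantile of nonzero values used as the detection
#'   floor; 0 disables flooring.
#' @param seed integer seed.
#'
#' @return list with `experiment` (a [ViromeExperiment-class]) and `truth`
#'   (a [SyntheticTruth-class]).
#' @examples
#' fl <- generateFieldLayout(seed = 1)
#' sim <- simulateAbundanceTable(fl, nVotus = 50, seed = 1)
#' @export
simulateAbundanceTable <- function(layout, nVotus = 500, decayScale = 2,
                                   treatmentLogEffect = 1,
                                   fracIndicator = 0.05, noiseSd = 0.5,
                                   detectionQuantile = 0.2, seed = 1) {
  stopifnot(is(layout, "FieldLayout"))
  if (nVotus < 2) stop("nVotus must be at least 2")
  if (fracIndicator < 0 || fracIndicator > 0.5)
    stop("fracIndicator must lie in [0, 0.5]")
  if (!(decayScale > 0)) stop("decayScale must be positive")
  set.seed(seed)
  s <- layout@samples
  votuIds <- sprintf("vOTU_%04d", seq_len(nVotus))
  px <- stats::runif(nVotus, min(layout@plots$x), max(layout@plots$x))
  py <- stats::runif(nVotus, min(layout@plots$y), max(layout@plots$y))
  baseline <- stats::rlnorm(nVotus, meanlog = log(20), sdlog = 1)

  d2 <- outer(px, s$x, "-")^2 + outer(py, s$y, "-")^2
  kernel <- exp(-d2 / (2 * decayScale^2))  # decayScale = Inf -> flat kernel
  expected <- baseline * kernel
  noise <- if (noiseSd > 0)
    matrix(stats::rlnorm(nVotus * nrow(s), 0, noiseSd), nVotus) else 1
  vals <- expected * noise

  nInd <- round(fracIndicator * nVotus)
  indicatorIds <- votuIds[seq_len(nInd)]
  depletedIds <- if (nInd > 0) votuIds[nInd + seq_len(nInd)] else character()
  t250 <- s$timepoint == "T2" & s$treatment == "50"
  if (nInd > 0 && any(t250)) {
    vals[seq_len(nInd), t250] <-
      vals[seq_len(nInd), t250] * exp(treatmentLogEffect)
    vals[nInd + seq_len(nInd), t250] <-
      vals[nInd + seq_len(nInd), t250] * exp(-treatmentLogEffect)
  }

  if (detectionQuantile > 0) {
    floorVal <- stats::quantile(vals[vals > 0], detectionQuantile, names = FALSE)
    vals[vals < floorVal] <- 0
  }
  dimnames(vals) <- list(votuIds, s$sample_id)

  truth <- new("SyntheticTruth", decayScale = decayScale,
               treatmentLogEffect = treatmentLogEffect,
               indicatorIds = indicatorIds, depletedIds = depletedIds,
               plantedModule = character(), divergenceRate = NA_real_,
               seed = as.integer(seed))
  list(experiment = ViromeExperiment(vals, s, kind = "trimmed_mean"),
       truth = truth)
}

#' Simulate a gene-sharing network with a planted trait-enriched module
#'
#' Draws a stochastic-block-model graph, assigns each edge a significance
#' score (uniform on `scoreRange`, interpreted as -log10 P of a protein
#' content overlap), and designates the first block as the planted module:
#' its members carry the `"enriched"` trait with probability `enrichProb`
#' versus `backgroundProb` elsewhere. Nodes not enriched are labeled
#' `"depleted"` with probability `backgroundProb`, otherwise `"none"`.
#'
#' When `truth` carries planted indicator/depleted vOTU ids (from
#' [simulateAbundanceTable()]), node names are assigned so that
#' enriched-trait nodes take indicator ids and depleted-trait nodes take
#' depleted ids (as far as available), which ties the network module to the
#' abundance-level treatment effect for end-to-end tests.
#'
#' @param nVotus total number of nodes; must equal `sum(blockSizes)`.
#' @param blockSizes sizes of the stochastic blocks; block 1 is the module.
#' @param pWithin within-block edge probability; a scalar, or one value per
#'   block. The default makes the planted module the densest region of the
#'   network, so that - as in real gene-sharing networks - the sizeable
#'   local neighborhoods concentrate in one highly interconnected area.
#' @param pBetween between-block edge probability (< `min(pWithin)`).
#' @param truth optional [SyntheticTruth-class]; updated and returned.
#' @param enrichProb,backgroundProb trait probabilities inside and outside
#'   the planted module (`enrichProb > backgroundProb`).
#' @param scoreRange length-2 numeric, uniform range of edge scores.
#' @param seed integer seed.
#'
#' @return list with `network` (a [GeneSharingNetwork-class]) and `truth`.
#' @export
simulateGeneSharingNetwork <- function(nVotus = 500,
                                       blockSizes = c(50, rep(75, 6)),
                                       pWithin = c(0.9, rep(0.1, 6)),
                                       pBetween = 0.005,
                                       truth = NULL, enrichProb = 0.5,
                                       backgroundProb = 0.05,
                                       scoreRange = c(1, 20), seed = 1) {
  if (sum(blockSizes) != nVotus)
    stop("blockSizes must sum to nVotus")
  if (any(c(pWithin, pBetween, enrichProb, backgroundProb) < 0) ||
      any(c(pWithin, pBetween, enrichProb, backgroundProb) > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(pWithin <= pBetween)) stop("pWithin must exceed pBetween")
  if (!length(pWithin) %in% c(1L, length(blockSizes)))
    stop("pWithin must be a scalar or one value per block")
  if (enrichProb <= backgroundProb)
    stop("enrichProb must exceed backgroundProb")
  set.seed(seed)
  k <- length(blockSizes)
  pref <- matrix(pBetween, k, k); diag(pref) <- rep(pWithin, length.out = k)
  g <- igraph::sample_sbm(nVotus, pref.matrix = pref,
                          block.sizes = blockSizes, directed = FALSE)
  inModule <- seq_len(nVotus) <= blockSizes[1]
  pEnr <- ifelse(inModule, enrichProb, backgroundProb)
  trait <- ifelse(stats::runif(nVotus) < pEnr, "enriched", "none")
  isNone <- trait == "none"
  trait[isNone][stats::runif(sum(isNone)) < backgroundProb] <- "depleted"

  nodeNames <- sprintf("vOTU_%04d", seq_len(nVotus))
  if (!is.null(truth) &&
      (length(truth@indicatorIds) || length(truth@depletedIds))) {
    pool <- sprintf("vOTU_%04d", seq_len(nVotus))
    nodeNames <- rep(NA_character_, nVotus)
    enrIdx <- which(trait == "enriched")
    depIdx <- which(trait == "depleted")
    useEnr <- utils::head(truth@indicatorIds, length(enrIdx))
    useDep <- utils::head(truth@depletedIds, length(depIdx))
    nodeNames[utils::head(enrIdx, length(useEnr))] <- useEnr
    nodeNames[utils::head(depIdx, length(useDep))] <- useDep
    left <- setdiff(pool, c(useEnr, useDep))
    nodeNames[is.na(nodeNames)] <- left[seq_len(sum(is.na(nodeNames)))]
  }
  igraph::V(g)$name <- nodeNames
  igraph::V(g)$trait <- trait
  igraph::V(g)$is_reference <- FALSE
  if (igraph::ecount(g) > 0)
    igraph::E(g)$score <- stats::runif(igraph::ecount(g),
                                       scoreRange[1], scoreRange[2])
  if (is.null(truth))
    truth <- new("SyntheticTruth", decayScale = NA_real_,
                 treatmentLogEffect = NA_real_,
                 indicatorIds = character(), depletedIds = character(),
                 plantedModule = character(), divergenceRate = NA_real_,
                 seed = as.integer(seed))
  truth@plantedModule <- nodeNames[inModule]
  list(network = new("GeneSharingNetwork", graph = g), truth = truth)
}

#' Attach labeled reference genomes to a gene-sharing network
#'
#' Adds reference-genome nodes (host taxon known from isolation records) and
#' connects each to a few vOTU nodes. References labeled `moduleTaxon` attach
#' preferentially to planted-module nodes, emulating a trait subnetwork
#' dominated by phages of one host phylum; the remainder get random taxa and
#' random attachments.
#'
#' @param network a [GeneSharingNetwork-class].
#' @param moduleNodes character, nodes of the planted module.
#' @param nModuleRefs,nOtherRefs reference counts of each kind.
#' @param moduleTaxon host taxon of module-attached references.
#' @param otherTaxa candidate taxa for the remaining references.
#' @param edgesPerRef edges added per reference node.
#' @param scoreRange uniform range of the new edge scores.
#' @param seed integer seed.
#' @return the augmented [GeneSharingNetwork-class].
#' @export
simulateReferenceGenomes <- function(network, moduleNodes,
                                     nModuleRefs = 10, nOtherRefs = 10,
                                     moduleTaxon = "Actinobacteria",
                                     otherTaxa = c("Proteobacteria",
                                                   "Firmicutes"),
                                     edgesPerRef = 3, scoreRange = c(1, 20),
                                     seed = 1) {
  set.seed(seed)
  g <- network@graph
  nRef <- nModuleRefs + nOtherRefs
  refIds <- sprintf("REF_%03d", seq_len(nRef))
  taxa <- c(rep(moduleTaxon, nModuleRefs),
            sample(otherTaxa, nOtherRefs, replace = TRUE))
  g <- igraph::add_vertices(g, nRef, name = refIds, trait = "none",
                            is_reference = TRUE, host_taxon = taxa)
  votus <- setdiff(igraph::V(g)$name[!igraph::V(g)$is_reference], refIds)
  other <- setdiff(votus, moduleNodes)
  edges <- character(0)
  for (i in seq_len(nRef)) {
    pool <- if (i <= nModuleRefs) moduleNodes else other
    tgt <- sample(pool, min(edgesPerRef, length(pool)))
    edges <- c(edges, rbind(refIds[i], tgt))
  }
  g <- igraph::add_edges(g, edges,
                         score = stats::runif(length(edges) / 2,
                                              scoreRange[1], scoreRange[2]))
  new("GeneSharingNetwork", graph = g)
}

#' Simulate per-position allele counts with distance-dependent genotype drift
#'
#' Every vOTU gets a random reference genotype and a set of variant sites,
#' each with one alternative allele and one shared site-level uniform draw.
#' A sample's dominant genotype carries the alternative allele at site j
#' whenever that site's uniform falls below the sample's flip probability
#' `q_s = min(0.5, divergenceRate * (distance of the sample's plot from the
#' field origin) + noise)`. Coupling the flips through a shared uniform makes
#' the expected consensus mismatch fraction between two samples equal to
#' `|q_s - q_t|`, which grows with their spatial separation and yields the
#' ANI distance decay the analysis is designed to detect. Read counts per
#' position are Poisson around `meanCoverage`; at variant sites a minor
#' allele receives a binomial `minorFreq` share so polymorphic sites are
#' detectable, and non-variant sites are monomorphic.
#'
#' @param layout a [FieldLayout-class].
#' @param nVotus number of vOTUs to profile (emulating prevalent vOTUs:
#'   every sample covers every vOTU).
#' @param genomeLength genome length, bp.
#' @param nVariantSites number of variant sites per genome.
#' @param divergenceRate flip-probability slope, per site per meter.
#' @param meanCoverage mean read depth.
#' @param noiseSd sd of Gaussian noise added to the flip probability.
#' @param minorFreq expected minor-allele frequency at variant sites.
#' @param seed integer seed.
#'
#' @return list with `profiles` (list of [AlleleCountProfile-class], one per
#'   vOTU x sample), `genomeLength`, `flipProbs` (named per-sample vector of
#'   planted flip probabilities), and `truth`.
#' @export
simulateAlleleCounts <- function(layout, nVotus = 10, genomeLength = 1000,
                                 nVariantSites = 50, divergenceRate = 0.005,
                                 meanCoverage = 20, noiseSd = 0,
                                 minorFreq = 0.15, seed = 1) {
  stopifnot(is(layout, "FieldLayout"))
  if (nVariantSites > genomeLength)
    stop("nVariantSites must not exceed genomeLength")
  if (meanCoverage <= 0) stop("meanCoverage must be positive")
  if (divergenceRate < 0) stop("divergenceRate must be non-negative")
  set.seed(seed)
  s <- layout@samples
  alleles <- c("A", "C", "G", "T")
  distOrigin <- sqrt(s$x^2 + s$y^2)
  q <- pmin(0.5, pmax(0, divergenceRate * distOrigin +
                        if (noiseSd > 0) stats::rnorm(nrow(s), 0, noiseSd)
                        else 0))
  names(q) <- s$sample_id

  profiles <- list()
  for (v in seq_len(nVotus)) {
    votuId <- sprintf("vOTU_%04d", v)
    refSeq <- sample(alleles, genomeLength, replace = TRUE)
    varPos <- sort(sample.int(genomeLength, nVariantSites))
    altSeq <- refSeq
    if (nVariantSites > 0)
      altSeq[varPos] <- vapply(refSeq[varPos], function(a)
        sample(setdiff(alleles, a), 1), character(1))
    u <- stats::runif(nVariantSites)
    for (i in seq_len(nrow(s))) {
      dominant <- refSeq
      if (nVariantSites > 0) {
        flip <- u < q[i]
        dominant[varPos[flip]] <- altSeq[varPos[flip]]
      }
      cov <- stats::rpois(genomeLength, meanCoverage)
      counts <- matrix(0L, genomeLength, 4,
                       dimnames = list(NULL, alleles))
      domIdx <- match(dominant, alleles)
      counts[cbind(seq_len(genomeLength), domIdx)] <- cov
      if (nVariantSites > 0 && minorFreq > 0) {
        minorN <- stats::rbinom(nVariantSites, cov[varPos], minorFreq)
        minorAllele <- ifelse(dominant[varPos] == refSeq[varPos],
                              altSeq[varPos], refSeq[varPos])
        minIdx <- match(minorAllele, alleles)
        counts[cbind(varPos, match(dominant[varPos], alleles))] <-
          counts[cbind(varPos, match(dominant[varPos], alleles))] - minorN
        counts[cbind(varPos, minIdx)] <- counts[cbind(varPos, minIdx)] + minorN
      }
      keep <- rowSums(counts) > 0
      profiles[[paste(votuId, s$sample_id[i], sep = "|")]] <-
        new("AlleleCountProfile", votuId = votuId,
            sampleId = s$sample_id[i],
            genomeLength = as.integer(genomeLength),
            positions = which(keep),
            counts = counts[keep, , drop = FALSE])
    }
  }
  truth <- new("SyntheticTruth", decayScale = NA_real_,
               treatmentLogEffect = NA_real_,
               indicatorIds = character(), depletedIds = character(),
               plantedModule = character(),
               divergenceRate = divergenceRate, seed = as.integer(seed))
  list(profiles = profiles, genomeLength = as.integer(genomeLength),
       flipProbs = q, truth = truth)
}

#' Simulate a spatially structured soil-chemistry table
#'
#' Each variable is a random linear gradient over the field (random direction
#' and slope) plus Gaussian noise, on an arbitrary positive scale, so that
#' pairwise environmental distance correlates with spatial distance as
#' observed for edaphic gradients at plot scale.
#'
#' @param layout a [FieldLayout-class].
#' @param nVars number of chemistry variables.
#' @param noiseSd residual sd relative to the gradient magnitude.
#' @param seed integer seed.
#' @return data.frame, samples in rows (rownames = sample ids), variables in
#'   columns.
#' @export
simulateSoilChemistry <- function(layout, nVars = 6, noiseSd = 0.3,
                                  seed = 1) {
  stopifnot(is(layout, "FieldLayout"))
  set.seed(seed)
  s <- layout@samples
  out <- sapply(seq_len(nVars), function(j) {
    a <- stats::rnorm(2)
    grad <- a[1] * s$x + a[2] * s$y
    grad <- (grad - mean(grad)) / max(stats::sd(grad), 1e-9)
    10 + 2 * grad + stats::rnorm(nrow(s), 0, noiseSd)
  })
  colnames(out) <- sprintf("chem_%02d", seq_len(nVars))
  out <- as.data.frame(out)
  rownames(out) <- s$sample_id
  out
}

#' Write a complete simulated input bundle to disk
#'
#' Emits every input the pipeline consumes, in the dialects the readers
#' expect: tab-separated coverage and read-count tables (vOTU rows, sample
#' columns), a metadata CSV, a soil-chemistry CSV, a `node1,node2,score`
#' network edge list CSV, a long-format allele-count pileup TSV, and a JSON
#' file recording the planted ground truth.
#'
#' @param dir output directory (created if absent).
#' @param layout a [FieldLayout-class].
#' @param abundance result of [simulateAbundanceTable()].
#' @param network result of [simulateGeneSharingNetwork()] (or `NULL`).
#' @param alleles result of [simulateAlleleCounts()] (or `NULL`).
#' @param chemistry data.frame from [simulateSoilChemistry()] (or `NULL`).
#' @param readsPerCoverage Poisson scale converting coverage to read counts.
#' @param seed integer seed for the count draw.
#' @return named character vector of the files written.
#' @export
writeSimulationBundle <- function(dir, layout, abundance, network = NULL,
                                  alleles = NULL, chemistry = NULL,
                                  readsPerCoverage = 10, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  m <- abundances(abundance$experiment)
  covPath <- file.path(dir, "coverage.tsv")
  writeCoverageTable(m, covPath)
  files["coverage"] <- covPath

  set.seed(seed)
  counts <- matrix(stats::rpois(length(m), m * readsPerCoverage),
                   nrow(m), dimnames = dimnames(m))
  cntPath <- file.path(dir, "counts.tsv")
  writeCoverageTable(counts, cntPath)
  files["counts"] <- cntPath

  meta <- layout@samples
  colnames(meta)[colnames(meta) == "x"] <- "x_m"
  colnames(meta)[colnames(meta) == "y"] <- "y_m"
  metaPath <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, metaPath, row.names = FALSE, quote = FALSE)
  files["metadata"] <- metaPath

  if (!is.null(chemistry)) {
    chemPath <- file.path(dir, "chemistry.csv")
    utils::write.csv(cbind(sample_id = rownames(chemistry), chemistry),
                     chemPath, row.names = FALSE, quote = FALSE)
    files["chemistry"] <- chemPath
  }
  if (!is.null(network)) {
    netPath <- file.path(dir, "network_edges.csv")
    writeEdgeList(network$network, netPath)
    files["network"] <- netPath
  }
  if (!is.null(alleles)) {
    pilePath <- file.path(dir, "pileups.tsv")
    writePileups(alleles$profiles, pilePath)
    files["pileups"] <- pilePath
  }
  truthPath <- file.path(dir, "truth.json")
  tr <- abundance$truth
  if (!is.null(network)) tr@plantedModule <- network$truth@plantedModule
  if (!is.null(alleles)) tr@divergenceRate <- alleles$truth@divergenceRate
  jsonlite::write_json(list(
    decay_scale = tr@decayScale,
    treatment_log_effect = tr@treatmentLogEffect,
    indicator_ids = tr@indicatorIds,
    depleted_ids = tr@depletedIds,
    planted_module = tr@plantedModule,
    divergence_rate = tr@divergenceRate,
    seed = tr@seed
  ), truthPath, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  files["truth"] <- truthPath
  files
}
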