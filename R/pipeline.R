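.defaultConfig <- function() {
  list(
    seed = 1,
    output_dir = NULL,
    filters = list(min_recovery_frac = 0.25),
    transform = list(log_scale = 100),
    permanova = list(factor = "treatment", n_perm = 999),
    decay = list(same_timepoint_only = TRUE),
    indicator = list(n_perm = 999, alpha = 0.05),
    enrichment = list(percentile = 1, min_size = 10, alpha = 0.05,
                      tail = "ge")
  )
}

.mergeConfig <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) user[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      user[[nm]] <- .mergeConfig(user[[nm]], defaults[[nm]])
  }
  user
}

#' Load and normalize a run configuration
#'
#' Accepts a YAML file path or a plain list; fills in the documented
#' defaults (recorded later in the run manifest) and validates that either
#' input paths or a `simulate` block are present.
#'
#' @param config path to a YAML file, or a list.
#' @return normalized configuration list.
#' @export
loadRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- .mergeConfig(config, .defaultConfig())
  if (is.null(cfg$inputs) && is.null(cfg$simulate))
    stop("config needs an 'inputs' block or a 'simulate' block")
  cfg
}

.resolveInputs <- function(cfg, needNetwork = FALSE) {
  if (!is.null(cfg$simulate)) {
    sb <- cfg$simulate
    layoutArgs <- sb$layout %||% list()
    layout <- do.call(generateFieldLayout,
                      c(layoutArgs, list(seed = cfg$seed)))
    abArgs <- sb[intersect(names(sb),
                           c("nVotus", "decayScale", "treatmentLogEffect",
                             "fracIndicator", "noiseSd",
                             "detectionQuantile"))]
    sim <- do.call(simulateAbundanceTable,
                   c(list(layout = layout, seed = cfg$seed), abArgs))
    net <- NULL
    if (needNetwork || !is.null(sb$network)) {
      netArgs <- sb$network %||% list()
      netArgs$nVotus <- netArgs$nVotus %||% nrow(sim$experiment)
      net <- do.call(simulateGeneSharingNetwork,
                     c(netArgs, list(truth = sim$truth, seed = cfg$seed)))
      sim$truth <- net$truth
    }
    chem <- simulateSoilChemistry(layout, seed = cfg$seed)
    list(ve = sim$experiment, chem = chem,
         network = if (!is.null(net)) net$network else NULL,
         truth = sim$truth)
  } else {
    inp <- cfg$inputs
    if (is.null(inp$coverage) || is.null(inp$metadata))
      stop("inputs block must name 'coverage' and 'metadata' files")
    meta <- readSampleMetadata(inp$metadata)
    ve <- readCoverageTable(inp$coverage, metadata = meta)
    chem <- if (!is.null(inp$chemistry)) readSoilChemistry(inp$chemistry)
            else NULL
    net <- if (!is.null(inp$network)) readEdgeList(inp$network) else NULL
    if (needNetwork && is.null(net))
      stop("this analysis requires a 'network' input")
    list(ve = ve, chem = chem, network = net, truth = NULL)
  }
}

.writeManifest <- function(cfg, stages, dir) {
  if (is.null(dir)) return(invisible(NULL))
  manifest <- list(package_version = as.character(
                     utils::packageVersion("viroscape")),
                   config = cfg, stages = stages)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE, force = TRUE)
}

#' Run the spatial beta-diversity analysis
#'
#' Executes the spatial arm of the study on an input bundle (or a simulated
#' one): singleton-vOTU and low-recovery-sample filtering, relative
#' abundance and log transform, Bray-Curtis dissimilarities, PCoA, a
#' one-factor PERMANOVA, the same-timepoint distance-decay fit, and the
#' correlations of spatial distance with community overlap and (when soil
#' chemistry is available) environmental distance. Row counts after every
#' filter are logged in the manifest, and all outputs are written as tidy
#' CSVs plus a JSON manifest of every applied parameter, so a rerun with
#' the same config is byte-identical.
#'
#' @param config list or YAML path, see [loadRunConfig()].
#' @return list with the fitted objects (`decay`, `permanova`, `pcoa`,
#'   `correlations`, `filtered`, `truth`) and the output directory.
#' @export
runSpatialAnalysis <- function(config) {
  cfg <- loadRunConfig(config)
  inputs <- .resolveInputs(cfg)
  ve <- inputs$ve
  stages <- list(input = dim(ve))

  ve <- filterSingletonVOTUs(ve)
  stages$after_singleton_filter <- dim(ve)
  lr <- filterLowRecoverySamples(ve, cfg$filters$min_recovery_frac)
  ve <- lr$x
  stages$after_recovery_filter <- dim(ve)
  stages$removed_samples <- lr$removed

  rel <- relativeAbundance(ve)
  lt <- logTransform(rel, scale = cfg$transform$log_scale)
  bc <- brayCurtis(lt)
  meta <- sampleMetadata(ve)
  space <- spatialDistance(meta)

  ord <- runPCoA(bc, nAxes = 2)
  grp <- meta[[cfg$permanova$factor]]
  perm <- permanovaTest(bc, grp, nPerm = cfg$permanova$n_perm,
                        seed = cfg$seed)
  decay <- distanceDecay(bc, space, meta,
                         sameTimepointOnly = cfg$decay$same_timepoint_only)
  mask <- sameTimepointMask(meta, labels = colnames(ve))
  overlap <- communityOverlap(ve)
  corrs <- list(
    overlap_vs_space = matrixCorrelation(overlap, space, mask))
  if (!is.null(inputs$chem)) {
    chem <- inputs$chem[colnames(ve), , drop = FALSE]
    corrs$environment_vs_space <-
      matrixCorrelation(environmentalDistance(chem), space, mask)
  }

  dir <- cfg$output_dir
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeDistanceMatrix(bc, file.path(dir, "bray_curtis.csv"))
    utils::write.csv(data.frame(sample_id = rownames(ord@coordinates),
                                ord@coordinates, check.names = FALSE),
                     file.path(dir, "pcoa_coordinates.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(
      term = c(cfg$permanova$factor, "decay"),
      stat = c(perm$pseudoF, decay@slope),
      r = c(NA, decay@r), p = c(perm$p, decay@pValue),
      n = c(ncol(ve), decay@nPairs)),
      file.path(dir, "spatial_stats.csv"), row.names = FALSE, quote = FALSE)
    .writeManifest(cfg, stages, dir)
  }
  list(decay = decay, permanova = perm, pcoa = ord, correlations = corrs,
       filtered = ve, truth = inputs$truth, stages = stages,
       output_dir = dir)
}

#' Run the soil-moisture response analysis
#'
#' Executes the moisture arm: the T2-50 grouping is derived from metadata
#' (second timepoint, 50% precipitation regime), vOTUs are tested with the
#' IndVal permutation test, the resulting enriched/depleted trait labels are
#' projected onto the gene-sharing network, the local-neighborhood
#' hypergeometric enrichment scan is run with Holm control, the significant
#' trait subnetwork is extracted, and (when reference genomes are present)
#' its vOTUs are annotated with linked host taxa.
#'
#' @param config list or YAML path, see [loadRunConfig()]; a network input
#'   (or simulate block) is required.
#' @return list with `indicator`, `scan`, `subnetwork`, `hostLinks`,
#'   `traits`, `truth`, and the output directory.
#' @export
runMoistureAnalysis <- function(config) {
  cfg <- loadRunConfig(config)
  inputs <- .resolveInputs(cfg, needNetwork = TRUE)
  ve <- inputs$ve
  stages <- list(input = dim(ve))
  ve <- filterSingletonVOTUs(ve)
  lr <- filterLowRecoverySamples(ve, cfg$filters$min_recovery_frac)
  ve <- lr$x
  stages$after_filters <- dim(ve)

  groups <- t250Groups(ve)
  if (!all(table(groups) > 0))
    stop("metadata does not yield both T2-50 and rest samples")
  rel <- relativeAbundance(ve)
  ind <- indvalTest(rel, groups, nPerm = cfg$indicator$n_perm,
                    seed = cfg$seed, alpha = cfg$indicator$alpha)
  stages$n_enriched <- sum(ind$call == "enriched")
  stages$n_depleted <- sum(ind$call == "depleted")

  net <- inputs$network
  traits <- stats::setNames(rep("none", length(igraph::V(net@graph))),
                            igraph::V(net@graph)$name)
  hit <- intersect(ind$votu_id, names(traits))
  traits[hit] <- ind$call[match(hit, ind$votu_id)]
  scan <- enrichmentScan(net, traits = traits,
                         percentile = cfg$enrichment$percentile,
                         minSize = cfg$enrichment$min_size,
                         alpha = cfg$enrichment$alpha,
                         tail = cfg$enrichment$tail)
  sub <- significantSubnetwork(scan, net, trait = "enriched")
  isref <- igraph::V(net@graph)$is_reference %||%
    logical(length(igraph::V(net@graph)))
  hostLinks <- if (any(isref)) annotateReferenceLinks(sub$nodes, net)
               else NULL

  dir <- cfg$output_dir
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ind, file.path(dir, "indicator_results.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(scan, file.path(dir, "enrichment_results.csv"),
                     row.names = FALSE, quote = FALSE)
    if (length(sub$nodes))
      writeEdgeList(sub$subnetwork, file.path(dir, "subnetwork_edges.csv"))
    utils::write.csv(data.frame(node = names(traits), trait = traits),
                     file.path(dir, "node_traits.csv"),
                     row.names = FALSE, quote = FALSE)
    .writeManifest(cfg, stages, dir)
  }
  list(indicator = ind, scan = scan, subnetwork = sub,
       hostLinks = hostLinks, traits = traits, truth = inputs$truth,
       stages = stages, output_dir = dir)
}
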