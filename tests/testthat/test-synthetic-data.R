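test_that("field layout reproduces the two-block plot geometry", {
  fl <- generateFieldLayout(9, 7, 7.5, 1.8, seed = 1)
  expect_equal(nrow(fl@plots), 16)
  upper <- fl@plots[fl@plots$block == "upper", ]
  expect_equal(max(upper$x) - min(upper$x), 8 * 1.8)
  lower <- fl@plots[fl@plots$block == "lower", ]
  expect_equal(max(lower$x) - min(lower$x), 6 * 1.8)
  expect_equal(unique(upper$y) - unique(lower$y), 7.5)

  tiny <- generateFieldLayout(1, 1, 7.5, 1.8, seed = 1)
  expect_equal(abs(diff(tiny@plots$y)), 7.5)
  expect_equal(diff(tiny@plots$x), 0)

  expect_identical(generateFieldLayout(9, 7, seed = 4),
                   generateFieldLayout(9, 7, seed = 4))
  expect_error(generateFieldLayout(0, 7), "at least 1")
  expect_error(generateFieldLayout(9, 7, blockGapM = -1), "positive")
})

test_that("layout samples reference plots and span both timepoints", {
  fl <- generateFieldLayout(seed = 3)
  s <- fl@samples
  expect_true(all(s$plot_id %in% fl@plots$plot_id))
  expect_setequal(unique(s$timepoint), c("T1", "T2"))
  expect_setequal(unique(s$treatment), c("100", "50"))
  perPlotTp <- table(s$plot_id, s$timepoint)
  expect_true(all(perPlotTp >= 1 & perPlotTp <= 2))
  expect_true(validObject(fl))
})

test_that("abundance generator with no structure yields identical samples", {
  fl <- generateFieldLayout(seed = 1)
  sim <- simulateAbundanceTable(fl, nVotus = 40, decayScale = Inf,
                                treatmentLogEffect = 0, fracIndicator = 0,
                                noiseSd = 0, seed = 2)
  m <- abundances(sim$experiment)
  expect_true(all(m == m[, 1]))
  bc <- brayCurtis(m)
  expect_true(all(bc == 0))
})

test_that("small decay scale plants a negative similarity-distance correlation", {
  fl <- generateFieldLayout(seed = 5)
  sim <- simulateAbundanceTable(fl, nVotus = 200, decayScale = 2,
                                treatmentLogEffect = 0, fracIndicator = 0,
                                seed = 5)
  lt <- logTransform(relativeAbundance(abundances(sim$experiment)))
  sim1 <- 1 - as.matrix(brayCurtis(lt))
  sp <- as.matrix(spatialDistance(sampleMetadata(sim$experiment)))
  keep <- lower.tri(sim1)
  expect_gt(sum(keep), 500)
  expect_lt(cor(sim1[keep], sp[keep]), 0)
})

test_that("planted indicator bookkeeping and parameter validation hold", {
  fl <- generateFieldLayout(seed = 1)
  sim <- simulateAbundanceTable(fl, nVotus = 500, fracIndicator = 0.1,
                                seed = 1)
  expect_length(sim$truth@indicatorIds, 50)
  expect_length(sim$truth@depletedIds, 50)
  expect_length(intersect(sim$truth@indicatorIds, sim$truth@depletedIds), 0)
  expect_error(simulateAbundanceTable(fl, nVotus = 1), "at least 2")
  expect_error(simulateAbundanceTable(fl, nVotus = 10, fracIndicator = 0.6),
               "0, 0.5")
  expect_identical(
    abundances(simulateAbundanceTable(fl, nVotus = 30, seed = 9)$experiment),
    abundances(simulateAbundanceTable(fl, nVotus = 30, seed = 9)$experiment))
})

test_that("SBM generator produces the designed block structure", {
  net0 <- simulateGeneSharingNetwork(20, blockSizes = c(10, 10),
                                     pWithin = 1, pBetween = 0, seed = 1)
  g <- networkGraph(net0$network)
  expect_equal(igraph::components(g)$no, 2)
  expect_true(all(igraph::degree(g) == 9))
  expect_length(net0$truth@plantedModule, 10)

  expect_error(simulateGeneSharingNetwork(20, blockSizes = c(10, 5)),
               "sum")
  expect_error(simulateGeneSharingNetwork(20, blockSizes = c(10, 10),
                                          pWithin = 0.1, pBetween = 0.5),
               "exceed")
  expect_error(simulateGeneSharingNetwork(20, blockSizes = c(10, 10),
                                          pWithin = 1.5), "\\[0, 1\\]")
})

test_that("module trait counts match the binomial expectation over seeds", {
  hits <- vapply(1:10, function(s) {
    net <- simulateGeneSharingNetwork(500, blockSizes = c(50, rep(75, 6)),
                                      enrichProb = 0.5,
                                      backgroundProb = 0.05, seed = s)
    tr <- nodeTraits(net$network)
    sum(tr[net$truth@plantedModule] == "enriched")
  }, numeric(1))
  # pooled module trait draws: Binomial(10 * 50, 0.5), 99% band
  expect_gte(sum(hits), qbinom(0.005, 500, 0.5))
  expect_lte(sum(hits), qbinom(0.995, 500, 0.5))
})

test_that("zero divergence yields identical consensus sequences everywhere", {
  fl <- generateFieldLayout(2, 2, seed = 1)
  ac <- simulateAlleleCounts(fl, nVotus = 2, genomeLength = 300,
                             nVariantSites = 20, divergenceRate = 0,
                             meanCoverage = 20, seed = 2)
  rec <- pairwiseConsensusANI(ac$profiles)
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$ani == 1))
})

test_that("non-variant positions are monomorphic in the simulated pileups", {
  fl <- generateFieldLayout(1, 1, seed = 1)
  ac <- simulateAlleleCounts(fl, nVotus = 1, genomeLength = 1000,
                             nVariantSites = 50, divergenceRate = 0.01,
                             meanCoverage = 30, seed = 3)
  for (p in ac$profiles[1:2]) {
    nAlleles <- rowSums(p@counts > 0)
    expect_lte(sum(nAlleles > 1), 50)
    expect_gte(sum(nAlleles == 1), 950)
  }
})

test_that("consensus mismatch fractions track the planted flip probabilities", {
  fl <- generateFieldLayout(seed = 1)
  nvar <- 400
  ac <- simulateAlleleCounts(fl, nVotus = 1, genomeLength = 2000,
                             nVariantSites = nvar, divergenceRate = 0.02,
                             meanCoverage = 100, noiseSd = 0, seed = 4)
  q <- ac$flipProbs
  cps <- lapply(ac$profiles, callSites)
  ids <- vapply(cps, function(x) x@sampleId, character(1))
  pick <- order(q)[round(seq(1, length(q), length.out = 5))]
  for (i in pick[-1]) {
    a <- cps[[which(ids == names(q)[pick[1]])]]
    b <- cps[[which(ids == names(q)[i])]]
    rec <- consensusANI(a, b)
    observed <- (1 - rec$ani) * rec$n_compared / nvar
    expected <- abs(q[pick[1]] - q[i])
    se <- sqrt(max(expected * (1 - expected), 1e-4) / nvar)
    expect_lt(abs(observed - expected), 5 * se + 0.01)
  }
})

test_that("simulation bundles round-trip through the file readers", {
  fl <- generateFieldLayout(3, 2, seed = 1)
  sim <- simulateAbundanceTable(fl, nVotus = 30, seed = 1)
  net <- simulateGeneSharingNetwork(30, blockSizes = c(10, 20),
                                    pWithin = 0.8, pBetween = 0.05,
                                    truth = sim$truth, seed = 1)
  ac <- simulateAlleleCounts(fl, nVotus = 2, genomeLength = 200,
                             nVariantSites = 10, seed = 1)
  chem <- simulateSoilChemistry(fl, seed = 1)
  dir <- withr::local_tempdir()
  files <- writeSimulationBundle(dir, fl, sim, net, ac, chem, seed = 1)
  expect_true(all(file.exists(files)))

  ve <- readCoverageTable(files["coverage"],
                          metadata = readSampleMetadata(files["metadata"]))
  expect_equal(abundances(ve), abundances(sim$experiment),
               tolerance = 1e-12)
  net2 <- readEdgeList(files["network"])
  expect_equal(igraph::ecount(networkGraph(net2)),
               igraph::ecount(networkGraph(net$network)))
  profs <- readPileups(files["pileups"], genomeLengths = 200)
  expect_length(profs, length(ac$profiles))
  truth <- jsonlite::read_json(files["truth"])
  expect_equal(unlist(truth$indicator_ids), sim$truth@indicatorIds)
})
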