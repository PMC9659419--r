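writeEdges <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("edge-list reader handles dialects, duplicates, and self-edges", {
  net <- readEdgeList(writeEdges(c("a,b,5", "b,c,2", "a,c,1")))
  expect_equal(igraph::ecount(networkGraph(net)), 3)

  dup <- readEdgeList(writeEdges(c("a,b,5", "b,a,9")))
  expect_equal(igraph::ecount(networkGraph(dup)), 1)
  expect_equal(igraph::E(networkGraph(dup))$score, 9)

  expect_warning(net2 <- readEdgeList(writeEdges(c("a,a,3", "a,b,2"))),
                 "self-edge")
  expect_equal(igraph::ecount(networkGraph(net2)), 1)

  expect_error(readEdgeList(writeEdges(c("a,b,0"))), "non-positive")
  ws <- readEdgeList(writeEdges(c("a b 5", "b c 2")))
  expect_equal(igraph::ecount(networkGraph(ws)), 2)
})

test_that("edge weights are reciprocal scores, strictly decreasing", {
  expect_equal(edgeWeights(10), 0.1)
  expect_equal(edgeWeights(1), 1)
  s <- sort(runif(20, 0.5, 30))
  expect_true(all(diff(edgeWeights(s)) < 0))
  expect_error(edgeWeights(0), "positive")
})

test_that("shortest paths add reciprocal weights along chains", {
  net <- readEdgeList(writeEdges(c("a,b,10", "b,c,5")))  # weights .1, .2
  D <- allPairsDistances(net)
  expect_equal(D["a", "c"], 0.3)
  expect_equal(D["a", "b"], 0.1)
  expect_true(all(diag(D) == 0))
})

test_that("Dijkstra distances equal the Floyd-Warshall oracle", {
  for (s in 1:20) {
    net <- randomScoredGraph(n = sample(5:40, 1), p = runif(1, 0.05, 0.4),
                             seed = s)
    D <- allPairsDistances(net)
    expect_equal(D, floydWarshall(weightMatrix(net)), tolerance = 1e-12)
  }
})

test_that("the percentile threshold interpolates order statistics", {
  D <- as.matrix(dist(cbind(1:101, 0)))   # pair distances include 1..100
  vals <- sort(D[lower.tri(D)])
  expect_equal(neighborhoodThreshold(D, 100), max(vals))

  lin <- matrix(0, 101, 101)
  lin[lower.tri(lin)] <- 0  # placeholder; build explicit set {1..100}
  x <- 1:100
  # embed {1..100} as the finite pair distances of a star-like matrix
  M <- matrix(Inf, 101, 101); diag(M) <- 0
  M[1, 2:101] <- M[2:101, 1] <- x
  expect_equal(neighborhoodThreshold(M, 1), 1.99)

  allc <- matrix(3, 5, 5); diag(allc) <- 0
  expect_equal(neighborhoodThreshold(allc, 1), 3)
  expect_error(neighborhoodThreshold(matrix(0, 1, 1)), "at least 2")
})

test_that("local neighborhoods follow the strict threshold and size rules", {
  # star: center c, 12 leaves at weight 0.1 (score 10)
  lines <- sprintf("c,l%02d,10", 1:12)
  net <- readEdgeList(writeEdges(lines))
  D <- allPairsDistances(net)
  nb <- localNeighborhoods(D, threshold = 0.15, minSize = 10)
  expect_setequal(nb$neighborhoods$c, rownames(D))     # all 13 nodes
  expect_length(nb$skipped, 12)
  expect_setequal(nb$skipped$l01, c("l01", "c"))

  tiny <- localNeighborhoods(D, threshold = 0.05, minSize = 10)
  expect_length(tiny$neighborhoods, 0)
  expect_true(all(lengths(tiny$skipped) == 1))
})

test_that("neighborhood membership is symmetric under a global threshold", {
  net <- randomScoredGraph(30, 0.2, seed = 42)
  D <- allPairsDistances(net)
  thr <- neighborhoodThreshold(D, 10)
  nb <- localNeighborhoods(D, thr, minSize = 1)
  all_ <- c(nb$neighborhoods, nb$skipped)
  for (u in names(all_)) for (v in all_[[u]])
    expect_true(u %in% all_[[v]])
})

test_that("brute-force thresholded neighborhoods match on random graphs", {
  for (s in 1:10) {
    net <- randomScoredGraph(25, 0.15, seed = 100 + s)
    D <- allPairsDistances(net)
    thr <- neighborhoodThreshold(D, 5)
    nb <- localNeighborhoods(D, thr, minSize = 1)
    FW <- floydWarshall(weightMatrix(net))
    for (u in rownames(FW))
      expect_setequal(c(nb$neighborhoods, nb$skipped)[[u]],
                      rownames(FW)[FW[u, ] < thr])
  }
})

test_that("upper-tail hypergeometric matches the worked example and phyper", {
  expect_equal(hypergeomUpper(4, 6, 5, 20), 540 / 38760, tolerance = 1e-12)
  expect_equal(hypergeomUpper(0, 6, 5, 20), 1)
  expect_equal(hypergeomUpper(5, 20, 5, 20), 1)   # n = N, k = K
  expect_error(hypergeomUpper(7, 6, 5, 20), "inconsistent")

  set.seed(14)
  for (i in 1:50) {
    N <- sample(5:400, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeomUpper(k, n, K, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(hypergeomUpper(k, n, K, N, tail = "gt"),
                 phyper(k, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("enrichment scan recovers a planted module and labels traits", {
  sim <- simulateGeneSharingNetwork(seed = 21)
  res <- enrichmentScan(sim$network)
  expect_true(all(res$p_holm >= res$p_raw - 1e-15))
  expect_true(all(res$N == 500))
  enr <- res[res$trait == "enriched", ]
  modFocal <- enr$focal %in% sim$truth@plantedModule
  expect_gt(mean(enr$significant[modFocal]), 0.8)
  if (any(!modFocal)) expect_lte(mean(enr$significant[!modFocal]), 0.05)

  sub <- significantSubnetwork(res, sim$network)
  expect_gt(mean(sim$truth@plantedModule %in% sub$nodes), 0.8)
  expect_length(setdiff(sub$nodes,
                        unlist(attr(res, "neighborhoods"))), 0)
})

test_that("all-none traits give p = 1 everywhere and no significance", {
  sim <- simulateGeneSharingNetwork(200, blockSizes = c(40, 160),
                                    pWithin = c(0.9, 0.1), seed = 22)
  traits <- setNames(rep("none", 200),
                     igraph::V(networkGraph(sim$network))$name)
  res <- enrichmentScan(sim$network, traits = traits)
  expect_true(all(res$p_raw == 1))
  expect_false(any(res$significant))
  empty <- significantSubnetwork(res, sim$network)
  expect_length(empty$nodes, 0)
})

test_that("reference genomes are excluded from the scan but drive host links", {
  sim <- simulateGeneSharingNetwork(seed = 23)
  full <- simulateReferenceGenomes(sim$network, sim$truth@plantedModule,
                                   nModuleRefs = 8, nOtherRefs = 6,
                                   seed = 23)
  res <- enrichmentScan(full)
  expect_true(all(res$N == 500))   # 14 reference nodes not counted

  sub <- significantSubnetwork(res, sim$network)
  links <- annotateReferenceLinks(sub$nodes, full)
  linked <- links$perNode[!is.na(links$perNode$exclusive), ]
  expect_gt(nrow(linked), 0)
  expect_true(all(grepl("Actinobacteria", linked$host_taxa)))
  expect_equal(links$fractionExclusive, 1)
})

test_that("mixed host links are flagged non-exclusive", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("v1", "v1", "v2"), to = c("r1", "r2", "r1"),
               score = c(5, 5, 5)), directed = FALSE)
  igraph::V(g)$is_reference <- grepl("^r", igraph::V(g)$name)
  igraph::V(g)$trait <- "none"
  igraph::V(g)$host_taxon <- ifelse(igraph::V(g)$name == "r1",
                                    "Actinobacteria", "Firmicutes")
  net <- new("GeneSharingNetwork", graph = g)
  ann <- annotateReferenceLinks(c("v1", "v2", "v3"), net)
  pn <- ann$perNode
  expect_false(pn$exclusive[pn$votu_id == "v1"])
  expect_true(pn$exclusive[pn$votu_id == "v2"])
  expect_true(is.na(pn$exclusive[pn$votu_id == "v3"]))
  expect_equal(ann$fractionExclusive, 0.5)
})
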