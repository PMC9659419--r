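# Independent oracles and small fixture builders shared across tests.

# Build an AlleleCountProfile from a position -> counts table.
acp <- function(counts, votu = "v1", sample = "s1", L = NULL) {
  counts <- as.matrix(counts)
  colnames(counts) <- c("A", "C", "G", "T")
  storage.mode(counts) <- "integer"
  pos <- as.integer(rownames(counts) %||% seq_len(nrow(counts)))
  new("AlleleCountProfile", votuId = votu, sampleId = sample,
      genomeLength = as.integer(L %||% max(pos, 1L)),
      positions = pos, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Floyd-Warshall all-pairs shortest paths on a weight matrix (Inf = no edge).
floydWarshall <- function(W) {
  D <- W
  diag(D) <- 0
  n <- nrow(D)
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, via)
  }
  D
}

# Weight matrix (reciprocal scores) of a GeneSharingNetwork.
weightMatrix <- function(net) {
  g <- networkGraph(net)
  n <- igraph::vcount(g)
  W <- matrix(Inf, n, n, dimnames = list(igraph::V(g)$name,
                                         igraph::V(g)$name))
  el <- igraph::as_edgelist(g)
  w <- 1 / igraph::E(g)$score
  W[el] <- pmin(W[el], w)
  W[el[, 2:1, drop = FALSE]] <- W[el]
  W
}

# Closed-form Holm step-down with cumulative max.
holmStepdown <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws.
hyperEnumerate <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  trait <- seq_len(K)
  hits <- colSums(matrix(draws %in% trait, nrow = n))
  mean(hits >= k)
}

# Random connected-ish weighted graph as a GeneSharingNetwork.
randomScoredGraph <- function(n, p, seed, scoreRange = c(1, 10)) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::V(g)$is_reference <- FALSE
  igraph::V(g)$trait <- "none"
  if (igraph::ecount(g) > 0)
    igraph::E(g)$score <- stats::runif(igraph::ecount(g),
                                       scoreRange[1], scoreRange[2])
  new("GeneSharingNetwork", graph = g)
}

# Hand computation of the one-factor PERMANOVA pseudo-F from a distance
# matrix (total SS = sum d^2 / n; within SS per group likewise).
pseudoF <- function(d, groups) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- factor(groups)
  a <- nlevels(groups)
  ssTotal <- sum(D[lower.tri(D)]^2) / n
  ssWithin <- sum(vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    Dg <- D[idx, idx]
    sum(Dg[lower.tri(Dg)]^2) / length(idx)
  }, numeric(1)))
  ssBetween <- ssTotal - ssWithin
  (ssBetween / (a - 1)) / (ssWithin / (n - a))
}
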