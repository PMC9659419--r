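.indvalComponents <- function(m, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  meanByGroup <- t(rowsum(t(m), groups)) / rep(as.numeric(sizes),
                                               each = nrow(m))
  occByGroup <- t(rowsum(t(m > 0) + 0, groups)) / rep(as.numeric(sizes),
                                                      each = nrow(m))
  A <- meanByGroup / rowSums(meanByGroup)  # NaN for all-zero vOTUs
  sqrt(A * occByGroup)
}

#' Group-size-corrected indicator value (IndVal.g) per vOTU
#'
#' For each vOTU and each of two sample groups computes specificity
#' `A_g = mean abundance in g / sum of group mean abundances` (group means,
#' so unequal group sizes do not bias A), fidelity `B_g = fraction of g's
#' samples where the vOTU is detected`, and `IndVal_g = sqrt(A_g * B_g)`.
#' The statistic is the maximum over the two groups and `best_group` its
#' argmax. vOTUs absent everywhere have an undefined statistic (`NA`).
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param groups two-level factor (or coercible), one label per sample.
#' @return data.frame with one row per vOTU: `votu_id`, per-group IndVal
#'   columns, `stat`, `best_group`.
#' @export
indvalStat <- function(x, groups) {
  if (is(x, "ViromeExperiment")) x <- abundances(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) == 0)) stop("both groups must be nonempty")
  iv <- .indvalComponents(x, groups)
  best <- max.col(replace(iv, is.na(iv), -Inf), ties.method = "first")
  stat <- iv[cbind(seq_len(nrow(iv)), best)]
  out <- data.frame(votu_id = rownames(x), iv, stringsAsFactors = FALSE)
  colnames(out)[2:3] <- paste0("indval_", levels(groups))
  out$stat <- stat
  out$best_group <- ifelse(is.na(stat), NA_character_, levels(groups)[best])
  rownames(out) <- NULL
  out
}

#' Indicator-species permutation test (two groups)
#'
#' Tests each vOTU's IndVal statistic by permuting group labels across
#' samples: `p = (1 + #{permuted stat >= observed}) / (1 + nPerm)`. A vOTU
#' is called `enriched` when its best group is `targetGroup` (by default the
#' T2-50 low-moisture group) and `p < alpha`, `depleted` when its best group
#' is the other one with `p < alpha`, and `none` otherwise. P values are
#' used raw (no correction across vOTUs), matching the conventional IndVal
#' workflow.
#'
#' @param x a vOTU x sample matrix or [ViromeExperiment-class].
#' @param groups two-level factor of sample groups (see [t250Groups()]).
#' @param nPerm number of label permutations (>= 99; default 999).
#' @param seed integer seed.
#' @param alpha significance level for the call.
#' @param targetGroup group whose indicators are called `enriched`.
#' @return data.frame with `votu_id`, per-group IndVal columns, `stat`,
#'   `best_group`, `p_value`, `call`.
#' @export
indvalTest <- function(x, groups, nPerm = 999, seed = 1, alpha = 0.05,
                       targetGroup = "T2-50") {
  if (is(x, "ViromeExperiment")) x <- abundances(x)
  groups <- factor(groups)
  if (nPerm < 99) stop("nPerm must be at least 99")
  obs <- indvalStat(x, groups)
  stat <- obs$stat
  exceed <- integer(nrow(x))
  set.seed(seed)
  for (b in seq_len(nPerm)) {
    pg <- sample(groups)
    iv <- .indvalComponents(x, pg)
    permStat <- pmax(iv[, 1], iv[, 2])
    exceed <- exceed + (permStat >= stat)
  }
  obs$p_value <- ifelse(is.na(stat), NA_real_, (1 + exceed) / (1 + nPerm))
  if (!targetGroup %in% levels(groups))
    stop("targetGroup '", targetGroup, "' is not a group level")
  other <- setdiff(levels(groups), targetGroup)
  obs$call <- "none"
  sig <- !is.na(obs$p_value) & obs$p_value < alpha
  obs$call[sig & obs$best_group == targetGroup] <- "enriched"
  obs$call[sig & obs$best_group == other] <- "depleted"
  obs
}

#' Summed relative abundance of indicator sets per sample
#'
#' Sums, within each sample, the relative abundances of the vOTUs called
#' `enriched` and (separately) those called `depleted`.
#'
#' @param x a relative-abundance vOTU x sample matrix or
#'   [ViromeExperiment-class] on that scale.
#' @param results data.frame from [indvalTest()] (needs `votu_id`, `call`).
#' @return data.frame with `sample_id`, `enriched_sum`, `depleted_sum`.
#' @export
summedIndicatorAbundance <- function(x, results) {
  if (is(x, "ViromeExperiment")) x <- abundances(x)
  enr <- results$votu_id[results$call == "enriched"]
  dep <- results$votu_id[results$call == "depleted"]
  sumSet <- function(ids)
    if (length(ids)) colSums(x[rownames(x) %in% ids, , drop = FALSE])
    else stats::setNames(numeric(ncol(x)), colnames(x))
  data.frame(sample_id = colnames(x), enriched_sum = sumSet(enr),
             depleted_sum = sumSet(dep), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Exhaustive IndVal permutation distribution (small n)
#'
#' Enumerates every distinct assignment of the observed group sizes to the
#' samples and returns the exact permutation P value for each vOTU:
#' `#{assignments with stat >= observed} / #assignments`. Intended as an
#' oracle for validating the Monte-Carlo test on small designs.
#'
#' @param x a vOTU x sample matrix.
#' @param groups two-level factor; `choose(n, n1)` must be manageable.
#' @return data.frame with `votu_id`, `stat`, `p_exact`, `n_assignments`.
#' @export
indvalExhaustiveP <- function(x, groups) {
  groups <- factor(groups)
  n <- ncol(x)
  n1 <- sum(groups == levels(groups)[1])
  combos <- utils::combn(n, n1)
  obs <- indvalStat(x, groups)
  exceed <- integer(nrow(x))
  for (j in seq_len(ncol(combos))) {
    g <- factor(ifelse(seq_len(n) %in% combos[, j],
                       levels(groups)[1], levels(groups)[2]),
                levels = levels(groups))
    iv <- .indvalComponents(x, g)
    exceed <- exceed + (pmax(iv[, 1], iv[, 2]) >= obs$stat)
  }
  data.frame(votu_id = obs$votu_id, stat = obs$stat,
             p_exact = exceed / ncol(combos),
             n_assignments = ncol(combos), stringsAsFactors = FALSE)
}
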