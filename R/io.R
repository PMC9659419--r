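#' Read a vOTU coverage table
#'
#' Parses a tab-separated table with a header row of sample ids and vOTU ids
#' in the first column, validating the contract strictly: rectangular rows,
#' no missing cells, no negative values, unique vOTU and sample ids. Errors
#' name the offending row.
#'
#' @param path path to the TSV file.
#' @param kind `"trimmed_mean"` or `"count"`.
#' @param metadata optional per-sample metadata data.frame passed through to
#'   [ViromeExperiment()].
#' @return a [ViromeExperiment-class].
#' @export
readCoverageTable <- function(path, kind = c("trimmed_mean", "count"),
                              metadata = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("coverage table format error: need a header and at least one vOTU row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  nCol <- length(header)
  sampleIds <- header[-1]
  if (anyDuplicated(sampleIds))
    stop("coverage table format error: duplicate sample ids")
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != nCol))
    stop("coverage table format error: ragged row ", which(widths != nCol)[1],
         " (", widths[which(widths != nCol)[1]], " fields, expected ", nCol, ")")
  votuIds <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(votuIds))
    stop("coverage table format error: duplicate vOTU ids (",
         votuIds[duplicated(votuIds)][1], ")")
  vals <- matrix(NA_real_, length(body), nCol - 1,
                 dimnames = list(votuIds, sampleIds))
  for (i in seq_along(body)) {
    x <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (any(is.na(x)))
      stop("coverage table format error: missing or non-numeric cell in row ",
           i, " (", votuIds[i], ")")
    if (any(x < 0))
      stop("coverage table format error: negative value in row ", i,
           " (", votuIds[i], ")")
    vals[i, ] <- x
  }
  ViromeExperiment(vals, metadata = metadata, kind = kind)
}

#' Write a vOTU x sample matrix as a tab-separated coverage table
#'
#' @param m numeric matrix with vOTU rownames and sample colnames.
#' @param path output path.
#' @export
writeCoverageTable <- function(m, path) {
  df <- data.frame(votu_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with columns `sample_id, plot_id, x_m, y_m, block, timepoint,
#' treatment` and optional `moisture`.
#'
#' @param path path to the CSV file.
#' @return data.frame with coordinate columns renamed to `x`, `y`.
#' @export
readSampleMetadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(treatment = "character"))
  need <- c("sample_id", "plot_id", "x_m", "y_m", "timepoint", "treatment")
  missing <- setdiff(need, colnames(meta))
  if (length(missing))
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids in metadata")
  if (!all(meta$timepoint %in% c("T1", "T2")))
    stop("timepoint must be 'T1' or 'T2'")
  colnames(meta)[colnames(meta) == "x_m"] <- "x"
  colnames(meta)[colnames(meta) == "y_m"] <- "y"
  rownames(meta) <- meta$sample_id
  meta
}

#' Read a soil-chemistry table
#'
#' CSV with a `sample_id` column followed by numeric variables.
#'
#' @param path path to the CSV file.
#' @return data.frame of variables with sample ids as rownames.
#' @export
readSoilChemistry <- function(path) {
  chem <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(chem))
    stop("chemistry table must contain a sample_id column")
  rownames(chem) <- chem$sample_id
  chem$sample_id <- NULL
  chem
}

#' Read a gene-sharing network edge list
#'
#' Accepts the `node1,node2,score` CSV dialect or its whitespace-delimited
#' variant (auto-detected). Scores are -log10 P values and must be positive.
#' Self-edges are dropped (with a warning giving the count) and duplicate
#' edges collapsed keeping the maximum score.
#'
#' @param path path to the edge-list file.
#' @return a [GeneSharingNetwork-class].
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("edge list format error: empty file")
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else "[[:space:]]+"
  parts <- strsplit(trimws(lines), sep)
  if (any(lengths(parts) != 3))
    stop("edge list format error: row ", which(lengths(parts) != 3)[1],
         " does not have 3 fields")
  first <- parts[[1]]
  if (is.na(suppressWarnings(as.numeric(first[3]))) &&
      tolower(first[3]) %in% c("score", "weight")) parts <- parts[-1]
  n1 <- vapply(parts, `[`, character(1), 1)
  n2 <- vapply(parts, `[`, character(1), 2)
  sc <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  if (any(is.na(sc))) stop("edge list format error: non-numeric score")
  if (any(sc <= 0)) stop("edge list format error: non-positive score in row ",
                         which(sc <= 0)[1])
  self <- n1 == n2
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    n1 <- n1[!self]; n2 <- n2[!self]; sc <- sc[!self]
  }
  key <- ifelse(n1 < n2, paste(n1, n2, sep = "\r"), paste(n2, n1, sep = "\r"))
  best <- tapply(sc, key, max)
  pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2], score = as.numeric(best)),
    directed = FALSE)
  igraph::V(g)$trait <- "none"
  igraph::V(g)$is_reference <- FALSE
  new("GeneSharingNetwork", graph = g)
}

#' Write a gene-sharing network as a `node1,node2,score` CSV
#'
#' @param network a [GeneSharingNetwork-class].
#' @param path output path.
#' @export
writeEdgeList <- function(network, path) {
  g <- network@graph
  el <- igraph::as_edgelist(g)
  utils::write.csv(
    data.frame(node1 = el[, 1], node2 = el[, 2],
               score = igraph::E(g)$score),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read allele-count pileups
#'
#' Long-format TSV with columns `votu_id, sample_id, pos, A, C, G, T`
#' (1-based positions). The genome length of each vOTU must be supplied (or
#' is taken as the maximum observed position).
#'
#' @param path path to the pileup TSV.
#' @param genomeLengths named integer vector of genome lengths per vOTU, or
#'   a single length shared by all, or `NULL` to infer the maximum position.
#' @return list of [AlleleCountProfile-class] named `"votu|sample"`.
#' @export
readPileups <- function(path, genomeLengths = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("votu_id", "sample_id", "pos", "A", "C", "G", "T")
  if (!all(need %in% colnames(df)))
    stop("pileup format error: need columns ", paste(need, collapse = ", "))
  split(df, paste(df$votu_id, df$sample_id, sep = "|")) |>
    lapply(function(d) {
      gl <- if (is.null(genomeLengths)) max(d$pos)
            else if (length(genomeLengths) == 1 && is.null(names(genomeLengths)))
              genomeLengths
            else genomeLengths[[d$votu_id[1]]]
      new("AlleleCountProfile", votuId = d$votu_id[1],
          sampleId = d$sample_id[1], genomeLength = as.integer(gl),
          positions = as.integer(d$pos),
          counts = as.matrix(d[, c("A", "C", "G", "T")]))
    })
}

#' Write allele-count profiles as a long-format pileup TSV
#'
#' @param profiles list of [AlleleCountProfile-class].
#' @param path output path.
#' @export
writePileups <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(votu_id = p@votuId, sample_id = p@sampleId,
               pos = p@positions, p@counts, check.names = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Round-trip a distance matrix to square CSV with a label header
#'
#' @param d a `dist` object or square matrix.
#' @param path output path.
#' @export
writeDistanceMatrix <- function(d, path) {
  m <- as.matrix(d)
  utils::write.csv(data.frame(sample_id = rownames(m), m,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @param path path to a square CSV written by [writeDistanceMatrix()].
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  stats::as.dist(m)
}
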