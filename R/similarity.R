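# Sample similarity (rank-correlation distance + classical MDS) and a
# generic hypergeometric over-representation test taking user-supplied
# gene sets (GMT-like TSV); no external annotation database is required.

#' Rank-correlation distance between samples
#'
#' Counts are transformed to log2-CPM with a prior of 0.5, restricted to
#' the `top_n` most variable features, and distances are
#' `1 - Spearman correlation` between samples.
#'
#' @param counts count matrix (features x samples), >= 2 samples.
#' @param top_n number of most-variable features to retain (default 500).
#' @return symmetric distance matrix with zero diagonal.
#' @export
sample_distances <- function(counts, top_n = 500) {
  if (ncol(counts) < 2) stop("sample_distances: need >= 2 samples")
  lib <- colSums(counts)
  logcpm <- log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)
  v <- apply(logcpm, 1, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(top_n, nrow(logcpm)))]
  sub <- logcpm[keep, , drop = FALSE]
  sds <- apply(sub, 2, sd)
  if (any(sds == 0))
    stop("sample_distances: constant values in sample ",
         colnames(counts)[which(sds == 0)[1]])
  d <- 1 - cor(sub, method = "spearman")
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering of squared distances and spectral embedding on the top
#' `k` eigenpairs, with negative eigenvalues clipped to zero. Axis signs
#' are fixed so that each axis's largest-magnitude loading is positive,
#' making the embedding deterministic.
#'
#' @param dist symmetric distance matrix (zero diagonal).
#' @param k embedding dimension, `k < nrow(dist)` (default 2).
#' @return numeric matrix (samples x k) of coordinates.
#' @export
classical_mds <- function(dist, k = 2) {
  n <- nrow(dist)
  if (k >= n) stop("classical_mds: k must be < number of samples")
  if (max(abs(dist - t(dist))) > 1e-12)
    stop("classical_mds: distance matrix not symmetric")
  fit <- cmdscale(as.dist(dist), k = k, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < k) {
    # degenerate spectra (zero eigenvalues) pad with zero coordinates
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  for (j in seq_len(k)) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(dist)
  colnames(coords) <- paste0("dim", seq_len(k))
  coords
}

#' Read a GMT-like gene-set collection
#'
#' Tab-separated lines: set id, description, then one member gene id per
#' remaining column.
#'
#' @param path path to the file.
#' @return named list of character vectors (unique members); descriptions
#'   in attribute `descriptions`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    stop("gene sets: line ", bad[1], " has no members")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "descriptions") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric p-value per set (sets are
#' intersected with the universe first), BH adjustment across sets, and a
#' significance flag at `fdr < fdr_threshold`.
#'
#' @param query_genes character vector of query gene ids (must be within
#'   the universe).
#' @param gene_sets named list of character vectors.
#' @param universe character vector of background gene ids.
#' @param fdr_threshold significance gate (default 0.05).
#' @return data.frame per set: `set_id`, `set_size`, `overlap`, `expected`,
#'   `p_value`, `fdr`, `significant`.
#' @export
overrepresentation <- function(query_genes, gene_sets, universe,
                               fdr_threshold = 0.05) {
  universe <- unique(universe)
  query <- unique(query_genes)
  if (length(universe) == 0) stop("overrepresentation: empty universe")
  if (length(query) == 0) stop("overrepresentation: empty query")
  bad <- setdiff(query, universe)
  if (length(bad) > 0)
    stop("overrepresentation: query gene outside universe: ", bad[1])
  n_u <- length(universe); n_q <- length(query)
  rows <- lapply(names(gene_sets), function(sid) {
    members <- intersect(gene_sets[[sid]], universe)
    k <- length(intersect(members, query))
    m <- length(members)
    p <- if (m == 0) 1 else
      phyper(k - 1, m, n_u - m, n_q, lower.tail = FALSE)
    data.frame(set_id = sid, set_size = m, overlap = k,
               expected = n_q * m / n_u, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_bh(out$p_value)
  out$significant <- out$fdr < fdr_threshold
  rownames(out) <- NULL
  out
}
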