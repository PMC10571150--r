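# Broad H3K9me2 domain (KDD) analysis: a z-score-vs-chromosome-background
# caller on binned coverage with gap merging and a minimum length, greedy
# 1:1 size comparison between conditions, and a label-permutation test of
# DEG proximity to changed domains.

#' Call broad domains from binned coverage
#'
#' Bins whose enrichment z-score (against the per-chromosome median/MAD)
#' reaches `z_threshold` are marked; marked runs are merged across gaps of
#' at most `max_gap_bins` unmarked bins, and runs shorter than
#' `min_domain_length` are discarded. Invariant to constant shifts of the
#' track.
#'
#' @param coverage_bins bedGraph-like data.frame (`chrom`, `start`, `end`,
#'   `value`) with sorted, constant-width bins per chromosome.
#' @param bin_size expected bin width in bp.
#' @param z_threshold minimum bin z-score (default 2.0; at 1 SD roughly a
#'   sixth of background bins are marked and gap merging chains them into
#'   spurious domains, so the default sits at the conventional two-sigma
#'   mark).
#' @param max_gap_bins maximum unmarked gap to merge across (default 2).
#' @param min_domain_length minimum domain span in bp (default 50000).
#' @return data.frame of domains: `chrom`, `start`, `end`,
#'   `mean_enrichment` (mean bin value over the span), `n_bins`.
#' @export
call_kdd <- function(coverage_bins, bin_size, z_threshold = 2.0,
                     max_gap_bins = 2, min_domain_length = 50000) {
  validate_intervals(coverage_bins, "coverage track")
  if (any(coverage_bins$end - coverage_bins$start != bin_size))
    stop("call_kdd: non-uniform bin widths (expected ", bin_size, ")")
  out <- list()
  for (cn in unique(coverage_bins$chrom)) {
    cb <- coverage_bins[coverage_bins$chrom == cn, , drop = FALSE]
    cb <- cb[order(cb$start), , drop = FALSE]
    med <- median(cb$value)
    scale <- mad(cb$value)
    if (scale == 0) next
    z <- (cb$value - med) / scale
    marked <- z >= z_threshold
    if (!any(marked)) next
    idx <- which(marked)
    # split marked bins into runs allowing gaps <= max_gap_bins
    brk <- c(0, which(diff(idx) > max_gap_bins + 1), length(idx))
    for (k in seq_len(length(brk) - 1)) {
      run <- idx[(brk[k] + 1):brk[k + 1]]
      s <- cb$start[min(run)]; e <- cb$end[max(run)]
      if (e - s < min_domain_length) next
      span <- which(cb$start >= s & cb$end <= e)
      out[[length(out) + 1]] <- data.frame(
        chrom = cn, start = s, end = e,
        mean_enrichment = mean(cb$value[span]),
        n_bins = length(span), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_enrichment = numeric(),
                      n_bins = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Compare domain sets between control and treatment
#'
#' Greedy 1:1 matching by descending overlap; matched pairs get
#' `size_log2_ratio = log2(len_treatment / len_control)` and are flagged
#' `changed` when the absolute ratio exceeds `size_change_threshold`.
#' Unmatched control domains are `changed` with ratio `-Inf`; unmatched
#' treatment domains appear as new domains with ratio `+Inf`.
#'
#' @param control_domains,treatment_domains domain tables from
#'   [call_kdd()] (or any interval tables) on the same genome.
#' @param size_change_threshold absolute log2 size-ratio above which a
#'   matched pair counts as changed (default 0.2).
#' @return list with `changes` (data.frame: `control_chrom`,
#'   `control_start`, `control_end`, `treatment_start`, `treatment_end`
#'   (NA when unmatched), `size_log2_ratio`, `changed`) and `summary`
#'   (`control_bp`, `treatment_bp`, `bp_log2_ratio`).
#' @export
compare_domains <- function(control_domains, treatment_domains,
                            size_change_threshold = 0.2) {
  nc <- nrow(control_domains); nt <- nrow(treatment_domains)
  ov <- matrix(0, nc, nt)
  if (nc > 0 && nt > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(control_domains),
                                        as_granges0(treatment_domains))
    for (k in seq_along(hits)) {
      i <- S4Vectors::queryHits(hits)[k]; j <- S4Vectors::subjectHits(hits)[k]
      ov[i, j] <- min(control_domains$end[i], treatment_domains$end[j]) -
        max(control_domains$start[i], treatment_domains$start[j])
    }
  }
  match_t <- rep(NA_integer_, nc)
  taken <- logical(nt)
  repeat {
    if (all(ov <= 0)) break
    best <- which(ov == max(ov), arr.ind = TRUE)[1, ]
    match_t[best[1]] <- best[2]
    taken[best[2]] <- TRUE
    ov[best[1], ] <- 0; ov[, best[2]] <- 0
  }
  rows <- lapply(seq_len(nc), function(i) {
    j <- match_t[i]
    len_c <- control_domains$end[i] - control_domains$start[i]
    if (is.na(j)) {
      data.frame(control_chrom = control_domains$chrom[i],
                 control_start = control_domains$start[i],
                 control_end = control_domains$end[i],
                 treatment_start = NA_integer_, treatment_end = NA_integer_,
                 size_log2_ratio = -Inf, changed = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      len_t <- treatment_domains$end[j] - treatment_domains$start[j]
      r <- log2(len_t / len_c)
      data.frame(control_chrom = control_domains$chrom[i],
                 control_start = control_domains$start[i],
                 control_end = control_domains$end[i],
                 treatment_start = treatment_domains$start[j],
                 treatment_end = treatment_domains$end[j],
                 size_log2_ratio = r,
                 changed = abs(r) > size_change_threshold,
                 stringsAsFactors = FALSE)
    }
  })
  new_t <- which(!taken)
  rows_new <- lapply(new_t, function(j)
    data.frame(control_chrom = treatment_domains$chrom[j],
               control_start = NA_integer_, control_end = NA_integer_,
               treatment_start = treatment_domains$start[j],
               treatment_end = treatment_domains$end[j],
               size_log2_ratio = Inf, changed = TRUE,
               stringsAsFactors = FALSE))
  changes <- do.call(rbind, c(rows, rows_new))
  if (is.null(changes))
    changes <- data.frame(control_chrom = character(),
                          control_start = integer(), control_end = integer(),
                          treatment_start = integer(),
                          treatment_end = integer(),
                          size_log2_ratio = numeric(), changed = logical(),
                          stringsAsFactors = FALSE)
  cbp <- covered_bp(control_domains)
  tbp <- covered_bp(treatment_domains)
  list(changes = changes,
       summary = c(control_bp = cbp, treatment_bp = tbp,
                   bp_log2_ratio = log2(tbp / cbp)))
}

#' Permutation test of DEG proximity to changed domains
#'
#' The observed statistic is the number of DEGs whose TSS lies within a
#' changed domain extended by `flank` on both sides. The null reassigns the
#' DEG labels uniformly at random (without replacement) over all genes,
#' `n_perm` times; `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param changed_domains interval table of changed domains (`chrom`,
#'   `start`, `end`).
#' @param deg_genes character vector of DEG gene ids.
#' @param gene_table gene-model table covering all genes (the permutation
#'   pool).
#' @param flank bp added on each side of a changed domain (default 1e5).
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param seed integer seed for the permutation draw.
#' @return list with `observed` and `p_value`.
#' @export
deg_proximity_test <- function(changed_domains, deg_genes, gene_table,
                               flank = 1e5, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop("deg_proximity_test: n_perm must be >= 100")
  bad <- setdiff(deg_genes, gene_table$gene_id)
  if (length(bad) > 0)
    stop("deg_proximity_test: DEG not in gene table: ", bad[1])
  if (nrow(changed_domains) == 0)
    return(list(observed = 0L, p_value = 1))
  ext <- data.frame(chrom = changed_domains$chrom,
                    start = pmax(0, changed_domains$start - flank),
                    end = changed_domains$end + flank,
                    stringsAsFactors = FALSE)
  tss <- data.frame(chrom = gene_table$chrom, start = gene_table$tss,
                    end = gene_table$tss + 1L, stringsAsFactors = FALSE)
  in_region <- IRanges::overlapsAny(as_granges0(tss), as_granges0(ext))
  names(in_region) <- gene_table$gene_id
  observed <- sum(in_region[deg_genes])
  k <- length(deg_genes)
  set.seed(as.integer(seed %% 2147483647))
  null <- vapply(seq_len(n_perm), function(...)
    sum(in_region[sample.int(length(in_region), k)]), integer(1))
  list(observed = as.integer(observed),
       p_value = (1 + sum(null >= observed)) / (n_perm + 1))
}
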