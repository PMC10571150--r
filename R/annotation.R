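# Peak annotation: promoter classification against TSS windows, linkage to
# genes through the interaction map (preferred) or proximity (for the
# GO-style annotation path only). Promoters take precedence over
# interaction linkage, mirroring a binary within/outside-promoter split.

# promoter windows [tss - window, tss + window + 1), 0-based half-open
promoter_windows <- function(gene_table, window = 1000) {
  data.frame(chrom = gene_table$chrom,
             start = pmax(0L, as.integer(gene_table$tss - window)),
             end = as.integer(gene_table$tss + window + 1L),
             gene_id = gene_table$gene_id,
             stringsAsFactors = FALSE)
}

#' Classify peaks as promoter-overlapping
#'
#' A peak is a promoter peak iff its interval overlaps
#' `[tss - window, tss + window + 1)` for at least one gene. Strand is used
#' only to locate the TSS upstream of this table, never to gate the overlap.
#'
#' @param peaks peak table (`chrom`, `start`, `end`, `name`).
#' @param gene_table gene-model table.
#' @param window promoter half-width in bp (default 1000). With
#'   `window = 0`, only peaks containing the TSS position qualify.
#' @return data.frame with `name`, `is_promoter`, and list-column
#'   `gene_ids` of the overlapped genes (empty when none).
#' @export
classify_promoter <- function(peaks, gene_table, window = 1000) {
  if (window < 0) stop("classify_promoter: window must be >= 0")
  validate_intervals(peaks, "peak table")
  wins <- promoter_windows(gene_table, window)
  hits <- GenomicRanges::findOverlaps(as_granges0(peaks), as_granges0(wins))
  gene_ids <- rep(list(character(0)), nrow(peaks))
  if (length(hits) > 0) {
    sp <- split(wins$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    gene_ids[as.integer(names(sp))] <- lapply(sp, function(g) sort(unique(g)))
  }
  out <- data.frame(name = peaks$name, is_promoter = lengths(gene_ids) > 0,
                    stringsAsFactors = FALSE)
  out$gene_ids <- gene_ids
  out
}

#' Link peaks to genes via promoter windows and the interaction map
#'
#' Per-peak precedence: (1) promoter-window overlap makes a promoter
#' element whose genes come from the windows; (2) otherwise overlap with a
#' distal interaction anchor makes an enhancer element whose genes come from
#' the interaction record(s); (3) otherwise the peak is unannotated
#' (`element_class = NA`) and counted in the summary.
#'
#' @param peaks peak table.
#' @param interaction_map interaction map (see
#'   [read_bedpe_interactions()]).
#' @param gene_table gene-model table.
#' @param window promoter half-width in bp (default 1000).
#' @param anchor_slack bp of slack added around distal anchors before
#'   overlap (default 0).
#' @return data.frame of regulatory-element annotations: `element_id`,
#'   `chrom`, `start`, `end`, `element_class` (`promoter`, `enhancer`, or
#'   `NA`), list-column `gene_ids`, `link_source` (`promoter_window`,
#'   `interaction`, or `NA`); attribute `summary` holds class counts.
#' @export
link_peaks_to_genes <- function(peaks, interaction_map, gene_table,
                                window = 1000, anchor_slack = 0) {
  prom <- classify_promoter(peaks, gene_table, window)
  gene_ids <- prom$gene_ids
  cls <- ifelse(prom$is_promoter, "promoter", NA_character_)
  src <- ifelse(prom$is_promoter, "promoter_window", NA_character_)
  distal_idx <- which(!prom$is_promoter)
  if (length(distal_idx) > 0 && nrow(interaction_map) > 0) {
    anchors <- data.frame(chrom = interaction_map$d_chrom,
                          start = pmax(0, interaction_map$d_start - anchor_slack),
                          end = interaction_map$d_end + anchor_slack,
                          stringsAsFactors = FALSE)
    hits <- GenomicRanges::findOverlaps(
      as_granges0(peaks[distal_idx, , drop = FALSE]), as_granges0(anchors))
    if (length(hits) > 0) {
      sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
      for (qi in names(sp)) {
        i <- distal_idx[as.integer(qi)]
        g <- sort(unique(unlist(interaction_map$gene_ids[sp[[qi]]])))
        if (length(g) > 0) {
          gene_ids[[i]] <- g
          cls[i] <- "enhancer"
          src[i] <- "interaction"
        }
      }
    }
  }
  out <- data.frame(element_id = peaks$name, chrom = peaks$chrom,
                    start = peaks$start, end = peaks$end,
                    element_class = cls, link_source = src,
                    stringsAsFactors = FALSE)
  out$gene_ids <- gene_ids
  attr(out, "summary") <- c(promoter = sum(cls == "promoter", na.rm = TRUE),
                            enhancer = sum(cls == "enhancer", na.rm = TRUE),
                            unannotated = sum(is.na(cls)))
  out
}

#' k nearest genes to a peak
#'
#' The `k` genes on the peak's chromosome whose TSS is closest to the peak
#' midpoint; distance ties are broken by lexicographic gene id. Used for the
#' GO-style annotation path; expression integration uses interaction and
#' promoter links only.
#'
#' @param peak one-row peak data.frame (or list with `chrom`, `start`,
#'   `end`).
#' @param gene_table gene-model table.
#' @param k number of genes (default 2).
#' @return character vector of up to `k` gene ids, nearest first.
#' @export
nearest_k_genes <- function(peak, gene_table, k = 2) {
  g <- gene_table[gene_table$chrom == peak$chrom[1], , drop = FALSE]
  if (nrow(g) == 0) return(character(0))
  mid <- floor((peak$start[1] + peak$end[1]) / 2)
  d <- abs(g$tss - mid)
  ord <- order(d, g$gene_id)
  g$gene_id[ord][seq_len(min(k, nrow(g)))]
}
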