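# Readers/writers for the plain-text formats the pipeline touches:
# BED3/BED6 peaks and domains, BEDPE+gene interactions, counts TSV,
# sample sheets, TSS tables, bedGraph-like binned coverage.
# Everything is tab-separated, LF-terminated, deterministic order.

#' Read a BED3/BED6 peak file
#'
#' Coordinates are kept BED-native (0-based half-open). Lines starting with
#' `#`, `track` or `browser` are skipped. When column 4 is absent, names
#' `peak_000001`, ... are generated in input order. Input order is preserved;
#' sorting is never implicit.
#'
#' @param path path to a BED file with >= 3 tab-separated columns.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`
#'   (character, `"0"` when absent) and `strand` (`"."` when absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  data_idx <- which(!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines))
  if (length(data_idx) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", data_idx[which(nf < 3)[1]],
         ": fewer than 3 tab-separated columns in ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop("malformed BED line ", data_idx[bad[1]],
         ": non-numeric coordinates in ", path)
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop("invalid interval at line ", data_idx[bad[1]],
         ": end <= start in ", path)
  name <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "", ""),
                 sprintf("peak_%06d", seq_along(fields)))
  score <- ifelse(nf >= 5, vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "", ""), "0")
  strand <- ifelse(nf >= 6, vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "", ""), ".")
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), name = name, score = score,
                    strand = strand, stringsAsFactors = FALSE)
  validate_intervals(out, what = paste0("BED file ", path))
  out
}

#' Write a peak table as 6-column BED
#'
#' Inverse of [read_bed()]: round-tripping a canonical 6-column BED file is
#' byte-identical.
#'
#' @param x peak data.frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "peak table")
  if (!"name" %in% names(x)) x$name <- sprintf("peak_%06d", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- "0"
  if (!"strand" %in% names(x)) x$strand <- "."
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(x) > 0) {
    writeLines(paste(x$chrom, format_coord(x$start), format_coord(x$end),
                     x$name, x$score, x$strand, sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

# integer-style coordinate formatting (no scientific notation)
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a TSS/gene-model table
#'
#' TSV with header `gene_id`, `gene_name`, `chrom`, `tss`, `strand`.
#' TSS positions are 0-based; converting from 1-based annotation is the
#' caller's responsibility upstream of this loader.
#'
#' @param path path to the TSV.
#' @return validated gene-model data.frame.
#' @export
read_gene_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_gene_table(x)
}

#' Validate a gene-model table
#'
#' @param x data.frame with `gene_id`, `gene_name`, `chrom`, `tss`, `strand`.
#' @return `x` (invisibly validated, returned visibly for chaining).
#' @export
validate_gene_table <- function(x) {
  req <- c("gene_id", "gene_name", "chrom", "tss", "strand")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("gene table: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$gene_id))
    stop("gene table: duplicate gene_id: ",
         x$gene_id[duplicated(x$gene_id)][1])
  if (any(x$tss < 0)) stop("gene table: negative TSS position")
  if (!all(x$strand %in% c("+", "-")))
    stop("gene table: strand must be '+' or '-'")
  x
}

#' Write a gene-model table
#' @param x gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  write_tsv(x[, c("gene_id", "gene_name", "chrom", "tss", "strand")], path)
}

#' Read a sample sheet
#'
#' TSV with header `sample_id`, `condition`, `replicate`, `assay`.
#'
#' @param path path to the TSV.
#' @return validated sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(x)
}

#' Validate a sample sheet
#' @param x data.frame with `sample_id`, `condition`, `replicate`, `assay`.
#' @return `x`.
#' @export
validate_sample_sheet <- function(x) {
  req <- c("sample_id", "condition", "replicate", "assay")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("sample sheet: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("sample sheet: duplicate sample_id: ",
         x$sample_id[duplicated(x$sample_id)][1])
  if (any(x$replicate < 1)) stop("sample sheet: replicate must be >= 1")
  x
}

#' Write a sample sheet
#' @param x sample sheet.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(x, path) {
  write_tsv(x[, c("sample_id", "condition", "replicate", "assay")], path)
}

#' Read a count matrix
#'
#' TSV whose header names the samples and whose first column (`feature_id`)
#' names the features. Counts must be finite non-negative integers. When a
#' sample sheet is supplied, columns are reordered to the sheet order and an
#' error names any sheet sample missing from the header.
#'
#' @param path path to the TSV.
#' @param sample_sheet optional sample sheet whose `sample_id` order the
#'   columns are aligned to.
#' @return integer matrix, features in rows, samples in columns.
#' @export
read_counts <- function(path, sample_sheet = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2) stop("count matrix: need feature_id plus >= 1 sample column")
  ids <- as.character(x[[1]])
  if (anyDuplicated(ids))
    stop("count matrix: duplicate feature_id: ", ids[duplicated(ids)][1])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (any(!is.finite(m))) stop("count matrix: missing or non-finite counts")
  if (any(m < 0)) stop("count matrix: negative counts")
  if (any(m != round(m))) stop("count matrix: non-integer counts")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (!is.null(sample_sheet)) {
    validate_sample_sheet(sample_sheet)
    missing <- setdiff(sample_sheet$sample_id, colnames(m))
    if (length(missing) > 0)
      stop("count matrix: sample(s) in sheet but not in header: ",
           paste(missing, collapse = ", "))
    m <- m[, sample_sheet$sample_id, drop = FALSE]
  }
  m
}

#' Write a count matrix
#' @param m integer matrix with feature rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a promoter-distal interaction map (BEDPE + gene column)
#'
#' The first six columns are the promoter and distal anchors (0-based
#' half-open); column 7 carries a comma-separated list of gene ids for the
#' promoter anchor. Gene ids are filtered against `gene_table`; records with
#' no resolvable gene are dropped with a warning.
#'
#' @param path path to the BEDPE-like file.
#' @param gene_table gene-model table used to resolve gene ids.
#' @return data.frame with `p_chrom`, `p_start`, `p_end`, `d_chrom`,
#'   `d_start`, `d_end` and list-column `gene_ids`.
#' @export
read_bedpe_interactions <- function(path, gene_table) {
  validate_gene_table(gene_table)
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  lines <- readLines(path)
  data_idx <- which(!grepl("^#", lines) & nzchar(lines))
  empty <- data.frame(p_chrom = character(), p_start = integer(),
                      p_end = integer(), d_chrom = character(),
                      d_start = integer(), d_end = integer(),
                      stringsAsFactors = FALSE)
  empty$gene_ids <- list()
  if (length(data_idx) == 0) return(empty)
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7))
    stop("BEDPE line ", data_idx[which(nf < 7)[1]],
         ": need 6 coordinate columns plus a gene-id column in ", path)
  num <- function(k) suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
  out <- data.frame(
    p_chrom = vapply(fields, `[[`, "", 1L), p_start = num(2), p_end = num(3),
    d_chrom = vapply(fields, `[[`, "", 4L), d_start = num(5), d_end = num(6),
    stringsAsFactors = FALSE)
  if (any(is.na(out$p_start) | is.na(out$p_end) | is.na(out$d_start) |
          is.na(out$d_end)))
    stop("BEDPE: non-numeric coordinates in ", path)
  validate_intervals(data.frame(chrom = out$p_chrom, start = out$p_start,
                                end = out$p_end), "BEDPE promoter anchors")
  validate_intervals(data.frame(chrom = out$d_chrom, start = out$d_start,
                                end = out$d_end), "BEDPE distal anchors")
  same <- out$p_chrom == out$d_chrom & out$p_start == out$d_start &
    out$p_end == out$d_end
  if (any(same))
    stop("BEDPE line ", data_idx[which(same)[1]],
         ": promoter and distal anchors identical")
  genes <- strsplit(vapply(fields, `[[`, "", 7L), ",", fixed = TRUE)
  genes <- lapply(genes, function(g) g[g %in% gene_table$gene_id])
  keep <- lengths(genes) > 0
  if (any(!keep))
    warning(sum(!keep), " interaction record(s) dropped: no gene id ",
            "resolvable against the gene table")
  out <- out[keep, , drop = FALSE]
  out$p_start <- as.integer(out$p_start); out$p_end <- as.integer(out$p_end)
  out$d_start <- as.integer(out$d_start); out$d_end <- as.integer(out$d_end)
  out$gene_ids <- genes[keep]
  rownames(out) <- NULL
  out
}

#' Write an interaction map as BEDPE + gene column
#' @param x interaction data.frame (see [read_bedpe_interactions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe_interactions <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(x) > 0) {
    writeLines(paste(x$p_chrom, format_coord(x$p_start), format_coord(x$p_end),
                     x$d_chrom, format_coord(x$d_start), format_coord(x$d_end),
                     vapply(x$gene_ids, paste, "", collapse = ","),
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a binned coverage track (bedGraph-like TSV)
#'
#' Four headerless columns: `chrom`, `start`, `end`, `value`; 0-based
#' half-open bins.
#'
#' @param path path to the TSV.
#' @return data.frame with `chrom`, `start`, `end`, `value`.
#' @export
read_coverage <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "value"))
  validate_intervals(x, "coverage track")
  if (any(!is.finite(x$value))) stop("coverage track: non-finite values")
  x
}

#' Write a binned coverage track
#' @param x coverage data.frame (`chrom`, `start`, `end`, `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(x) > 0) {
    writeLines(paste(x$chrom, format_coord(x$start), format_coord(x$end),
                     format(x$value, scientific = FALSE, trim = TRUE,
                            digits = 15),
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

# header + LF, no quoting, deterministic
write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(x), collapse = "\t"), con, sep = "\n")
  if (nrow(x) > 0) {
    cols <- lapply(x, function(col) {
      if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE,
                                  digits = 15)
      else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}
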