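# Genomic intervals: plain data.frames with columns chrom/start/end
# (0-based half-open), validated once at construction or file boundaries.
# GRanges (1-based closed) is used transiently for overlap machinery only.

#' Validate a table of genomic intervals
#'
#' Checks the universal interval invariants: non-empty chromosome names,
#' `start >= 0`, `end > start`, and (when present) strand in `+`, `-`, `.`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`. Coordinates are 0-based half-open.
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(x, what = "interval table") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop(what, ": missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(as.character(x$chrom))))
    stop(what, ": empty chromosome name")
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    stop(what, ": non-finite coordinates")
  if (any(x$start < 0))
    stop(what, ": negative start coordinate")
  bad <- which(x$end <= x$start)
  if (length(bad) > 0)
    stop(what, ": end <= start at row ", bad[1])
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'")
  invisible(x)
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Midpoint of intervals
#'
#' Integer midpoint `floor((start + end) / 2)` of 0-based half-open intervals.
#'
#' @param x interval data.frame.
#' @return integer vector of midpoints.
#' @export
interval_midpoint <- function(x) {
  as.integer(floor((x$start + x$end) / 2))
}

# Total bp covered by a set of (possibly overlapping) intervals.
covered_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(IRanges::width(GenomicRanges::reduce(as_granges0(x))))
}

#' Jaccard index of two interval sets
#'
#' Base-pair level Jaccard: intersection bp over union bp of the two sets
#' (each reduced first).
#'
#' @param a,b interval data.frames (`chrom`, `start`, `end`).
#' @return scalar in `[0, 1]`; `NA` if both sets are empty.
#' @export
interval_jaccard <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) return(NA_real_)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  ga <- GenomicRanges::reduce(as_granges0(a))
  gb <- GenomicRanges::reduce(as_granges0(b))
  inter <- sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
  uni <- sum(IRanges::width(GenomicRanges::union(ga, gb)))
  inter / uni
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed from a base seed and a string tag (< 2^31)
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
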