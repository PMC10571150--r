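# Differential analysis of count matrices: TMM normalization, moment-based
# shrunk dispersion, an NB Wald test on group means, BH FDR, and the
# gained/lost/unchanged status call at the pipeline thresholds
# (ChIP: FDR < 0.1 and |log2FC| > 0.3; RNA: FDR < 0.1 only).

#' Define a treatment-vs-control contrast
#'
#' @param treatment,control condition labels present in the sample sheet.
#' @param assay assay label (a mark name or `"RNA"`).
#' @return a `contrast` list.
#' @export
contrast <- function(treatment, control, assay) {
  if (identical(treatment, control))
    stop("contrast: treatment and control must differ")
  structure(list(treatment = treatment, control = control, assay = assay),
            class = "contrast")
}

# samples of a contrast, in sheet order; errors if either group has < 2 reps
contrast_samples <- function(sample_sheet, contrast) {
  sel <- sample_sheet[sample_sheet$assay == contrast$assay &
                        sample_sheet$condition %in%
                        c(contrast$treatment, contrast$control), , drop = FALSE]
  n_t <- sum(sel$condition == contrast$treatment)
  n_c <- sum(sel$condition == contrast$control)
  if (n_t < 2 || n_c < 2)
    stop("contrast ", contrast$treatment, " vs ", contrast$control, " (",
         contrast$assay, "): need >= 2 replicates per group, have ",
         n_t, " vs ", n_c)
  sel
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: log ratios vs a reference sample (the one whose
#' upper quartile is closest to the mean upper quartile) are trimmed at 30%
#' (log-ratio) and 5% (intensity) and combined in a precision-weighted mean;
#' factors are rescaled to geometric mean 1. The factor computation is
#' delegated to edgeR.
#'
#' @param counts integer count matrix (features x samples).
#' @return named numeric vector of normalization factors, geometric mean 1.
#' @export
normalize_counts <- function(counts) {
  if (ncol(counts) < 2) stop("normalization needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("normalization error: sample ", colnames(counts)[which(lib == 0)[1]],
         " has zero total count")
  # reference: upper quartile (of nonzero-scaled counts) closest to the mean
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  shared <- counts[, ref] > 0
  for (j in seq_len(ncol(counts))) {
    if (j != ref && !any(shared & counts[, j] > 0))
      stop("normalization error: sample ", colnames(counts)[j],
           " shares no nonzero features with the reference")
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref)
  names(f) <- colnames(counts)
  f
}

# normalized counts: counts scaled so effective library sizes are equal
normalized_counts <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- normalize_counts(counts)
  eff <- colSums(counts) * factors
  sweep(counts, 2, eff / mean(eff), "/")
}

#' Per-feature NB dispersion by moments, shrunk toward the trimmed mean
#'
#' Within-group residual variance on normalized counts yields a
#' method-of-moments dispersion `(var - mean) / denom` with the
#' small-sample-corrected denominator `mean^2 - var/n` (the naive `mean^2`
#' is biased upward by the sampling error of the mean, which deflates the
#' dispersion and, downstream, the test's false-positive control). The raw
#' values are floored at `1e-4`, then shrunk toward the trimmed-mean
#' dispersion with weight `n_prior / (n_prior + residual_df)`.
#'
#' The returned vector carries attributes `prior_weight` and `residual_df`
#' used by [test_differential()]'s t reference.
#'
#' @param counts count matrix.
#' @param sample_sheet sample sheet matching the columns.
#' @param contrast a [contrast()].
#' @param n_prior prior weight of the trimmed-mean dispersion (default 10).
#' @param floor dispersion floor (default `1e-4`).
#' @param trim trim fraction of the cross-feature mean (default 0.05).
#' @return named numeric vector of per-feature dispersions with attributes
#'   `prior_weight`, `residual_df`, and `trimmed_mean`.
#' @export
estimate_dispersion <- function(counts, sample_sheet, contrast,
                                n_prior = 10, floor = 1e-4, trim = 0.05) {
  sel <- contrast_samples(sample_sheet, contrast)
  m <- counts[, sel$sample_id, drop = FALSE]
  y <- normalized_counts(m)
  grp <- sel$condition == contrast$treatment
  n1 <- sum(grp); n0 <- sum(!grp)
  df <- n1 + n0 - 2
  nbar <- (n1 + n0) / 2
  mu1 <- rowMeans(y[, grp, drop = FALSE])
  mu0 <- rowMeans(y[, !grp, drop = FALSE])
  v1 <- apply(y[, grp, drop = FALSE], 1, var)
  v0 <- apply(y[, !grp, drop = FALSE], 1, var)
  v <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
  mu <- (n1 * mu1 + n0 * mu0) / (n1 + n0)
  denom <- pmax(mu^2 - v / nbar, 0.25 * mu^2)
  raw <- ifelse(mu > 0, (v - mu) / denom, floor)
  raw <- pmax(raw, floor)
  tm <- mean(raw[mu > 0], trim = trim)
  if (!is.finite(tm)) tm <- floor
  w <- n_prior / (n_prior + df)
  out <- w * tm + (1 - w) * raw
  names(out) <- rownames(counts)
  attr(out, "prior_weight") <- w
  attr(out, "residual_df") <- df
  attr(out, "trimmed_mean") <- tm
  out
}

#' NB Wald test of a treatment-vs-control contrast
#'
#' Group abundances are means of normalized counts; the Wald statistic
#' contrasts the log abundances (with a prior count of 0.5 taming zeros)
#' with a delta-method variance under the NB model at the supplied
#' dispersions. When the dispersions carry the shrinkage attributes set by
#' [estimate_dispersion()], the statistic is referred to a per-feature
#' Satterthwaite t distribution whose degrees of freedom reflect the
#' effective information of the shrunk dispersion (`residual_df /
#' (1 - prior_weight)^2`, divided by the squared share the dispersion term
#' contributes to the Wald variance); dispersions supplied as a bare vector
#' are treated as known and referred to the normal. `log2fc` is the log2
#' ratio of prior-augmented group means (treatment over control). Features
#' with zero counts in every sample of both groups are dropped.
#'
#' @param counts count matrix.
#' @param sample_sheet sample sheet matching the columns.
#' @param contrast a [contrast()].
#' @param dispersions per-feature dispersions (default: estimated).
#' @param prior_count prior added to group means (default 0.5).
#' @return data.frame with `feature_id`, `mean_logcpm`, `log2fc`, `pvalue`.
#' @export
test_differential <- function(counts, sample_sheet, contrast,
                              dispersions = NULL, prior_count = 0.5) {
  sel <- contrast_samples(sample_sheet, contrast)
  m <- counts[, sel$sample_id, drop = FALSE]
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, sample_sheet, contrast)
  a <- dispersions[rownames(m)]
  factors <- normalize_counts(m)
  eff <- colSums(m) * factors
  s <- eff / mean(eff)                      # relative size factors, mean 1
  y <- sweep(m, 2, s, "/")
  grp <- sel$condition == contrast$treatment
  n1 <- sum(grp); n0 <- sum(!grp)
  q1 <- rowMeans(y[, grp, drop = FALSE]) + prior_count
  q0 <- rowMeans(y[, !grp, drop = FALSE]) + prior_count
  # Var(mean of K_j/s_j) for K_j ~ NB(mu = s_j q, disp a), on the log scale
  var_logmean <- function(q, which_grp) {
    sj <- s[which_grp]
    (q * sum(1 / sj) + a * q^2 * length(sj)) / length(sj)^2 / q^2
  }
  v1 <- var_logmean(q1, grp)
  v0 <- var_logmean(q0, !grp)
  z <- (log(q1) - log(q0)) / sqrt(v1 + v0)
  w <- attr(dispersions, "prior_weight")
  df <- attr(dispersions, "residual_df")
  if (!is.null(w) && !is.null(df) && w < 1) {
    rho <- (a * (1 / n1 + 1 / n0)) / (v1 + v0)  # dispersion share of Var
    d_sat <- (df / (1 - w)^2) / pmax(rho, 1e-8)^2
    p <- pmin(1, 2 * stats::pt(-abs(z), d_sat))
  } else {
    p <- pmin(1, 2 * pnorm(-abs(z)))
  }
  avg_cpm <- ((q1 - prior_count) * n1 + (q0 - prior_count) * n0) /
    (n1 + n0) / mean(eff) * 1e6
  data.frame(feature_id = rownames(m),
             mean_logcpm = log2(avg_cpm + 0.5),
             log2fc = log2(q1 / q0),
             pvalue = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR transform: `q_(i) = min_{j >= i} m p_(j) / j`, ties
#' preserved, original order restored.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of the same length.
#' @export
adjust_bh <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("adjust_bh: p-values must be finite and in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call gained/lost/unchanged status at FDR and log2FC thresholds
#'
#' Adds `fdr` (BH over the table's p-values, unless already present) and
#' `status`: `gained` if `fdr < fdr_threshold` and `log2fc > lfc_threshold`,
#' `lost` if `fdr < fdr_threshold` and `log2fc < -lfc_threshold`, else
#' `unchanged`. ChIP peak calls use `fdr_threshold = 0.1`,
#' `lfc_threshold = 0.3`; expression calls use `lfc_threshold = 0`.
#'
#' @param results data.frame from [test_differential()].
#' @param fdr_threshold FDR gate (default 0.1).
#' @param lfc_threshold absolute log2FC gate (default 0.3).
#' @return `results` with `fdr` and `status` columns appended.
#' @export
call_status <- function(results, fdr_threshold = 0.1, lfc_threshold = 0.3) {
  if (!"fdr" %in% names(results)) results$fdr <- adjust_bh(results$pvalue)
  results$status <- ifelse(
    results$fdr < fdr_threshold & results$log2fc > lfc_threshold, "gained",
    ifelse(results$fdr < fdr_threshold & results$log2fc < -lfc_threshold,
           "lost", "unchanged"))
  results
}

#' Run the full differential pipeline for one contrast
#'
#' Normalization, dispersion estimation, NB Wald test, BH adjustment and
#' status call. BH is applied within this single mark x contrast table,
#' never pooled across marks.
#'
#' @param counts count matrix for one assay.
#' @param sample_sheet sample sheet.
#' @param treatment,control condition labels.
#' @param assay assay label.
#' @param fdr_threshold,lfc_threshold status-call gates; defaults are the
#'   ChIP gates (0.1, 0.3). Use `lfc_threshold = 0` for expression.
#' @return a DifferentialResult data.frame: `feature_id`, `mean_logcpm`,
#'   `log2fc`, `pvalue`, `fdr`, `status`.
#' @export
run_differential <- function(counts, sample_sheet, treatment, control, assay,
                             fdr_threshold = 0.1, lfc_threshold = 0.3) {
  ctr <- contrast(treatment, control, assay)
  disp <- estimate_dispersion(counts, sample_sheet, ctr)
  res <- test_differential(counts, sample_sheet, ctr, dispersions = disp)
  res$fdr <- adjust_bh(res$pvalue)
  call_status(res, fdr_threshold = fdr_threshold,
              lfc_threshold = lfc_threshold)
}
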