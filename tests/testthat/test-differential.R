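test_that("TMM factors are unity for identical or proportional samples", {
  m <- matrix(rpois(400, 50), 200, 2,
              dimnames = list(sprintf("f%03d", 1:200), c("A", "B")))
  m[, 2] <- m[, 1]
  f <- normalize_counts(m)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)

  # B exactly 2x A: composition identical, factors 1; depth carries the 2x
  m2 <- cbind(A = m[, 1], B = 2L * m[, 1])
  f2 <- normalize_counts(m2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12)
  eff <- colSums(m2) * f2
  expect_equal(unname(eff[2] / eff[1]), 2, tolerance = 1e-12)
  expect_equal(prod(f2), 1, tolerance = 1e-12)

  expect_error(normalize_counts(cbind(A = c(0L, 5L), B = c(7L, 0L))),
               "shares no nonzero")
  expect_error(normalize_counts(cbind(A = c(1L, 2L), B = c(0L, 0L))),
               "zero total")
})

test_that("dispersion estimation recovers the floor, Poisson and NB truth", {
  sheet <- data.frame(sample_id = c("C1", "C2", "C3", "T1", "T2", "T3"),
                      condition = rep(c("C", "T"), each = 3),
                      replicate = rep(1:3, 2), assay = "X")
  ctr <- contrast("T", "C", "X")

  const <- matrix(7L, 50, 6,
                  dimnames = list(sprintf("f%02d", 1:50), sheet$sample_id))
  d0 <- estimate_dispersion(const, sheet, ctr)
  expect_equal(as.vector(d0), rep(1e-4, 50))

  set.seed(21)
  pois <- matrix(rpois(2000 * 6, 500), 2000, 6,
                 dimnames = list(sprintf("f%04d", 1:2000), sheet$sample_id))
  dp <- estimate_dispersion(pois, sheet, ctr)
  expect_lte(median(dp), 0.05)

  q <- exp(rnorm(2000, log(200), 1))
  nb <- sapply(1:6, function(j) rnbinom(2000, size = 1 / 0.2, mu = q))
  dimnames(nb) <- dimnames(pois)
  dn <- estimate_dispersion(nb, sheet, ctr)
  expect_equal(attr(dn, "trimmed_mean"), 0.2, tolerance = 0.05)
})

test_that("identical groups give zero log2FC and p-value one; all-zero rows drop", {
  m <- matrix(rpois(300, 40), 50, 6)
  m[, 4:6] <- m[, 1:3]
  m[7, ] <- 0L
  dimnames(m) <- list(sprintf("f%02d", 1:50),
                      c("C1", "C2", "C3", "T1", "T2", "T3"))
  sheet <- data.frame(sample_id = colnames(m),
                      condition = rep(c("C", "T"), each = 3),
                      replicate = rep(1:3, 2), assay = "X")
  res <- test_differential(m, sheet, contrast("T", "C", "X"))
  expect_false("f07" %in% res$feature_id)
  expect_equal(nrow(res), 49)
  expect_equal(res$log2fc, rep(0, 49))
  expect_equal(res$pvalue, rep(1, 49))
})

test_that("swapping treatment and control negates log2FC and keeps p-values", {
  fx <- nb_fixture(n_feat = 300, lfc = 1, frac_dp = 0.2, seed = 5)
  d1 <- estimate_dispersion(fx$counts, fx$sheet, contrast("T", "C", "X"))
  d2 <- estimate_dispersion(fx$counts, fx$sheet, contrast("C", "T", "X"))
  expect_equal(unname(d1), unname(d2))
  r1 <- test_differential(fx$counts, fx$sheet, contrast("T", "C", "X"), d1)
  r2 <- test_differential(fx$counts, fx$sheet, contrast("C", "T", "X"), d2)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$pvalue, r2$pvalue)
})

test_that("planted fold-changes are recovered with small bias", {
  fx <- nb_fixture(n_feat = 2000, lfc = 1, disp = 0.05, mu = 1000,
                   frac_dp = 1, seed = 9, baseline_sd = 0.5)
  res <- test_differential(fx$counts, fx$sheet, contrast("T", "C", "X"))
  sgn <- fx$sign[match(res$feature_id, fx$dp_ids)]
  expect_equal(mean(res$log2fc * sgn), 1, tolerance = 0.15)
})

test_that("BH adjustment matches frozen example and the naive step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.1, NA)), "\\[0, 1\\]")

  set.seed(33)
  for (i in 1:25) {
    n <- sample(1:400, 1)
    p <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(adjust_bh(p), bh_naive(p))
  }
})

test_that("status calls apply both FDR and log2FC gates", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    mean_logcpm = 5, log2fc = c(0.5, 0.2, 2.0, -0.5),
                    pvalue = c(0.001, 0.001, 0.2, 0.001),
                    fdr = c(0.05, 0.05, 0.15, 0.05))
  out <- call_status(res, fdr_threshold = 0.1, lfc_threshold = 0.3)
  expect_equal(out$status, c("gained", "unchanged", "unchanged", "lost"))
  # RNA convention: no fold-change gate
  out_rna <- call_status(res, fdr_threshold = 0.1, lfc_threshold = 0)
  expect_equal(out_rna$status, c("gained", "gained", "unchanged", "lost"))
})

test_that("differential engine agrees with edgeR on strong effects", {
  fx <- nb_fixture(n_feat = 800, lfc = 2, disp = 0.1, frac_dp = 0.1,
                   seed = 17)
  res <- run_differential(fx$counts, fx$sheet, "T", "C", "X")
  y <- edgeR::DGEList(fx$counts,
                      group = factor(fx$sheet$condition, c("C", "T")))
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y)
  tt <- edgeR::topTags(et, n = Inf, sort.by = "none")$table
  # fold-change agreement on the planted features
  idx <- match(fx$dp_ids, res$feature_id)
  expect_gt(cor(res$log2fc[idx], tt[fx$dp_ids, "logFC"]), 0.98)
  # call overlap at the same gate
  mine <- res$feature_id[res$status != "unchanged"]
  theirs <- rownames(tt)[p.adjust(tt$PValue, "BH") < 0.1 &
                           abs(tt$logFC) > 0.3]
  expect_gt(length(intersect(mine, theirs)) /
              max(1, length(union(mine, theirs))), 0.7)
})
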