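make_bins <- function(values, chrom = "chr1", bin = 5000L) {
  n <- length(values)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * bin,
             end = seq_len(n) * bin, value = values,
             stringsAsFactors = FALSE)
}

test_that("domain calling ignores flat or pure-noise tracks", {
  expect_equal(nrow(call_kdd(make_bins(rep(1.5, 200)), 5000)), 0)
  set.seed(3)
  expect_equal(nrow(call_kdd(make_bins(rnorm(5000)), 5000)), 0)
})

test_that("a planted block is recovered and shift invariance holds", {
  set.seed(4)
  v <- rnorm(2000)
  v[801:820] <- v[801:820] + 3      # 100 kb block at +3 SD
  bins <- make_bins(v)
  d <- call_kdd(bins, 5000)
  expect_equal(nrow(d), 1)
  truth <- data.frame(chrom = "chr1", start = 800 * 5000, end = 820 * 5000)
  expect_gte(interval_jaccard(d, truth), 0.8)

  shifted <- bins; shifted$value <- shifted$value + 42
  d2 <- call_kdd(shifted, 5000)
  expect_equal(d2[, c("chrom", "start", "end", "n_bins")],
               d[, c("chrom", "start", "end", "n_bins")])
})

test_that("gap merging joins blocks across short dips only", {
  set.seed(5)
  v <- rnorm(3000)
  v[1001:1010] <- v[1001:1010] + 4
  v[1012:1021] <- v[1012:1021] + 4  # one low bin between blocks
  bins <- make_bins(v)
  merged <- call_kdd(bins, 5000, max_gap_bins = 2, min_domain_length = 5e4)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$end - merged$start, 21 * 5000)
  split2 <- call_kdd(bins, 5000, max_gap_bins = 0, min_domain_length = 5e4)
  expect_equal(nrow(split2), 2)
})

test_that("non-uniform bin widths are rejected", {
  bins <- make_bins(rnorm(100))
  bins$end[5] <- bins$end[5] + 1L
  expect_error(call_kdd(bins, 5000), "non-uniform")
})

test_that("domain comparison matches, measures ratios and flags the unmatched", {
  ctrl <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(0L, 500000L, 0L),
                     end = c(100000L, 700000L, 80000L),
                     stringsAsFactors = FALSE)
  same <- compare_domains(ctrl, ctrl)
  expect_equal(same$changes$size_log2_ratio, rep(0, 3))
  expect_false(any(same$changes$changed))
  expect_equal(unname(same$summary["bp_log2_ratio"]), 0)

  half <- ctrl[1, ]; half$end <- 50000L
  cmp <- compare_domains(ctrl[1, , drop = FALSE], half)
  expect_equal(cmp$changes$size_log2_ratio, -1)
  expect_true(cmp$changes$changed)

  gone <- compare_domains(ctrl, ctrl[-2, , drop = FALSE])
  row2 <- gone$changes[gone$changes$control_start == 500000, ]
  expect_equal(row2$size_log2_ratio, -Inf)
  expect_true(row2$changed)
})

test_that("DEG proximity permutation detects planted clustering and honors edge cases", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:300), gene_name = "x",
                      chrom = "chr1",
                      tss = as.integer(seq(5000, 3e6, length.out = 300)),
                      strand = "+", stringsAsFactors = FALSE)
  dom <- data.frame(chrom = "chr1", start = 1000000L, end = 1100000L)
  inside <- genes$gene_id[genes$tss >= 9e5 & genes$tss <= 1.2e6]
  res <- deg_proximity_test(dom, inside, genes, flank = 1e5, n_perm = 1000,
                            seed = 7)
  expect_equal(res$observed, length(inside))
  expect_lte(res$p_value, 0.01)

  none <- deg_proximity_test(dom[0, ], inside, genes, seed = 7)
  expect_equal(none$observed, 0L)
  expect_equal(none$p_value, 1)

  expect_error(deg_proximity_test(dom, "not_a_gene", genes, seed = 7),
               "not in gene table")
  expect_error(deg_proximity_test(dom, inside, genes, n_perm = 10, seed = 7),
               "n_perm")
})

test_that("proximity p-values are reproducible under a fixed seed", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200), gene_name = "x",
                      chrom = "chr1",
                      tss = as.integer(seq(5000, 2e6, length.out = 200)),
                      strand = "+", stringsAsFactors = FALSE)
  dom <- data.frame(chrom = "chr1", start = 500000L, end = 700000L)
  degs <- genes$gene_id[seq(1, 200, by = 5)]
  p1 <- deg_proximity_test(dom, degs, genes, n_perm = 200, seed = 99)
  p2 <- deg_proximity_test(dom, degs, genes, n_perm = 200, seed = 99)
  expect_identical(p1, p2)
})
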