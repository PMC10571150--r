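small_cfg <- function(...) {
  args <- list(seed = 11, n_chroms = 2, chrom_length = 5e6, n_genes = 200,
               n_peaks_per_mark = c(H3K27ac = 200L),
               conditions = c("control", "T1"),
               replicates_per_condition = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

test_that("config validation rejects out-of-range parameters", {
  expect_error(small_cfg(frac_dp = 1.5), "frac_dp")
  expect_error(small_cfg(replicates_per_condition = 1), "replicates")
  expect_error(small_cfg(effect_log2fc = -1), "effect_log2fc")
  expect_error(simulation_config(conditions = "control"), "treatment")
})

test_that("genome simulation places genes with spacing and honors linkage fraction", {
  cfg <- small_cfg()
  geo <- simulate_genome(cfg)
  expect_equal(nrow(geo$genes), 200)
  expect_true(all(geo$genes$tss < cfg$chrom_length))
  for (cn in unique(geo$genes$chrom)) {
    tss <- sort(geo$genes$tss[geo$genes$chrom == cn])
    expect_true(all(diff(tss) >= 5000))
  }
  # placement classes partition the atlas at the configured fraction
  pl <- geo$placement$H3K27ac
  expect_equal(sum(pl$class == "promoter"), round(0.3 * 200))
  # linked distal peaks match frac_enhancer_linked
  expect_equal(nrow(geo$interactions),
               round(0.5 * sum(pl$class == "distal")))

  geo0 <- simulate_genome(small_cfg(frac_enhancer_linked = 0))
  expect_equal(nrow(geo0$interactions), 0)

  expect_error(simulate_genome(small_cfg(n_genes = 100000L)), "too small")
})

test_that("identical config and seed reproduce identical tables", {
  cfg <- small_cfg()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$chip$H3K27ac$counts, b$chip$H3K27ac$counts)
  expect_identical(a$rna$counts, b$rna$counts)
  expect_identical(a$truth, b$truth)
})

test_that("null config produces empty truth sets", {
  cfg <- small_cfg(frac_dp = 0, couple_prob = 0, frac_deg_background = 0,
                   frac_kdd_changed = 0)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$dp$H3K27ac$T1), 0)
  expect_equal(nrow(sim$truth$deg$T1), 0)
  expect_equal(length(sim$truth$kdd_changed$T1), 0)
})

test_that("planted ChIP shifts reproduce the configured log2FC in the count means", {
  # near-zero dispersion and deep counts: empirical ratio ~ 2^(sign * effect)
  cfg <- small_cfg(effect_log2fc = 2, nb_dispersion = 0.005,
                   baseline_logmean_mu = log(2000), baseline_logmean_sd = 0.3,
                   replicates_per_condition = 3, frac_dp = 0.2,
                   lib_size_range = c(1, 1))
  geo <- simulate_genome(cfg)
  truth <- draw_chip_truth(cfg, geo$peaks)
  sim <- simulate_chip_counts(cfg, geo$peaks$H3K27ac, truth, "H3K27ac")
  grp_t <- sim$samples$condition == "T1"
  ratio <- log2(rowMeans(sim$counts[, grp_t]) / rowMeans(sim$counts[, !grp_t]))
  td <- truth$dp$H3K27ac$T1
  expect_equal(unname(ratio[td$peak_id]), 2 * td$sign, tolerance = 0.12)
  expect_lt(max(abs(ratio[setdiff(rownames(sim$counts), td$peak_id)])), 0.5)
})

test_that("forced coupling makes DEG truth exactly the H3K27ac-linked genes", {
  cfg <- small_cfg(couple_prob = 1, frac_deg_background = 0, frac_dp = 0.2)
  geo <- simulate_genome(cfg)
  truth <- draw_chip_truth(cfg, geo$peaks)
  truth$placement <- geo$placement
  rna <- simulate_rna_counts(cfg, geo$genes, geo$interactions, truth)
  td <- truth$dp$H3K27ac$T1
  link_genes <- unique(c(
    vapply(geo$interactions$gene_ids[geo$interactions$peak_id %in% td$peak_id],
           `[[`, "", 1L),
    na.omit(geo$placement$H3K27ac$gene_id[
      geo$placement$H3K27ac$name %in% td$peak_id &
        geo$placement$H3K27ac$class == "promoter"])))
  expect_setequal(rna$deg$T1$gene_id, link_genes)

  rna0 <- simulate_rna_counts(small_cfg(couple_prob = 0,
                                        frac_deg_background = 0),
                              geo$genes, geo$interactions, truth)
  expect_equal(nrow(rna0$deg$T1), 0)
})

test_that("coupling probability thins linked genes binomially", {
  hits <- vapply(1:30, function(s) {
    cfg <- small_cfg(seed = 100 + s, couple_prob = 0.5,
                     frac_deg_background = 0, frac_dp = 0.2)
    geo <- simulate_genome(cfg)
    truth <- draw_chip_truth(cfg, geo$peaks)
    truth$placement <- geo$placement
    rna <- simulate_rna_counts(cfg, geo$genes, geo$interactions, truth)
    td <- truth$dp$H3K27ac$T1
    n_link <- length(unique(c(
      vapply(geo$interactions$gene_ids[geo$interactions$peak_id %in%
                                         td$peak_id], `[[`, "", 1L),
      na.omit(geo$placement$H3K27ac$gene_id[
        geo$placement$H3K27ac$name %in% td$peak_id &
          geo$placement$H3K27ac$class == "promoter"]))))
    nrow(rna$deg$T1) / n_link
  }, numeric(1))
  # mean retention over seeds concentrates near couple_prob
  expect_equal(mean(hits), 0.5, tolerance = 0.1)
})

test_that("KDD coverage plants elevated bins and honors the effect switch", {
  cfg <- small_cfg(n_kdd = 1, kdd_length_range = c(1e5, 1e5),
                   kdd_signal = 3, bin_size = 5000L)
  kdd <- simulate_kdd_coverage(cfg)
  d <- kdd$domains$control
  expect_equal(nrow(d), 1)
  expect_equal(d$end - d$start, 1e5)
  cv <- kdd$coverage$control
  inside <- cv$chrom == d$chrom & cv$start >= d$start & cv$end <= d$end
  expect_equal(sum(inside), 20)  # 100 kb / 5 kb bins
  expect_gt(mean(cv$value[inside]) - mean(cv$value[!inside]), 2)

  flat <- simulate_kdd_coverage(small_cfg(n_kdd = 0))
  expect_equal(nrow(flat$domains$control), 0)
  expect_lt(max(abs(flat$coverage$control$value)), 6)

  frozen <- simulate_kdd_coverage(small_cfg(kdd_effect = 0, n_kdd = 3,
                                            kdd_length_range = c(6e4, 1e5)))
  expect_identical(frozen$domains$control[, c("start", "end")],
                   frozen$domains$T1[, c("start", "end")])
})

test_that("fixture bundles are byte-identical across reruns and read back", {
  cfg <- small_cfg(n_kdd = 2, kdd_length_range = c(6e4, 1e5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim <- simulate_dataset(cfg)
  write_dataset(sim, d1)
  write_dataset(simulate_dataset(cfg), d2)
  h1 <- dir_digests(d1); h2 <- dir_digests(d2)
  expect_identical(names(h1), names(h2))
  expect_identical(unname(h1), unname(h2))
  # read-back fidelity
  sheet <- read_sample_sheet(file.path(d1, "sample_sheet.tsv"))
  m <- read_counts(file.path(d1, "counts_H3K27ac.tsv"),
                   sheet[sheet$assay == "H3K27ac", ])
  expect_identical(m, sim$chip$H3K27ac$counts)
  expect_identical(read_gene_table(file.path(d1, "genes.tsv")), sim$genes)
})
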