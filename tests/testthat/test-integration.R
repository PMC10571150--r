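test_that("cross-tabulation does set arithmetic over the declared universe", {
  uni <- paste0("g", 1:5)
  expect_equal(unname(crosstab_dp_deg(c("g1", "g2"), c("g2", "g3"), uni)),
               c(1, 1, 1, 2))
  expect_equal(crosstab_dp_deg(c("g1"), c("g2"), uni)[["a"]], 0)
  expect_equal(unname(crosstab_dp_deg(uni, uni, uni)), c(5, 0, 0, 0))
  expect_error(crosstab_dp_deg(c("gX"), c("g1"), uni), "outside the universe")
})

test_that("Fisher p-values match hand-enumerated tables and odds-ratio rules", {
  r <- fisher_exact(c(3, 1, 1, 3))
  expect_equal(r$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(r$odds_ratio, 9)

  r2 <- fisher_exact(c(0, 5, 5, 0))
  expect_equal(r2$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r2$odds_ratio, 0)

  r3 <- fisher_exact(c(0, 0, 5, 5))  # degenerate margin: single table
  expect_equal(r3$p_value, 1)

  expect_equal(fisher_exact(c(4, 0, 1, 3))$odds_ratio, Inf)
  expect_equal(fisher_exact(c(0, 3, 2, 0))$odds_ratio, 0)
  expect_true(is.nan(fisher_exact(c(0, 0, 2, 0))$odds_ratio))
  expect_error(fisher_exact(c(-1, 1, 1, 1)), "non-negative")
})

test_that("Fisher enumeration agrees with brute force and stats::fisher.test", {
  set.seed(8)
  for (i in 1:200) {
    tab <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    mine <- fisher_exact(tab)$p_value
    expect_equal(mine, fisher_bruteforce(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(mine, ft, tolerance = 1e-7)
  }
})

test_that("promoter split sums to one and handles the empty case", {
  ann <- data.frame(element_id = paste0("p", 1:4),
                    element_class = c("promoter", "enhancer", NA, "enhancer"),
                    stringsAsFactors = FALSE)
  fr <- promoter_fraction(paste0("p", 1:4), ann)
  expect_equal(unname(fr), c(0.25, 0.75))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(promoter_fraction("p1", ann)), c(1, 0))
  expect_true(all(is.na(promoter_fraction(character(0), ann))))
  expect_error(promoter_fraction("nope", ann), "not in annotation")
})

test_that("activation status follows the gain/loss rule", {
  expect_equal(activation_status("dp1", character(0)), "activated")
  expect_equal(activation_status(character(0), "dp1"), "repressed")
  expect_equal(activation_status("dp1", "dp2"), "ambiguous")
  expect_equal(activation_status(character(0), character(0)), "unchanged")
})

test_that("overlapping same-gene peaks merge into one regulatory element", {
  ann <- data.frame(element_id = c("pk1", "pk2", "pk3"),
                    chrom = "chr1",
                    start = c(100L, 300L, 5000L), end = c(400L, 700L, 5400L),
                    element_class = c("enhancer", "enhancer", "enhancer"),
                    link_source = "interaction", stringsAsFactors = FALSE)
  ann$gene_ids <- list("gA", c("gA", "gB"), "gA")
  el <- build_regulatory_elements(ann)
  expect_equal(nrow(el), 2)  # pk1+pk2 merge; pk3 distinct (no overlap)
  merged <- el[vapply(el$peak_ids, length, 1L) == 2, ]
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 700L)
  expect_setequal(merged$gene_ids[[1]], c("gA", "gB"))
})

test_that("activation matrix keeps regulated elements and encodes mixed states", {
  el <- data.frame(element_id = c("e1", "e2", "e3"), chrom = "chr1",
                   start = c(1L, 100L, 200L), end = c(50L, 150L, 250L),
                   element_class = c("enhancer", "promoter", "enhancer"),
                   stringsAsFactors = FALSE)
  el$gene_ids <- list("gA", "gB", "gC")
  el$peak_ids <- list(c("pk1", "pk2"), "pk3", "pk4")
  dp <- list(
    T1 = data.frame(feature_id = c("pk1", "pk2", "pk3", "pk4"),
                    status = c("gained", "lost", "gained", "unchanged"),
                    stringsAsFactors = FALSE),
    T2 = data.frame(feature_id = c("pk1", "pk2", "pk3", "pk4"),
                    status = c("unchanged", "unchanged", "lost", "unchanged"),
                    stringsAsFactors = FALSE))
  act <- build_activation_matrix(el, dp, require_deg = FALSE)
  expect_equal(rownames(act$matrix), c("e1", "e2"))  # e3 never regulated
  expect_equal(unname(act$matrix["e1", ]), c("ambiguous", "unchanged"))
  expect_equal(unname(act$matrix["e2", ]), c("activated", "repressed"))
  expect_equal(unname(act$summary["promoters"]), 1L)

  # the DEG filter retains only elements whose genes are modulated
  act2 <- build_activation_matrix(el, dp, deg_by_treatment = list(T1 = "gB"),
                                  require_deg = TRUE)
  expect_equal(rownames(act2$matrix), "e2")

  # full matrix for truth recovery includes the quiet element
  act3 <- build_activation_matrix(el, dp, require_deg = FALSE,
                                  regulated_only = FALSE)
  expect_equal(nrow(act3$matrix), 3)
  expect_equal(unname(act3$matrix["e3", ]), c("unchanged", "unchanged"))
})

test_that("coupled simulation yields a strong Fisher association", {
  cfg <- simulation_config(seed = 41, n_chroms = 2, chrom_length = 1e7,
                           n_genes = 500,
                           n_peaks_per_mark = c(H3K27ac = 500L),
                           conditions = c("control", "T1"),
                           replicates_per_condition = 3,
                           effect_log2fc = 3, couple_prob = 1,
                           frac_deg_background = 0, frac_dp = 0.1)
  sim <- simulate_dataset(cfg)
  ann <- link_peaks_to_genes(sim$peaks$H3K27ac, sim$interactions, sim$genes)
  dp <- list(T1 = run_differential(sim$chip$H3K27ac$counts,
                                   sim$chip$H3K27ac$samples,
                                   "T1", "control", "H3K27ac"))
  rna <- run_differential(sim$rna$counts, sim$rna$samples, "T1", "control",
                          "RNA", lfc_threshold = 0)
  deg <- list(T1 = rna$feature_id[rna$status != "unchanged"])
  uni <- rownames(sim$rna$counts)[rowSums(sim$rna$counts) > 0]
  assoc <- associate_dp_deg(dp, ann, deg, uni)
  expect_lt(assoc$p_value, 0.01)
  expect_gt(assoc$odds_ratio, 1)
  expect_equal(assoc$a + assoc$b + assoc$c + assoc$d, length(uni))
})
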