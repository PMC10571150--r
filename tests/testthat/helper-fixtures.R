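# Shared fixture builders and independent oracles used across test files.

# tiny gene-model table with evenly spaced TSSs on one chromosome
tiny_genes <- function(tss = c(4000, 7000, 20000), chrom = "chr1",
                       ids = NULL) {
  n <- length(tss)
  if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
  data.frame(gene_id = ids, gene_name = toupper(ids),
             chrom = rep(chrom, length.out = n), tss = as.integer(tss),
             strand = rep(c("+", "-"), length.out = n),
             stringsAsFactors = FALSE)
}

# peak table from parallel vectors
peaks_df <- function(chrom, start, end, name = NULL) {
  n <- length(start)
  if (is.null(name)) name <- sprintf("pk%02d", seq_len(n))
  data.frame(chrom = rep(chrom, length.out = n), start = as.integer(start),
             end = as.integer(end), name = name, score = "0", strand = ".",
             stringsAsFactors = FALSE)
}

# NB count matrix with a sample sheet: two groups, optional planted log2FC
nb_fixture <- function(n_feat = 500, n_per_group = 3, mu = 200, disp = 0.1,
                       lfc = 0, frac_dp = 0, seed = 1, assay = "X",
                       baseline_sd = 1) {
  set.seed(seed)
  q <- exp(rnorm(n_feat, log(mu), baseline_sd))
  n_dp <- round(frac_dp * n_feat)
  dp_idx <- if (n_dp > 0) sort(sample.int(n_feat, n_dp)) else integer(0)
  sgn <- sample(c(-1, 1), n_feat, replace = TRUE)
  eff <- rep(1, n_feat)
  eff[dp_idx] <- 2^(sgn[dp_idx] * lfc)
  counts <- cbind(
    sapply(seq_len(n_per_group), function(j)
      rnbinom(n_feat, size = 1 / disp, mu = q)),
    sapply(seq_len(n_per_group), function(j)
      rnbinom(n_feat, size = 1 / disp, mu = q * eff)))
  rownames(counts) <- sprintf("f%04d", seq_len(n_feat))
  colnames(counts) <- c(sprintf("C_rep%d", seq_len(n_per_group)),
                        sprintf("T_rep%d", seq_len(n_per_group)))
  sheet <- data.frame(
    sample_id = colnames(counts),
    condition = rep(c("C", "T"), each = n_per_group),
    replicate = rep(seq_len(n_per_group), 2),
    assay = assay, stringsAsFactors = FALSE)
  list(counts = counts, sheet = sheet,
       dp_ids = rownames(counts)[dp_idx], sign = sgn[dp_idx])
}

# naive O(n^2) Benjamini-Hochberg step-up, straight from the definition
bh_naive <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(m * p[ord][i:m] / (i:m)), numeric(1))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# brute-force two-sided Fisher p from exact binomial coefficients
fisher_bruteforce <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  obs <- probs[xs == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force hypergeometric upper tail P(X >= k)
hyper_tail_bruteforce <- function(k, set_size, universe, query) {
  xs <- k:min(set_size, query)
  if (length(xs) == 0 || k > min(set_size, query)) return(0)
  sum(choose(set_size, xs) * choose(universe - set_size, query - xs)) /
    choose(universe, query)
}

# md5 digests of every file in a directory (relative names), excluding logs
dir_digests <- function(dir, exclude = "run.log") {
  files <- setdiff(list.files(dir, recursive = TRUE), exclude)
  out <- tools::md5sum(file.path(dir, files))
  names(out) <- files
  out
}
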