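# Synthetic-data generator: a labelled, seed-deterministic emulation of the
# study design the pipeline assumes -- several treatments against an
# untreated control, >=2 replicates, four histone marks with NB-distributed
# peak counts, a minority of peaks carrying planted log2FC shifts,
# expression shifts coupled to H3K27ac changes at interaction-linked
# enhancers/promoters, and broad H3K9me2 domains in binned coverage.

#' Build and validate a simulation configuration
#'
#' Defaults describe the "paper-shaped" design: four treatments plus an
#' untreated control, two replicates, four histone marks with 2,000 peaks
#' each, 2,000 genes, NB counts with dispersion 0.1 around a median depth
#' of 200 reads per peak, planted |log2FC| shifts of 1.5 in 5% of peaks,
#' and a dozen broad H3K9me2 domains per genome.
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @param n_chroms,chrom_length genome geometry (bp).
#' @param n_genes number of genes, placed with >= 5 kb spacing.
#' @param n_peaks_per_mark named integer vector, peaks per histone mark.
#' @param conditions condition labels; the first is the untreated control.
#' @param replicates_per_condition replicates per condition (>= 2).
#' @param frac_dp fraction of peaks per treatment x mark given a planted
#'   shift.
#' @param effect_log2fc magnitude of planted shifts (sign drawn at random).
#' @param nb_dispersion common NB dispersion of simulated counts.
#' @param baseline_logmean_mu,baseline_logmean_sd natural-log mean and sd of
#'   per-feature baseline abundance.
#' @param lib_size_range min/max of the uniform per-sample depth multiplier.
#' @param frac_promoter_peaks fraction of each mark's peaks placed inside
#'   promoter windows (the rest are distal).
#' @param frac_enhancer_linked fraction of distal peaks entered into the
#'   interaction map.
#' @param couple_prob probability that a gene linked to a planted H3K27ac
#'   gain/loss is planted as an up/down DEG with matching sign.
#' @param frac_deg_background fraction of genes with mark-independent
#'   expression shifts.
#' @param n_kdd,kdd_length_range,kdd_effect,frac_kdd_changed,kdd_signal
#'   H3K9me2 domain parameters: number, bp length range, fractional
#'   shrink/grow of changed domains, fraction changed per treatment, and
#'   in-domain enrichment shift in background-SD units.
#' @param bin_size coverage bin width (bp).
#' @param peak_width_range min/max peak width (bp).
#' @param promoter_window promoter half-width around the TSS (bp).
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 4L,
                              chrom_length = 2.5e7,
                              n_genes = 2000L,
                              n_peaks_per_mark = c(H3K27ac = 2000L,
                                                   H3K4me1 = 2000L,
                                                   H3K9me2 = 2000L,
                                                   H3K27me3 = 2000L),
                              conditions = c("control", "Fe2O3", "Fe2O3Co",
                                             "FeSO4", "CoCl2"),
                              replicates_per_condition = 2L,
                              frac_dp = 0.05,
                              effect_log2fc = 1.5,
                              nb_dispersion = 0.1,
                              baseline_logmean_mu = log(200),
                              baseline_logmean_sd = 1,
                              lib_size_range = c(0.8, 1.2),
                              frac_promoter_peaks = 0.3,
                              frac_enhancer_linked = 0.5,
                              couple_prob = 0.8,
                              frac_deg_background = 0.02,
                              n_kdd = 12L,
                              kdd_length_range = c(8e4, 2e5),
                              kdd_effect = 0.3,
                              frac_kdd_changed = 0.5,
                              kdd_signal = 3,
                              bin_size = 5000L,
                              peak_width_range = c(400L, 1200L),
                              promoter_window = 1000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              n_peaks_per_mark = n_peaks_per_mark,
              conditions = conditions,
              replicates_per_condition = as.integer(replicates_per_condition),
              frac_dp = frac_dp, effect_log2fc = effect_log2fc,
              nb_dispersion = nb_dispersion,
              baseline_logmean_mu = baseline_logmean_mu,
              baseline_logmean_sd = baseline_logmean_sd,
              lib_size_range = lib_size_range,
              frac_promoter_peaks = frac_promoter_peaks,
              frac_enhancer_linked = frac_enhancer_linked,
              couple_prob = couple_prob,
              frac_deg_background = frac_deg_background,
              n_kdd = as.integer(n_kdd), kdd_length_range = kdd_length_range,
              kdd_effect = kdd_effect, frac_kdd_changed = frac_kdd_changed,
              kdd_signal = kdd_signal, bin_size = as.integer(bin_size),
              peak_width_range = peak_width_range,
              promoter_window = as.integer(promoter_window))
  fracs <- c(frac_dp = cfg$frac_dp,
             frac_promoter_peaks = cfg$frac_promoter_peaks,
             frac_enhancer_linked = cfg$frac_enhancer_linked,
             couple_prob = cfg$couple_prob,
             frac_deg_background = cfg$frac_deg_background,
             frac_kdd_changed = cfg$frac_kdd_changed)
  bad <- which(fracs < 0 | fracs > 1)
  if (length(bad) > 0)
    stop("simulation config: ", names(fracs)[bad[1]], " must be in [0, 1]")
  if (cfg$replicates_per_condition < 2)
    stop("simulation config: replicates_per_condition must be >= 2")
  if (cfg$effect_log2fc <= 0)
    stop("simulation config: effect_log2fc must be positive")
  if (cfg$nb_dispersion <= 0)
    stop("simulation config: nb_dispersion must be positive")
  if (any(cfg$lib_size_range <= 0) || diff(cfg$lib_size_range) < 0)
    stop("simulation config: invalid lib_size_range")
  if (length(cfg$conditions) < 2)
    stop("simulation config: need a control plus >= 1 treatment")
  if (is.null(names(cfg$n_peaks_per_mark)))
    stop("simulation config: n_peaks_per_mark must be a named vector")
  structure(cfg, class = "sim_config")
}

treatments_of <- function(config) config$conditions[-1]

#' Simulate genome geometry: genes, peak atlases, interaction map
#'
#' Genes are placed uniformly on a 5 kb grid (guaranteeing >= 5 kb spacing);
#' per mark, `frac_promoter_peaks` of the peaks are centred on sampled TSSs
#' (inside the promoter window) and the rest are placed distal to every
#' promoter window. `frac_enhancer_linked` of the distal peaks become
#' interaction records pointing at sampled genes' promoters.
#'
#' @param config a `sim_config`.
#' @return list with `genes` (gene-model table), `peaks` (named list of peak
#'   tables per mark), `interactions` (interaction map with an extra
#'   `peak_id` column tying each record to its distal peak), and `placement`
#'   (named list per mark: data.frame `name`, `class` in promoter/distal,
#'   `gene_id` for promoter peaks).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  spacing <- 5000
  slots_per_chrom <- floor((config$chrom_length - spacing) / spacing)
  if (config$n_genes > slots_per_chrom * config$n_chroms)
    stop("genome too small: cannot place ", config$n_genes,
         " genes with 5 kb spacing")
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  genes <- do.call(rbind, lapply(seq_len(config$n_chroms), function(ci) {
    n <- per_chrom[ci]
    if (n == 0) return(NULL)
    slots <- sort(sample.int(slots_per_chrom, n))
    data.frame(chrom = chroms[ci], tss = as.integer(slots * spacing),
               stringsAsFactors = FALSE)
  }))
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes$gene_name <- toupper(genes$gene_id)
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes <- genes[, c("gene_id", "gene_name", "chrom", "tss", "strand")]

  win <- config$promoter_window
  marks <- names(config$n_peaks_per_mark)
  peaks <- list(); placement <- list(); inter_rows <- list()
  for (mark in marks) {
    n <- config$n_peaks_per_mark[[mark]]
    n_prom <- round(config$frac_promoter_peaks * n)
    n_dist <- n - n_prom
    widths <- as.integer(round(runif(n, config$peak_width_range[1],
                                     config$peak_width_range[2])))
    # promoter peaks: centred within +/- win/2 of a sampled TSS
    gi <- sample.int(nrow(genes), n_prom, replace = n_prom > nrow(genes))
    centers_p <- genes$tss[gi] + as.integer(round(runif(n_prom, -win / 2, win / 2)))
    # distal peaks: rejection-sample positions > win + width from every TSS
    centers_d <- integer(0); chrom_d <- character(0)
    if (n_dist > 0) {
      need <- n_dist; tries <- 0
      while (need > 0) {
        tries <- tries + 1
        if (tries > 50)
          stop("genome too small: cannot place distal peaks away from promoters")
        cand_chrom <- sample(chroms, 2 * need, replace = TRUE)
        cand_pos <- as.integer(round(runif(2 * need, 2000,
                                           config$chrom_length - 2000)))
        ok <- vapply(seq_along(cand_pos), function(k) {
          tss_k <- genes$tss[genes$chrom == cand_chrom[k]]
          length(tss_k) == 0 || min(abs(tss_k - cand_pos[k])) > win + 1500
        }, logical(1))
        take <- which(ok)[seq_len(min(need, sum(ok)))]
        centers_d <- c(centers_d, cand_pos[take])
        chrom_d <- c(chrom_d, cand_chrom[take])
        need <- n_dist - length(centers_d)
      }
    }
    pk <- data.frame(
      chrom = c(genes$chrom[gi], chrom_d),
      center = c(centers_p, centers_d),
      width = widths,
      class = rep(c("promoter", "distal"), c(n_prom, n_dist)),
      gene_id = c(genes$gene_id[gi], rep(NA_character_, n_dist)),
      stringsAsFactors = FALSE)
    pk$start <- pmax(0L, as.integer(pk$center - floor(pk$width / 2)))
    pk$end <- pk$start + pk$width
    ord <- order(pk$chrom, pk$start)
    pk <- pk[ord, , drop = FALSE]
    pk$name <- sprintf("%s_peak_%05d", mark, seq_len(nrow(pk)))
    peaks[[mark]] <- data.frame(chrom = pk$chrom, start = pk$start,
                                end = pk$end, name = pk$name, score = "0",
                                strand = ".", stringsAsFactors = FALSE)
    placement[[mark]] <- data.frame(name = pk$name, class = pk$class,
                                    gene_id = pk$gene_id,
                                    stringsAsFactors = FALSE)
    # interaction records from a sample of this mark's distal peaks
    dist_idx <- which(pk$class == "distal")
    n_link <- round(config$frac_enhancer_linked * length(dist_idx))
    if (n_link > 0) {
      li <- sort(sample(dist_idx, n_link))
      tgt <- sample.int(nrow(genes), n_link, replace = n_link > nrow(genes))
      inter_rows[[mark]] <- data.frame(
        p_chrom = genes$chrom[tgt],
        p_start = pmax(0L, genes$tss[tgt] - win),
        p_end = genes$tss[tgt] + win + 1L,
        d_chrom = pk$chrom[li], d_start = pk$start[li], d_end = pk$end[li],
        gene = genes$gene_id[tgt], peak_id = pk$name[li],
        stringsAsFactors = FALSE)
    }
  }
  interactions <- if (length(inter_rows) > 0) {
    x <- do.call(rbind, inter_rows)
    rownames(x) <- NULL
    x$gene_ids <- as.list(x$gene)
    x$gene <- NULL
    x
  } else {
    x <- data.frame(p_chrom = character(), p_start = integer(),
                    p_end = integer(), d_chrom = character(),
                    d_start = integer(), d_end = integer(),
                    peak_id = character(), stringsAsFactors = FALSE)
    x$gene_ids <- list()
    x
  }
  list(genes = genes, peaks = peaks, interactions = interactions,
       placement = placement)
}

#' Draw planted differential-peak truth
#'
#' Per mark x treatment, samples `frac_dp` of the peaks as true differential
#' peaks with a random sign. The control carries no effects.
#'
#' @param config a `sim_config`.
#' @param peaks named list of peak tables (from [simulate_genome()]).
#' @return truth list: `truth$dp[[mark]][[treatment]]` is a data.frame with
#'   `peak_id` and `sign` (+1/-1).
#' @export
draw_chip_truth <- function(config, peaks) {
  set.seed(derive_seed(config$seed, "chip_truth"))
  dp <- lapply(names(peaks), function(mark) {
    n <- nrow(peaks[[mark]])
    n_dp <- round(config$frac_dp * n)
    out <- lapply(treatments_of(config), function(tr) {
      idx <- sort(sample.int(n, n_dp))
      data.frame(peak_id = peaks[[mark]]$name[idx],
                 sign = sample(c(-1L, 1L), n_dp, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    names(out) <- treatments_of(config)
    out
  })
  names(dp) <- names(peaks)
  list(dp = dp)
}

# shared NB sampler: features x (conditions x replicates)
nb_count_matrix <- function(config, feature_ids, effect_l2fc_by_condition,
                            assay) {
  n_feat <- length(feature_ids)
  conds <- config$conditions
  reps <- config$replicates_per_condition
  sample_ids <- as.vector(vapply(conds, function(cn)
    sprintf("%s_%s_rep%d", assay, cn, seq_len(reps)), character(reps)))
  sheet <- data.frame(
    sample_id = sample_ids,
    condition = rep(conds, each = reps),
    replicate = rep(seq_len(reps), times = length(conds)),
    assay = assay, stringsAsFactors = FALSE)
  q <- exp(rnorm(n_feat, config$baseline_logmean_mu,
                 config$baseline_logmean_sd))
  L <- runif(nrow(sheet), config$lib_size_range[1], config$lib_size_range[2])
  counts <- matrix(0L, n_feat, nrow(sheet),
                   dimnames = list(feature_ids, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    l2 <- effect_l2fc_by_condition[[sheet$condition[j]]]
    mu <- L[j] * q * if (is.null(l2)) 1 else 2^l2
    counts[, j] <- as.integer(rnbinom(n_feat, size = 1 / config$nb_dispersion,
                                      mu = mu))
  }
  list(counts = counts, samples = sheet)
}

#' Simulate ChIP-seq peak counts for one mark
#'
#' Count for peak i in sample j is NB with mean
#' `L_j * q_i * 2^(sign * effect_log2fc)` when peak i is a planted DP for
#' sample j's treatment (control samples never carry effects), common
#' dispersion `nb_dispersion`, baselines `q_i` log-normal and depth factors
#' `L_j` uniform in `lib_size_range`.
#'
#' @param config a `sim_config`.
#' @param peaks peak table for `mark`.
#' @param truth truth list holding `truth$dp` (see [draw_chip_truth()]).
#' @param mark mark name (indexes `truth$dp`).
#' @return list with `counts` (matrix) and `samples` (sample sheet).
#' @export
simulate_chip_counts <- function(config, peaks, truth, mark) {
  stopifnot(inherits(config, "sim_config"), mark %in% names(truth$dp))
  set.seed(derive_seed(config$seed, paste0("chip_", mark)))
  eff <- lapply(config$conditions, function(cn) {
    l2 <- numeric(nrow(peaks)); names(l2) <- peaks$name
    if (cn != config$conditions[1]) {
      t_dp <- truth$dp[[mark]][[cn]]
      l2[t_dp$peak_id] <- t_dp$sign * config$effect_log2fc
    }
    l2
  })
  names(eff) <- config$conditions
  nb_count_matrix(config, peaks$name, eff, assay = mark)
}

#' Derive DEG truth from H3K27ac truth and simulate RNA-seq counts
#'
#' A gene linked to a planted H3K27ac gain/loss -- through an interaction
#' record or a promoter-window peak -- becomes a true DEG with matching sign
#' with probability `couple_prob`; `frac_deg_background` of the remaining
#' genes get mark-independent shifts. Counts are NB as for ChIP.
#'
#' @param config a `sim_config`.
#' @param gene_table gene-model table.
#' @param interaction_map interaction map with `peak_id` column (from
#'   [simulate_genome()]).
#' @param truth truth list with `truth$dp$H3K27ac` and (for promoter links)
#'   `truth$placement`.
#' @return list with `counts`, `samples`, and `deg` truth
#'   (`deg[[treatment]]`: data.frame `gene_id`, `sign`, `source` in
#'   coupled/background).
#' @export
simulate_rna_counts <- function(config, gene_table, interaction_map, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (!"H3K27ac" %in% names(truth$dp))
    stop("RNA simulation requires H3K27ac ChIP truth")
  set.seed(derive_seed(config$seed, "rna"))
  placement <- truth$placement[["H3K27ac"]]
  # peak -> linked genes: interaction records + promoter placements
  link_tab <- rbind(
    if (nrow(interaction_map) > 0)
      data.frame(peak_id = interaction_map$peak_id,
                 gene_id = vapply(interaction_map$gene_ids, `[[`, "", 1L),
                 stringsAsFactors = FALSE),
    if (!is.null(placement))
      with(placement[placement$class == "promoter", ],
           data.frame(peak_id = name, gene_id = gene_id,
                      stringsAsFactors = FALSE)))
  deg <- list()
  for (tr in treatments_of(config)) {
    t_dp <- truth$dp[["H3K27ac"]][[tr]]
    hits <- merge(link_tab, t_dp, by = "peak_id")
    # per linked gene, net sign of its planted peaks (ties -> random)
    sgn <- if (nrow(hits) > 0) {
      tapply(hits$sign, hits$gene_id, function(s) {
        tot <- sum(s)
        if (tot != 0) sign(tot) else sample(c(-1, 1), 1)
      })
    } else integer(0)
    linked <- data.frame(gene_id = names(sgn) %||% character(0),
                         sign = as.integer(sgn),
                         source = rep("coupled", length(sgn)),
                         stringsAsFactors = FALSE)
    keep <- runif(nrow(linked)) < config$couple_prob
    linked <- linked[keep, , drop = FALSE]
    pool <- setdiff(gene_table$gene_id, linked$gene_id)
    n_bg <- round(config$frac_deg_background * nrow(gene_table))
    bg <- if (n_bg > 0 && length(pool) > 0) {
      ids <- sample(pool, min(n_bg, length(pool)))
      data.frame(gene_id = ids,
                 sign = sample(c(-1L, 1L), length(ids), replace = TRUE),
                 source = "background", stringsAsFactors = FALSE)
    }
    out <- rbind(linked, bg)
    deg[[tr]] <- out[order(out$gene_id), , drop = FALSE]
    rownames(deg[[tr]]) <- NULL
  }
  eff <- lapply(config$conditions, function(cn) {
    l2 <- numeric(nrow(gene_table)); names(l2) <- gene_table$gene_id
    if (cn != config$conditions[1] && nrow(deg[[cn]]) > 0)
      l2[deg[[cn]]$gene_id] <- deg[[cn]]$sign * config$effect_log2fc
    l2
  })
  names(eff) <- config$conditions
  sim <- nb_count_matrix(config, gene_table$gene_id, eff, assay = "RNA")
  c(sim, list(deg = deg))
}

#' Simulate binned H3K9me2 coverage with broad domains
#'
#' Background bins are standard normal on a log-enrichment scale; bins
#' inside a true domain are shifted by `+kdd_signal`. In each treated
#' condition, a `frac_kdd_changed` subset of domains shrinks or grows by
#' `kdd_effect` of its length (sign random, symmetric about the centre).
#'
#' @param config a `sim_config`.
#' @param truth ignored except for API symmetry; domain truth is drawn here.
#' @return list with `coverage` (named list per condition of bedGraph-like
#'   data.frames), `domains` (named list per condition of domain interval
#'   tables with `domain_id`), and `changed` (named list per treatment of
#'   changed `domain_id`s).
#' @export
simulate_kdd_coverage <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "kdd"))
  bs <- config$bin_size
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  n_bins <- floor(config$chrom_length / bs)
  bins <- do.call(rbind, lapply(chroms, function(cn)
    data.frame(chrom = cn, start = as.integer((seq_len(n_bins) - 1) * bs),
               end = as.integer(seq_len(n_bins) * bs),
               stringsAsFactors = FALSE)))
  # place non-overlapping control domains, bin-aligned
  doms <- NULL
  if (config$n_kdd > 0) {
    lens <- round(runif(config$n_kdd, config$kdd_length_range[1],
                        config$kdd_length_range[2]) / bs) * bs
    placed <- 0; tries <- 0
    rows <- list()
    occupied <- lapply(chroms, function(...) cbind(numeric(0), numeric(0)))
    names(occupied) <- chroms
    while (placed < config$n_kdd) {
      tries <- tries + 1
      if (tries > 200 * config$n_kdd)
        stop("cannot place ", config$n_kdd,
             " non-overlapping domains on this genome")
      cn <- sample(chroms, 1)
      len <- lens[placed + 1]
      max_start_bin <- n_bins - len / bs
      if (max_start_bin < 1) next
      s <- sample.int(max_start_bin, 1) * bs
      e <- s + len
      occ <- occupied[[cn]]
      # keep a one-bin gap between domains
      if (nrow(occ) > 0 && any(s < occ[, 2] + bs & e > occ[, 1] - bs)) next
      occupied[[cn]] <- rbind(occ, c(s, e))
      placed <- placed + 1
      rows[[placed]] <- data.frame(chrom = cn, start = as.integer(s),
                                   end = as.integer(e),
                                   stringsAsFactors = FALSE)
    }
    doms <- do.call(rbind, rows)
    doms <- doms[order(doms$chrom, doms$start), , drop = FALSE]
    doms$domain_id <- sprintf("kdd_%03d", seq_len(nrow(doms)))
    rownames(doms) <- NULL
  } else {
    doms <- data.frame(chrom = character(), start = integer(),
                       end = integer(), domain_id = character(),
                       stringsAsFactors = FALSE)
  }
  domains <- list(); changed <- list()
  domains[[config$conditions[1]]] <- doms
  for (tr in treatments_of(config)) {
    d <- doms
    ch <- character(0)
    if (nrow(d) > 0 && config$frac_kdd_changed > 0 && config$kdd_effect > 0) {
      n_ch <- round(config$frac_kdd_changed * nrow(d))
      idx <- sort(sample.int(nrow(d), n_ch))
      grow <- sample(c(-1, 1), n_ch, replace = TRUE)
      for (k in seq_along(idx)) {
        i <- idx[k]
        len <- d$end[i] - d$start[i]
        delta <- round(grow[k] * config$kdd_effect * len / 2 / bs) * bs
        d$start[i] <- max(0L, as.integer(d$start[i] - delta))
        d$end[i] <- min(as.integer(n_bins * bs), as.integer(d$end[i] + delta))
      }
      ch <- d$domain_id[idx]
    }
    domains[[tr]] <- d
    changed[[tr]] <- ch
  }
  coverage <- lapply(config$conditions, function(cn) {
    v <- rnorm(nrow(bins))
    d <- domains[[cn]]
    if (nrow(d) > 0) {
      hit <- IRanges::overlapsAny(as_granges0(bins), as_granges0(d),
                                  minoverlap = as.integer(bs / 2) + 1L)
      v[hit] <- v[hit] + config$kdd_signal
    }
    out <- bins
    out$value <- round(v, 6)
    out
  })
  names(coverage) <- config$conditions
  list(coverage = coverage, domains = domains, changed = changed)
}

#' Simulate a complete labelled dataset
#'
#' Orchestrates [simulate_genome()], [draw_chip_truth()],
#' [simulate_chip_counts()] per mark, [simulate_rna_counts()] and
#' [simulate_kdd_coverage()], collecting everything plus the ground truth.
#'
#' @param config a `sim_config`.
#' @return list with `genes`, `peaks`, `interactions`, `chip` (per mark:
#'   `counts`, `samples`), `rna` (`counts`, `samples`), `kdd`, and `truth`
#'   (`dp`, `deg`, `placement`, `links`, `kdd_domains`, `kdd_changed`).
#' @export
simulate_dataset <- function(config) {
  geo <- simulate_genome(config)
  truth <- draw_chip_truth(config, geo$peaks)
  truth$placement <- geo$placement
  chip <- lapply(names(geo$peaks), function(mark)
    simulate_chip_counts(config, geo$peaks[[mark]], truth, mark))
  names(chip) <- names(geo$peaks)
  rna <- simulate_rna_counts(config, geo$genes, geo$interactions, truth)
  truth$deg <- rna$deg
  kdd <- simulate_kdd_coverage(config)
  truth$kdd_domains <- kdd$domains
  truth$kdd_changed <- kdd$changed
  truth$links <- geo$interactions[, c("peak_id"), drop = FALSE]
  truth$links$gene_id <- vapply(geo$interactions$gene_ids, `[[`, "", 1L)
  list(genes = geo$genes, peaks = geo$peaks,
       interactions = geo$interactions,
       chip = chip, rna = list(counts = rna$counts, samples = rna$samples),
       kdd = kdd, truth = truth)
}

#' Write a simulated dataset as a fixture bundle
#'
#' Emits `genes.tsv`, `interactions.bedpe`, per-mark `peaks_<mark>.bed` and
#' `counts_<mark>.tsv`, `rna_counts.tsv`, `sample_sheet.tsv`,
#' `kdd_coverage_<condition>.tsv`, and machine-readable `truth.json`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_table(sim$genes, file.path(dir, "genes.tsv"))
  write_bedpe_interactions(sim$interactions, file.path(dir, "interactions.bedpe"))
  sheets <- list()
  for (mark in names(sim$peaks)) {
    write_bed(sim$peaks[[mark]], file.path(dir, sprintf("peaks_%s.bed", mark)))
    write_counts(sim$chip[[mark]]$counts,
                 file.path(dir, sprintf("counts_%s.tsv", mark)))
    sheets[[mark]] <- sim$chip[[mark]]$samples
  }
  write_counts(sim$rna$counts, file.path(dir, "rna_counts.tsv"))
  sheets[["RNA"]] <- sim$rna$samples
  write_sample_sheet(do.call(rbind, sheets), file.path(dir, "sample_sheet.tsv"))
  for (cn in names(sim$kdd$coverage))
    write_coverage(sim$kdd$coverage[[cn]],
                   file.path(dir, sprintf("kdd_coverage_%s.tsv", cn)))
  truth <- list(
    dp = lapply(sim$truth$dp, function(m) lapply(m, as.list)),
    deg = lapply(sim$truth$deg, as.list),
    placement = lapply(sim$truth$placement, as.list),
    links = as.list(sim$truth$links),
    kdd_domains = lapply(sim$truth$kdd_domains, as.list),
    kdd_changed = sim$truth$kdd_changed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}
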