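# End-to-end orchestration: simulate (optional) -> differential (all marks
# + RNA, all contrasts) -> annotate -> integrate -> KDD -> MDS -> ORA, with
# a run manifest. Stage outputs are plain files; every stage can be re-run
# independently through the exported functions with identical results.
# Data files never contain timestamps, so reruns are byte-identical.

default_thresholds <- function() {
  list(fdr_chip = 0.1, lfc_chip = 0.3, fdr_rna = 0.1, ora_fdr = 0.05,
       promoter_window = 1000)
}

default_kdd_params <- function() {
  list(z_threshold = 2.0, max_gap_bins = 2, min_domain_length = 50000,
       size_change_threshold = 0.2, flank = 1e5, n_perm = 1000)
}

#' Load a pipeline configuration
#'
#' Either a YAML path or a list. Recognised fields: `seed` (integer),
#' `outdir`, `simulate` (list of [simulation_config()] overrides; presence
#' switches on simulation), `inputs` (paths: `genes`, `interactions`,
#' `sample_sheet`, `counts` named per mark, `rna_counts`, `kdd_coverage`
#' named per condition, optional `gene_sets`), `thresholds` (`fdr_chip`,
#' `lfc_chip`, `fdr_rna`, `ora_fdr`, `promoter_window`), and `kdd`
#' (caller/test parameters). Missing thresholds take the pipeline defaults.
#'
#' @param config list or path to a YAML file.
#' @return normalized config list.
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("pipeline config: seed is mandatory")
  if (is.null(config$outdir)) stop("pipeline config: outdir is required")
  config$seed <- as.integer(config$seed)
  thr <- default_thresholds()
  thr[names(config$thresholds)] <- config$thresholds
  if (any(unlist(thr) <= 0)) stop("pipeline config: thresholds must be positive")
  config$thresholds <- thr
  kp <- default_kdd_params()
  kp[names(config$kdd)] <- config$kdd
  config$kdd <- kp
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("pipeline config: need either a simulate block or input paths")
  config
}

# pre-flight existence check before any stage runs
check_input_paths <- function(inputs) {
  paths <- c(inputs$genes, inputs$interactions, inputs$sample_sheet,
             unlist(inputs$peaks), unlist(inputs$counts), inputs$rna_counts,
             unlist(inputs$kdd_coverage), inputs$gene_sets)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("pipeline pre-flight: missing input path(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

log_stage <- function(log_path, msg) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

# collapse a list-column of gene ids for TSV output
collapse_genes <- function(x) vapply(x, paste, "", collapse = ",")

#' Run the full pipeline
#'
#' Executes simulate (when configured), differential analysis for every
#' mark and every treatment-vs-control contrast plus RNA, annotation,
#' integration (Fisher association, promoter split, activation matrix),
#' KDD analysis, MDS, and ORA, writing all outputs plus `manifest.json`
#' under the configured output directory. Identical config + seed produces
#' byte-identical non-log outputs.
#'
#' @param config pipeline config (list or YAML path), see
#'   [load_pipeline_config()].
#' @return the output directory, invisibly; the manifest is returned as
#'   attribute `manifest`.
#' @export
run_all <- function(config) {
  cfg <- load_pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  cat("", file = log_path)  # truncate
  manifest <- list(package_version = as.character(utils::packageVersion("epimark")),
                   seed = cfg$seed, stages = list())
  stage <- "preflight"
  tryCatch({
    # ---- inputs -----------------------------------------------------------
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      log_stage(log_path, "stage simulate")
      sim_args <- cfg$simulate
      sim_args$seed <- cfg$seed
      scfg <- do.call(simulation_config, sim_args)
      sim <- simulate_dataset(scfg)
      fixdir <- file.path(outdir, "fixtures")
      write_dataset(sim, fixdir)
      genes <- sim$genes
      interactions <- sim$interactions
      chip_counts <- lapply(sim$chip, `[[`, "counts")
      sheet <- rbind(do.call(rbind, lapply(sim$chip, `[[`, "samples")),
                     sim$rna$samples)
      rownames(sheet) <- NULL
      rna_counts <- sim$rna$counts
      coverage <- sim$kdd$coverage
      conditions <- scfg$conditions
      gene_sets <- synthetic_gene_sets(genes$gene_id, cfg$seed)
      write_gene_sets(gene_sets, file.path(fixdir, "gene_sets.tsv"))
      peaks <- sim$peaks
    } else {
      log_stage(log_path, "stage preflight")
      check_input_paths(cfg$inputs)
      stage <- "load"
      genes <- read_gene_table(cfg$inputs$genes)
      interactions <- read_bedpe_interactions(cfg$inputs$interactions, genes)
      sheet <- read_sample_sheet(cfg$inputs$sample_sheet)
      if (is.null(cfg$inputs$peaks))
        stop("pipeline config: inputs$peaks (named per mark) is required")
      peaks <- lapply(cfg$inputs$peaks, read_bed)
      chip_counts <- lapply(names(cfg$inputs$counts), function(mark)
        read_counts(cfg$inputs$counts[[mark]],
                    sheet[sheet$assay == mark, , drop = FALSE]))
      names(chip_counts) <- names(cfg$inputs$counts)
      rna_counts <- read_counts(cfg$inputs$rna_counts,
                                sheet[sheet$assay == "RNA", , drop = FALSE])
      coverage <- lapply(cfg$inputs$kdd_coverage, read_coverage)
      conditions <- cfg$conditions
      if (is.null(conditions)) conditions <- unique(sheet$condition)
      gene_sets <- if (!is.null(cfg$inputs$gene_sets))
        read_gene_sets(cfg$inputs$gene_sets) else NULL
    }
    control <- conditions[1]
    treatments <- conditions[-1]
    thr <- cfg$thresholds
    marks <- names(chip_counts)

    # ---- differential -----------------------------------------------------
    stage <- "diff"
    log_stage(log_path, "stage diff")
    dp <- list()
    for (mark in marks) {
      dp[[mark]] <- list()
      for (tr in treatments) {
        res <- run_differential(chip_counts[[mark]], sheet, tr, control,
                                mark, fdr_threshold = thr$fdr_chip,
                                lfc_threshold = thr$lfc_chip)
        dp[[mark]][[tr]] <- res
        write_tsv(res, file.path(outdir, sprintf("dp_%s_%s.tsv", mark, tr)))
      }
    }
    deg_res <- list()
    for (tr in treatments) {
      res <- run_differential(rna_counts, sheet, tr, control, "RNA",
                              fdr_threshold = thr$fdr_rna, lfc_threshold = 0)
      deg_res[[tr]] <- res
      write_tsv(res, file.path(outdir, sprintf("deg_%s.tsv", tr)))
    }
    deg_sets <- lapply(deg_res, function(r)
      r$feature_id[r$status != "unchanged"])
    manifest$stages$diff <- list(
      dp_tables = length(marks) * length(treatments),
      dp_rows = vapply(dp, function(m) sum(vapply(m, nrow, 0L)), 0L),
      deg_rows = vapply(deg_res, nrow, 0L))

    # ---- annotation -------------------------------------------------------
    stage <- "annotate"
    log_stage(log_path, "stage annotate")
    annot <- lapply(marks, function(mark)
      link_peaks_to_genes(peaks[[mark]], interactions, genes,
                          window = thr$promoter_window))
    names(annot) <- marks
    for (mark in marks) {
      a <- annot[[mark]]
      out <- data.frame(peak_id = a$element_id,
                        element_class = ifelse(is.na(a$element_class),
                                               "unannotated", a$element_class),
                        gene_ids = collapse_genes(a$gene_ids),
                        link_source = ifelse(is.na(a$link_source), ".",
                                             a$link_source),
                        stringsAsFactors = FALSE)
      write_tsv(out, file.path(outdir, sprintf("annotation_%s.tsv", mark)))
    }
    manifest$stages$annotate <- lapply(annot, attr, "summary")

    # ---- integration ------------------------------------------------------
    stage <- "integrate"
    log_stage(log_path, "stage integrate")
    universe <- rownames(rna_counts)[rowSums(rna_counts) > 0]
    assoc <- do.call(rbind, lapply(marks, function(mark) {
      x <- associate_dp_deg(dp[[mark]], annot[[mark]], deg_sets, universe)
      cbind(mark = mark, x)
    }))
    write_tsv(assoc, file.path(outdir, "association_stats.tsv"))
    split_rows <- list()
    for (mark in marks) for (tr in treatments) {
      res <- dp[[mark]][[tr]]
      dp_ids <- res$feature_id[res$status != "unchanged"]
      fr <- promoter_fraction(dp_ids, annot[[mark]])
      split_rows[[paste(mark, tr)]] <- data.frame(
        mark = mark, treatment = tr, n_dp = length(dp_ids),
        within_promoter = fr[["within_promoter"]],
        outside = fr[["outside"]], stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, split_rows),
              file.path(outdir, "promoter_split.tsv"))
    act <- NULL
    if ("H3K27ac" %in% marks) {
      elements <- build_regulatory_elements(annot[["H3K27ac"]])
      act <- build_activation_matrix(elements, dp[["H3K27ac"]],
                                     deg_by_treatment = deg_sets,
                                     require_deg = TRUE)
      code <- c(activated = "A", repressed = "R", ambiguous = "X",
                unchanged = ".")
      coded <- matrix(code[act$matrix], nrow = nrow(act$matrix),
                      dimnames = dimnames(act$matrix))
      mat_df <- data.frame(element_id = rownames(act$matrix),
                           element_class = act$elements$element_class,
                           coded, check.names = FALSE,
                           stringsAsFactors = FALSE)
      write_tsv(mat_df, file.path(outdir, "activation_matrix.tsv"))
      write_tsv(data.frame(element_id = act$elements$element_id,
                           gene_ids = collapse_genes(act$elements$gene_ids),
                           stringsAsFactors = FALSE),
                file.path(outdir, "linked_genes.tsv"))
    }
    manifest$stages$integrate <- list(
      association_rows = nrow(assoc),
      activation = if (!is.null(act)) as.list(act$summary) else NULL)

    # ---- kdd --------------------------------------------------------------
    stage <- "kdd"
    log_stage(log_path, "stage kdd")
    kp <- cfg$kdd
    bin_size <- if (!is.null(cfg$simulate)) scfg$bin_size else
      with(coverage[[1]], end[1] - start[1])
    domains <- lapply(coverage, function(cv)
      call_kdd(cv, bin_size, z_threshold = kp$z_threshold,
               max_gap_bins = kp$max_gap_bins,
               min_domain_length = kp$min_domain_length))
    for (cn in names(domains)) {
      d <- domains[[cn]]
      write_bed(data.frame(chrom = d$chrom, start = d$start, end = d$end,
                           name = sprintf("kdd_%03d", seq_len(nrow(d))),
                           score = format(round(d$mean_enrichment, 4),
                                          trim = TRUE),
                           strand = ".", stringsAsFactors = FALSE),
                file.path(outdir, sprintf("domains_%s.bed", cn)))
    }
    prox <- list()
    change_rows <- list()
    for (tr in treatments) {
      cmpd <- compare_domains(domains[[control]], domains[[tr]],
                              size_change_threshold = kp$size_change_threshold)
      change_rows[[tr]] <- cbind(treatment = tr, cmpd$changes)
      changed <- cmpd$changes[cmpd$changes$changed &
                                !is.na(cmpd$changes$control_start), ,
                              drop = FALSE]
      changed_iv <- data.frame(chrom = changed$control_chrom,
                               start = changed$control_start,
                               end = changed$control_end,
                               stringsAsFactors = FALSE)
      pt <- deg_proximity_test(changed_iv, deg_sets[[tr]], genes,
                               flank = kp$flank, n_perm = kp$n_perm,
                               seed = derive_seed(cfg$seed,
                                                  paste0("kdd_perm_", tr)))
      prox[[tr]] <- pt
    }
    write_tsv(do.call(rbind, change_rows),
              file.path(outdir, "domain_changes.tsv"))
    jsonlite::write_json(prox, file.path(outdir, "deg_proximity.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages$kdd <- list(domains = vapply(domains, nrow, 0L))

    # ---- mds --------------------------------------------------------------
    stage <- "mds"
    log_stage(log_path, "stage mds")
    for (mark in marks) {
      co <- classical_mds(sample_distances(chip_counts[[mark]]), k = 2)
      write_tsv(data.frame(sample_id = rownames(co), co,
                           stringsAsFactors = FALSE),
                file.path(outdir, sprintf("mds_%s.tsv", mark)))
    }
    co <- classical_mds(sample_distances(rna_counts), k = 2)
    write_tsv(data.frame(sample_id = rownames(co), co,
                         stringsAsFactors = FALSE),
              file.path(outdir, "mds_RNA.tsv"))

    # ---- ora --------------------------------------------------------------
    stage <- "ora"
    log_stage(log_path, "stage ora")
    if (!is.null(gene_sets)) {
      for (tr in treatments) {
        q <- intersect(deg_sets[[tr]], universe)
        if (length(q) == 0) next
        res <- overrepresentation(q, gene_sets, universe,
                                  fdr_threshold = thr$ora_fdr)
        write_tsv(res, file.path(outdir, sprintf("ora_%s.tsv", tr)))
      }
    }

    # ---- manifest ---------------------------------------------------------
    stage <- "manifest"
    cfg_for_hash <- cfg
    cfg_for_hash$outdir <- NULL  # hash the analysis config, not its location
    tmp <- tempfile()
    writeLines(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE,
                                digits = NA, force = TRUE), tmp)
    manifest$config_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage(log_path, "done")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  out <- outdir
  attr(out, "manifest") <- manifest
  invisible(out)
}

# deterministic generic gene sets for synthetic runs: a partition of the
# gene universe into sets of ~100
synthetic_gene_sets <- function(gene_ids, seed, set_size = 100) {
  set.seed(derive_seed(seed, "gene_sets"))
  ids <- sample(gene_ids)
  n_sets <- max(1, floor(length(ids) / set_size))
  grp <- rep(seq_len(n_sets), length.out = length(ids))
  sets <- split(ids, grp)
  names(sets) <- sprintf("set_%03d", seq_len(n_sets))
  attr(sets, "descriptions") <- sprintf("synthetic gene set %d",
                                        seq_len(n_sets))
  sets
}

#' Write a gene-set collection as GMT-like TSV
#' @param sets named list of character vectors (see [read_gene_sets()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- names(sets)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), ""),
    con, sep = "\n")
  invisible(path)
}
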