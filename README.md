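# epimark

Integrative, count-level analysis of histone-mark ChIP-seq and RNA-seq for
multi-arm exposure studies — the setting where several treatments are
compared against one untreated control and the question is whether
transcriptional changes can be attributed to the redistribution of histone
modifications at promoters and enhancers.

The package is written for computational epigenomics analysts. It takes
count-level inputs only (peak atlases in BED, per-peak and per-gene count
matrices in TSV, a TSS table, a promoter–distal interaction map in
BEDPE+gene format from promoter-capture Hi-C, and binned H3K9me2 coverage)
and provides:

* **Differential analysis** — TMM normalization, method-of-moments
  dispersion with shrinkage, and an NB Wald test with a Satterthwaite t
  reference; BH FDR per mark × contrast. Differential peaks (DPs) are
  regions with FDR < 0.1 and |log2FC| > 0.3; differentially expressed
  genes (DEGs) use FDR < 0.1.
* **Annotation** — peaks classified as *promoter* (overlapping
  `[TSS − 1000, TSS + 1001)`) or *enhancer* (overlapping a distal
  interaction anchor), with promoter precedence; nearest-k-genes for
  ORA-style annotation.
* **Integration** — Fisher's exact test (log-space enumeration of the
  two-sided tail) of DP-linked genes vs DEGs over the expressed-gene
  universe; the promoter/outside split of DPs; and an activation-status
  matrix of regulatory elements where an H3K27ac gain means activation and
  a loss means repression.
* **KDD analysis** — broad H3K9me2 heterochromatic domains called from
  binned coverage by per-chromosome z-score with gap merging and a
  minimum length, greedy 1:1 size comparison between conditions, and a
  label-permutation test of DEG proximity to changed domains.
* **Similarity & ORA** — Spearman-distance MDS of samples and a
  hypergeometric over-representation test against user-supplied gene-set
  collections.
* **A synthetic-data generator** — a seed-deterministic emulation of the
  full study design (4 treatments + control, replicated NB counts, planted
  mark shifts coupled to expression through the interaction map, broad
  K9 domains) with machine-readable ground truth, so every stage is
  testable without any external download.

The statistical core in one line per stage: counts are modelled
NB(μ, α) with variance μ + αμ²; the Wald statistic contrasts log group
abundances at the shrunk dispersion; BH controls FDR at 0.1; association
is the two-sided Fisher exact p for the 2×2 table (DP-linked × DEG);
activation is the sign pattern of H3K27ac DPs on an element; domain and
proximity inference is nonparametric (z-score runs; permutation p).

## Worked example

Simulate a study-shaped dataset and ask whether H3K27ac redistribution
under one treatment is coupled to expression:

```r
library(epimark)

cfg <- simulation_config(seed = 7)        # 4 treatments + control, 4 marks
sim <- simulate_dataset(cfg)

res <- run_differential(sim$chip$H3K27ac$counts, sim$chip$H3K27ac$samples,
                        "Fe2O3Co", "control", "H3K27ac")
table(res$status)
#>    gained      lost unchanged
#>        22        33      1945
```

55 differential peaks at the FDR < 0.1, |log2FC| > 0.3 gate (the generator
planted 100, at effect 1.5 with two replicates roughly half are
detectable). Annotate the atlas and integrate with expression:

```r
ann <- link_peaks_to_genes(sim$peaks$H3K27ac, sim$interactions, sim$genes)
attr(ann, "summary")
#>    promoter    enhancer unannotated
#>         600         721         679

rna <- run_differential(sim$rna$counts, sim$rna$samples,
                        "Fe2O3Co", "control", "RNA", lfc_threshold = 0)
deg <- rna$feature_id[rna$status != "unchanged"]
uni <- rownames(sim$rna$counts)[rowSums(sim$rna$counts) > 0]

associate_dp_deg(list(Fe2O3Co = res), ann, list(Fe2O3Co = deg), uni)
#>   treatment  a  b  c    d odds_ratio p_value
#> 1   Fe2O3Co 17 21 50 1912         31 1.7e-16

promoter_fraction(res$feature_id[res$status != "unchanged"], ann)
#> within_promoter         outside
#>           0.273           0.727
```

Reading the numbers: of the genes linked to a detected H3K27ac DP, 17 are
also DEGs against 21 that are not — a 31-fold enrichment over the 2,000-gene
universe (Fisher p ≈ 2×10⁻¹⁶), i.e. mark redistribution and transcriptional
modulation are strongly associated, as the generator's coupling dictates.
73% of the DPs fall outside promoter windows, recovering the generator's
70/30 distal/promoter placement.

The whole pipeline — differential analysis for every mark and contrast,
annotation, integration, KDD analysis, MDS, ORA, and a run manifest — is
one call:

```r
run_all(list(seed = 7, outdir = "run1", simulate = list()))
```

or, from a shell, via the thin dispatcher
`Rscript inst/cli/epimark.R run-all --config pipeline.yaml` (subcommands
`simulate`, `diff`, `annotate`, `integrate`, `kdd`, `mds`, `ora`,
`run-all`). Reruns with the same config and seed are byte-identical.

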