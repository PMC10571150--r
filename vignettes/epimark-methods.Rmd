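---
title: "Methods: integrating histone-mark redistribution with transcription"
author: "epimark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating histone-mark redistribution with transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimark)
```

# Scope and model

epimark analyses count-level ChIP-seq and RNA-seq data from a multi-arm
exposure design: several treatments against one untreated control, with
replicated libraries for each of four histone marks (H3K27ac, H3K4me1,
H3K9me2, H3K27me3) and for expression. The pipeline answers three linked
questions:

1. *Which genomic regions gain or lose a histone mark, and which genes
   change expression?* (differential analysis)
2. *Are the two coupled?* Differential peaks (DPs) are assigned to genes
   through promoter windows and promoter-capture Hi-C (PCHi-C) style
   interaction records, and the DP-linked gene set is cross-tabulated
   against the differentially expressed gene (DEG) set with Fisher's exact
   test. H3K27ac gains on a regulatory element are read as activation,
   losses as repression.
3. *Do broad repressive H3K9me2 domains (KDDs) change, and do DEGs
   cluster around the changed ones?* (domain calling, size comparison,
   and a label-permutation proximity test)

All coordinates are 0-based half-open internally; conversion happens only
at file boundaries. Promoters are operationally regions within 1000 bp of
an annotated TSS, i.e. the window `[tss - w, tss + w + 1)` with `w = 1000`
by default; the overlap test is region-based (any overlap with the window
counts), the conservative reading of "within 1000 bp of a TSS". A peak
overlapping both a promoter window and a distal interaction anchor is
classified as a promoter: the promoter/enhancer split is a binary
partition and promoter evidence takes precedence. Distal anchors are
matched by overlap with zero slack (configurable via `anchor_slack`).

# The differential engine

## Normalization and abundance

Library composition is corrected by TMM (trimmed mean of M-values):
log-ratios against a reference sample — the one whose upper count quartile
is closest to the mean upper quartile — are trimmed at 30% (log-ratio) and
5% (intensity) and averaged with precision weights; factors are rescaled
to geometric mean 1 (computed by edgeR). Per-feature abundance in each
group is the mean of counts divided by relative effective library sizes.

## Dispersion

Counts are modelled as negative binomial with a per-feature dispersion
$\alpha$ (variance $\mu + \alpha\mu^2$). The raw estimate is
method-of-moments from the within-group residual variance $v$ and the
pooled mean $m$:

$$\hat\alpha_{raw} = \frac{v - m}{m^2 - v/n}.$$

The denominator correction ($m^2 - v/n$ rather than $m^2$) matters: the
naive denominator is inflated by the sampling error of $m$, which biases
the dispersion down by roughly $15\%$ at $n = 3$ per group and, through
the Wald denominator, inflates the far tail of the test statistic several
fold. Raw values are floored at $10^{-4}$ and shrunk toward the 5%
trimmed mean $\bar\alpha$ across features with weight
$w = n_{prior}/(n_{prior} + df)$, $n_{prior} = 10$, $df$ the residual
degrees of freedom. At 3 vs 3 this places ~71% of the weight on the
common value — appropriate for the replicate numbers this design has.

## The Wald test and its reference distribution

For a contrast the statistic is

$$z = \frac{\log(\hat q_T + c) - \log(\hat q_C + c)}
          {\sqrt{\widehat{Var}_T + \widehat{Var}_C}},$$

with prior count $c = 0.5$ and delta-method variances evaluated at the
group abundances under the NB model with the shrunk dispersion. Because
the dispersion is estimated, referring $z$ to the normal is
anti-conservative: at 3 vs 3 replicates the measured tail probability at
$p = 5\times10^{-5}$ was ~3x nominal, enough to produce a spurious BH
discovery in half of null datasets of 2,000 features. The engine
therefore uses a per-feature Satterthwaite t reference: the shrunk
dispersion carries effective degrees of freedom
$d_\alpha = df/(1-w)^2$, and the dispersion term contributes a fraction
$\rho$ of the Wald variance, giving

$$p = 2\,P\!\left(T_{d} > |z|\right), \qquad d = d_\alpha / \rho^2.$$

For abundant features ($\rho \to 1$, $d \approx 50$ at 3 vs 3) this is a
mild correction; for low counts ($\rho$ small) the reference approaches
the normal, as it should since there the Poisson part of the variance
dominates and is not estimated. Verified on 400k directly simulated null
features, the tail is calibrated to within Monte-Carlo error across
$10^{-5} \le p \le 0.1$. Dispersions supplied as a bare numeric vector
are treated as known and referred to the normal.

Features with zero counts across both groups are dropped before testing.
`log2fc` is the log2 ratio of prior-augmented group means, so fold-changes
of all-zero-vs-something features stay bounded.

## Multiple testing and status calls

BH adjustment is applied within one mark x contrast table, never pooled
across marks. Peak calls use both gates (FDR < 0.1 and |log2FC| > 0.3);
expression calls use FDR < 0.1 only. Both thresholds are arguments
everywhere they appear.

# Integration

The gene universe for the Fisher cross-tabulation is every gene present
in the expression matrix after the all-zero filter; DP-linked genes come
exclusively from promoter windows and interaction records (never
nearest-gene, which is reserved for the ORA annotation path). The
two-sided Fisher p-value enumerates all tables with the observed margins
in log space and sums the hypergeometric probabilities not exceeding the
observed one (relative tolerance $10^{-7}$), the same rule as
`stats::fisher.test`, which the test suite uses as an independent
cross-check together with a brute-force enumeration oracle.

Regulatory elements are unions of annotated peaks that overlap and share
a linked gene. Per element and treatment, the activation status is
`activated` if the element carries at least one gained H3K27ac DP and no
lost one, `repressed` in the converse case, `ambiguous` when both occur
(a state the two-colour reporting convention cannot show but the data
model must represent), and `unchanged` otherwise. The reported matrix
keeps elements regulated in at least one treatment and, by default, only
elements linked to at least one DEG (`require_deg = TRUE`), since the
activation table ties regulatory elements to transcriptional modulation.
Truth-recovery checks use `regulated_only = FALSE` and
`require_deg = FALSE`: the property being validated is the status logic
itself, so the comparison must include elements the caller might have
missed, not only those it flagged.

# KDD analysis

Domains are called per chromosome from binned coverage: bins with
enrichment z-score (against the chromosome median/MAD) at or above
`z_threshold` are marked, marked runs are merged across gaps of at most
`max_gap_bins` bins, and runs shorter than `min_domain_length` (50 kb)
are discarded. The default `z_threshold` is 2.0: at 1 SD roughly one
background bin in six is marked and gap merging chains them into spurious
50 kb domains (~30 per 100 Mb of pure noise, measured), while at 2 SD
false domains essentially vanish and planted 100 kb blocks at +3 SD are
recovered with base-pair Jaccard 0.87-0.99. The caller is invariant to
constant shifts of the track by construction.

Between conditions, domains are matched greedily 1:1 by descending
overlap; matched pairs get `log2(len_T/len_C)` and are flagged changed
beyond `size_change_threshold` (0.2); unmatched control domains are
changed with a `-Inf` sentinel, new treatment domains with `+Inf`.

The DEG proximity test counts DEG TSSs within changed domains extended by
`flank` (100 kb) and compares against `n_perm` random reassignments of
the DEG labels over all genes (without replacement), with
$p = (1 + \#\{null \ge obs\})/(n_{perm} + 1)$. Label permutation (rather
than domain shuffling) preserves the gene-density structure of the
genome. The permutation seed is mandatory. The p-value is discrete and
slightly super-uniform (the +1 correction); validating its null
uniformity with a KS test therefore requires an ensemble in which the
observed statistic has wide support — the validation suite uses 150 DEGs
of 1,000 genes with domain coverage varying across datasets, where the
Binomial-mixture statistic spreads over enough values for the KS test to
be meaningful.

# Similarity and over-representation

Sample distances are `1 - Spearman` on log2-CPM (prior 0.5) over the 500
most variable features; rank correlation makes the metric invariant to
depth and to any monotone distortion of signal. Classical (Torgerson)
MDS embeds the distances; negative eigenvalues are clipped and each
axis's sign is fixed so its largest-magnitude loading is positive, making
plots reproducible. Two-dimensional embeddings are used for figures; the
replicate-clustering validation embeds in k = 3 because five condition
centroids are nearly a simplex in similarity space and a 2-D projection
necessarily crowds them (measured: replicates are mutual nearest
neighbours in 83% of seeds at k = 2 and 100% at k = 3).

ORA is a one-sided hypergeometric upper tail per gene set (sets
intersected with the universe first) with BH across sets at FDR < 0.05.
Gene sets are user-supplied GMT-like files; no external ontology database
is consulted, so enrichment labels are only as meaningful as the supplied
collections.

# The synthetic-data generator

The generator emulates the statistical structure the inference assumes,
with machine-readable ground truth:

* genome: genes placed uniformly on a 5 kb grid; per mark, 30% of peaks
  centred in promoter windows and 70% distal (at least `window + 1500` bp
  from every TSS); 50% of distal peaks entered into the interaction map;
* counts: NB with common dispersion 0.1, log-normal baselines
  (median 200, log-sd 1), uniform depth factors in [0.8, 1.2]; planted
  symmetric $\pm$ log2FC shifts of 1.5 in 5% of peaks per treatment x
  mark; control samples never carry effects;
* coupling: genes linked to a planted H3K27ac gain/loss become true DEGs
  with matching sign with probability 0.8 by default, plus 2% background
  DEGs — one shared gene universe serves ChIP linkage and RNA counts;
* KDDs: a dozen non-overlapping 80-200 kb domains at +3 SD over N(0,1)
  background in 5 kb bins; half of them shrink or grow by 30% of their
  length per treatment.

The default design is "study-shaped": 4 treatments + control, 2
replicates, 4 marks x 2,000 peaks, 2,000 genes. These sizes generate in
a few seconds and give every downstream stage measurable signal. The
recovery analyses use the published defaults except where the property
under test dictates the condition: null analyses set `frac_dp = 0`;
effect-recovery uses 3 replicates (the minimum where within-group
variance is estimable with a usable residual df) and the default effect
1.5; the integration-recovery fixture uses `couple_prob = 1` with effect
3 ("strong effects"), so that status recovery measures the integration
logic rather than the detection floor of the differential engine.

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify on real data: read-level artifacts (GC, mappability,
fragment-length effects), peak-calling uncertainty, spike-in or global
occupancy shifts (TMM assumes most features unchanged), correlated
dispersions, batch effects, and interaction maps with cell-type mismatch.
The generator's truth labels are exact by construction, which real
datasets never offer.

# Numerical and degenerate-input choices

* Fisher enumeration in log space; ties in the null set compared with
  relative tolerance $10^{-7}$.
* Odds ratio `ad/bc` reported as `Inf` when `bc = 0` and `ad > 0`, `NaN`
  when both products vanish.
* `promoter_fraction` of an empty DP set is `NA` (undefined), never 0.
* Peaks with no promoter overlap and no anchor overlap stay unannotated
  and count toward the "outside promoters" side of the split.
* MAD of a constant track is zero: no domains are called on flat input.
* All-zero count rows are dropped before testing; constant-within-group
  features fall to the dispersion floor of $10^{-4}$.
* Every stochastic step derives its seed from one base seed and a stage
  tag, so stages are individually re-runnable and whole runs are
  byte-identical under a fixed configuration (logs carry timestamps,
  data files never do).

# Problem sizes used in validation

The packaged validation suite uses 2,000-feature matrices at 3 vs 3 for
calibration and recovery (20 null seeds, 3 effect seeds), a 2,000-peak /
2,000-gene coupled dataset for integration recovery, 200 null datasets at
`n_perm = 200` for permutation validity, 20 seeds for replicate
clustering, and two full study-shaped pipeline runs for determinism.
These sizes were chosen so the full suite completes in a few minutes on a
single core while keeping Monte-Carlo error well below the decision
margins.

# Known limitations

* The NB Wald engine is a deliberate, documented stand-in: the upstream
  study reports FDR/log2FC semantics without naming its tool, and exact
  conditional tests or quasi-likelihood F-tests would be natural
  alternatives at larger replicate numbers.
* Interaction records are taken at face value; no weighting by contact
  frequency or distance decay.
* The KDD caller is a thresholding heuristic, not an HMM; its parameters
  are exposed rather than claimed to match any published domain caller.
* ORA ignores gene-set overlap structure and annotation bias.
* With two replicates per condition the dispersion shrinkage is nearly
  total, so per-feature dispersion differences are invisible at the
  study-shaped design; three or more replicates are needed for the
  per-feature component to matter.
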