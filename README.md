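# clonemapr

Maps single-cell RNA-seq expression profiles onto clonal phylogenies of
copy-number alterations called from bulk exome-seq. Intended for groups
studying intratumoural heterogeneity (e.g. in gliomas) who have bulk CNV
segment calls and single-cell expression from the same biopsy and want
to know *which cells carry which CNVs*, *in what order the CNVs were
acquired*, and *how expression changes along that clonal progression* —
without single-cell DNA sequencing.

## What it computes

**Per-cell CNV genotyping.** A large CNV shifts the sum of
library-size-normalized read counts over its member genes. For each CNV
candidate region and cell, `clonemapr` sums CPM over in-region genes and
compares the sum with its distribution over CNV-free control cells: a
one-tailed add-one empirical p-value in the CNV's direction,

p = (r + 1) / (n + 1),  r = #{controls at least as extreme},

with Benjamini–Hochberg correction over all cell × region tests and
calls at adjusted q < 0.05. The classifier's false-call rate is
estimated by 10-fold cross-validation on the controls alone.

**Clone phylogenies.** Cells with identical call sets form genotype
classes; pairwise Jaccard distances between class genotypes,
d(A,B) = 1 − |A∩B|/|A∪B|, feed a Fitch–Margoliash least-squares fit

min over topologies, b ≥ 0 of Σ_{i<j} (d_ij − p_ij)² / d_ij²,

with branch lengths solved exactly per topology by non-negative least
squares, exhaustive topology search up to 8 leaves (stepwise addition +
NNI beyond), and rooting on a CNV-free "normal" out-group.

**Clonal pseudotime.** A backbone path through the tree follows the most
frequent mutation at each level; classes along it are binned
early/mid/late, and genes with strictly ordered bin means are flagged as
monotone. Dose–response analysis ranks genes by Spearman correlation
with a focal transcript; subtype classifiers (centroid regression and
two-module averaging) and per-clone raw-count export round out the
expression side.

**Exon-depletion testing.** For a receptor gene across an exome cohort,
each sample's fraction of reads on target exons is tested lower-tailed
against blood controls (BH at adjusted p < 0.25, plus a 10th-percentile
fixed-threshold variant) to detect intragenic in-frame deletions.

**Synthetic data.** A negative-binomial clone-tree simulator
(`sim_config()`, `simulate_cells()`, `simulate_controls()`,
`simulate_exon_coverage()`) generates the full set of inputs with known
ground truth, so the entire pipeline is testable end to end.

## Worked example

```r
library(clonemapr)

# simulate a four-clone tumour: 2,000 genes, 4 CNV regions of 300 genes
cfg <- sim_config(n_genes = 2000, n_regions = 4, genes_per_region = 300,
                  cells_per_clone = 30, n_control_cells = 100, seed = 7)
truth <- simulate_truth(cfg)
tumor <- simulate_cells(truth)
controls <- simulate_controls(cfg)

regions <- data.frame(
  region_id = names(truth$region_gene_map),
  direction = truth$region_directions,
  genes = vapply(truth$region_gene_map,
                 function(i) paste(sprintf("gene_%04d", i), collapse = ","),
                 character(1)))

# genotype every cell against the control distribution
ref <- build_control_reference(
  score_regions(cpm_normalize(controls), regions))
gt <- call_genotypes(
  empirical_pvalues(score_regions(cpm_normalize(tumor), regions), ref))
gt
#> genotype_matrix: 120 cells x 4 regions, 315 calls (alpha = 0.05)
mean(gt$calls == truth$genotypes)
#> [1] 0.9604167

# collapse to genotype classes and fit the rooted phylogeny
cl <- collapse_genotypes(gt)
head(cl$classes, 4)
#>   class_id n_cells                                genotype
#> 1      gc1      34 region_01+region_02+region_03+region_04
#> 2      gc2      31                     region_01+region_02
#> 3      gc3      27           region_01+region_02+region_03
#> 4      gc4      22                               region_01
fm <- fitch_margoliash_fit(cl$dist)
backbone_path(fm, cl)
#>     position class_id n_cells n_regions  acquired   bin
#> gc4        1      gc4      22         1 region_01 early
#> gc2        2      gc2      31         2 region_02 early
#> gc3        3      gc3      27         3 region_03   mid
#> gc1        4      gc1      34         4 region_04  late

# cross-validated false-call rate on the CNV-free controls
crossval_fdr(controls, regions, folds = 10, seed = 7)$max_fold
#> [1] 0
```

The genotyper recovers 96% of the true per-cell region states; the four
major genotype classes reproduce the simulated acquisition chain
(region_01 → 02 → 03 → 04, 22/31/27/34 cells), the backbone orders them
correctly into early/mid/late bins, and held-out control cells generate
no false CNV calls.

`to_newick(fm, classes = cl)` serializes the rooted tree with member
counts in the leaf labels; `wavelet_smooth_track()` produces the
chromosome-ordered smoothed ratio matrix behind CNV heatmaps;
`depletion_test()` / `cooccurrence_report()` cover the exon-level
deletion analysis. A thin CLI over these functions ships in
`inst/cli/clonemapr.R` (subcommands `simulate`, `qc`, `triage`,
`genotype`, `tree`, `exon-del`).

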