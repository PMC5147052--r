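---
title: "Mapping single-cell expression onto clonal copy-number phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping single-cell expression onto clonal copy-number phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemapr)
```

## The problem

Bulk exome sequencing of a tumour biopsy yields a set of large somatic
copy-number alterations (CNVs), but not their distribution over the
tumour's subclones. Single-cell RNA-seq of the same biopsy carries that
information indirectly: a copy-number change shifts expression when read
counts are averaged over the hundreds of adjacent genes a large CNV
spans, even though any single gene is far too noisy. `clonemapr`
exploits this to (i) genotype each cell for each bulk-called CNV,
(ii) build a rooted phylogeny of the resulting cellular genotypes,
(iii) analyse expression along the phylogeny's main line of clonal
progression, and (iv) test cohort-scale exome data for focal exon
depletion caused by intragenic in-frame deletions.

## Per-cell CNV genotyping

For a CNV candidate region the per-cell statistic is the sum of CPM
(counts-per-million) over the region's genes. Its null distribution is
taken from a CNV-free control population (e.g. non-malignant brain
cells) scored identically. Each tumour cell receives a one-tailed
empirical p-value in the direction of the candidate — upper tail for
gains, lower tail for losses — with the add-one convention
$p = (r + 1)/(n + 1)$, where $r$ counts controls at least as extreme,
so no p-value is exactly zero and ties count as extreme
(conservative). Benjamini–Hochberg correction is applied jointly over
all cell-by-region tests, and a region is called present at adjusted
$q < \alpha$ with $\alpha = 0.05$, the same 5% level as the empirical
threshold.

Two reading notes on the thresholding. First, the 5% significance level
is taken on the side consistent with the CNV's direction; a literal
fifth percentile cannot separate gain carriers from controls, so the
direction-consistent reading is the only workable one. Second, the test
family for BH is all cell-by-region tests jointly; the per-fold family
is used inside cross-validation, where each fold is an independent
calling run. `alpha >= 1` is treated as the degenerate everything-called
setting (useful only for sanity checks).

The classifier's error rate is estimated by 10-fold cross-validation on
the control cells alone: the reference is rebuilt from each 90%
training tranche and calls are made on the held-out 10%; every held-out
test is null, so (positive calls)/(total tests) per fold estimates the
false-call rate directly. On the synthetic study conditions used in the
test suite (200 control cells, 10 regions of 300 genes, default noise)
every fold's rate is below 0.01 — in fact the add-one floor
$1/181 \approx 0.0055$ exceeds the BH rank-one threshold
$0.05/200$, so a single extreme score can never be called and the
realized rate is zero.

`wavelet_smooth_track()` produces the visual counterpart of the calls:
per-gene log2 ratios of cell CPM to median control CPM (pseudo-count 1
CPM), denoised along genomic order within each chromosome by a
single-level Haar transform with soft thresholding (universal threshold
$\hat\sigma\sqrt{2\log n}$, $\hat\sigma$ the MAD of the detail
coefficients), then z-scored per cell. The basis and depth are a
deliberate minimal choice: the triage itself never depends on the
smoothing, and the test suite checks that thresholding the smoothed and
unsmoothed tracks classifies cells identically on strong-effect data.

## Phylogenies of cellular genotypes

Cells with identical call sets collapse into genotype classes — the
tree leaves — plus a CNV-free "normal" out-group. Pairwise dissimilarity
is the Jaccard distance, $1 - |A \cap B| / |A \cup B|$: shared calls as
a fraction of all distinct calls. Trees are fitted by the
Fitch–Margoliash criterion

$$\min_{T,\,b \ge 0} \sum_{i<j} \frac{(d_{ij} - p_{ij}(T, b))^2}{d_{ij}^2},$$

with $p_{ij}$ the leaf-to-leaf path length. Given a topology the branch
lengths are solved exactly by non-negative least squares on the
path-membership design matrix, so the objective per topology is not
itself approximated. Up to 8 leaves every unrooted binary topology is
enumerated ($(2n-5)!!$ of them); beyond that, greedy stepwise addition
in label order is refined by nearest-neighbour interchange until no
move improves the objective (which therefore never increases during
refinement). Zero distances between distinct labels are allowed; their
$1/d^2$ weights are capped at the smallest positive distance's weight.
Ties between equally optimal topologies resolve to the first in the
deterministic enumeration order. The tree is rooted on the branch to
the out-group, and newick export (via `ape`) quotes labels containing
reserved characters.

Cells lacking the founding CNV are retained: they simply form classes
near the root rather than being filtered, since no principled exclusion
rule exists at calling time.

## Clonal pseudotime and expression kinetics

The backbone path follows the most frequent mutation at each level:
starting from the CNV-free root, the walk repeatedly steps to an unused
class whose genotype minimally extends everything acquired so far,
choosing the step whose newly acquired region is carried by the most
cells (ties: larger class, then lexicographic id). Restricting steps to
*minimal* supersets matters — without it a deep genotype sharing the
most frequent founding region would swallow the whole path in one step.
Path positions are binned into early/mid/late terciles (ties favour
earlier bins; `floor(3(i-1)/k) + 1`). A gene is monotone when its bin
means are *strictly* ordered in the requested direction; under the null
a strict three-bin ordering occurs with probability 1/6, which the test
suite verifies on unlinked genes.

One structural consequence of binary presence/absence dosage is worth
stating: a region acquired exactly at a bin boundary has a tied
expected mean across two bins (carrier fraction 0 or 1 in both), so
only regions acquired strictly inside the middle tercile have strictly
increasing expected expression across all three bins (carrier fraction
0 → partial → 1). The recovery test therefore simulates a six-clone
linear chain and measures recall on the genes of the mid-tercile
acquisition, which is the configuration in which strict monotonicity is
the correct expectation.

Dose–response ranking computes each gene's Spearman correlation with a
focal transcript's per-cell expression and reports the top and bottom
5% tails separately (the positively and negatively responding sets are
analysed separately downstream, so the tails are not pooled on
$|\rho|$). Genes are prefiltered by the expression rule: drop a gene
when more than 80% of cells sit below 1 CPM.

Subtype classification ships two classifiers with user-supplied
signature files (no third-party gene lists are redistributed; tests use
synthetic centroids). The centroid-regression classifier regresses the
cell's standardized log2(CPM+1) profile over the signature genes on the
standardized centroid columns without intercept — standardization makes
an intercept vanish — and assigns the subtype with the largest
coefficient magnitude. Standardization is per vector over the signature
genes; the transform is `log2(x + 1)`, base and pseudo-count being a
package choice. The two-module classifier averages log2(CPM+1) over two
gene modules and labels a cell only when one module's average strictly
exceeds twice the other, else "ambiguous".

## Exon-depletion testing

For one gene of interest, each sample's statistic is the fraction of
the gene's reads falling on the target exons. Blood controls give the
null distribution; tumours get lower-tail add-one empirical p-values,
BH correction across tumours, and significance at adjusted $p < 0.25$
(the conventional CNV threshold in large-cohort work). The
fixed-threshold variant — fraction below the controls' 10th
percentile — is reported alongside, because the two estimators bracket
the answer differently: a call set controlled at FDR 0.25 contains up
to ~25% false calls by construction, and the fixed threshold admits
~10% of nulls, so both *over*-estimate prevalence on a mixed cohort.
The test suite measures exactly this: sensitivity is complete at strong
suppression and the false-discovery proportion respects the BH budget,
while the raw prevalence estimate carries the estimator's structural
upward bias.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions for every statistical claim above. It emulates:

- a clone tree (default: a linear chain) whose clones cumulatively
  acquire disjoint CNV regions of `genes_per_region` contiguous genes
  (default 300, the scale of large CNVs spanning hundreds of genes);
- expression dosage linear in copy number: mean multiplied by 1.5 per
  single-copy gain and 0.5 per single-copy loss. No generative model is
  prescribed by the biology beyond "dosage shifts regional expression";
  linearity in copy number is the simplest law consistent with it;
- negative-binomial counts with shared dispersion (size 2) around
  `base_mean` 0.5 counts/gene/cell, log-normal library-size factors
  (sd 0.2 on the log scale) — a standard count model for scRNA-seq at
  modest depth;
- a CNV-free control population under the identical law; and
- per-exon coverage profiles with a configurable fraction of tumours
  whose target-exon means are suppressed by a configurable factor
  (default 0.02; partial suppression models heterozygous or subclonal
  deletions).

Default region directions alternate gain/loss so that the affected gene
mass roughly balances and CPM normalization does not convert regional
dosage into a global composition artefact; this mirrors real tumours
carrying both gains and losses. It deliberately does *not* emulate
doublets, ambient RNA, gene-length effects, transcriptional bursting
beyond NB dispersion, overlapping CNVs, or subclonal copy-number states
above one gain — so green tests demonstrate correctness of the
machinery under the stated law, not robustness to every real-data
artefact.

All generators are deterministic given `seed` (controls draw from a
stream derived from `seed + 1` so tumour and control noise are
independent).

## Numerical and scale choices

- Empirical p-values use add-one ranks; ties count as extreme.
- BH is `stats::p.adjust(method = "BH")`, cross-checked in tests
  against a brute-force step-up oracle on enumerated inputs.
- NNLS is `pracma::lsqnonneg` (Lawson–Hanson, exact active set), which
  drives Fitch–Margoliash residuals on additive inputs to ~1e-30.
- Degenerate inputs: all-zero distance matrices yield a star-like tree
  with a warning; zero-library cells are flagged and excluded from QC
  metrics; regions resolving to zero genes are flagged and excluded
  from calling.
- Test-suite problem sizes are desk-scale by design: 200-cell control
  populations for calibration, 200–1,500 tumour cells for recovery,
  5–6-leaf trees (20 replicates) for the exhaustive-search oracle,
  400-tumour/170-control cohorts for depletion testing. The full suite
  runs in well under a minute per heavy test.

## Known limitations

- Genotyping requires regions called from bulk data; no de novo CNV
  discovery from expression alone, and no integer copy-number
  estimation per cell.
- The Lorenz cell filter's exact statistic follows the package's own
  definition (one-sided sup-deviation of the cell's Lorenz curve above
  the pooled reference curve, rank p-values); the filter threshold is a
  required user parameter.
- The stromal triage's clustering criterion depends on a sensible
  marker panel and cluster count; with an empty panel it degrades, with
  a warning, to the genomic criteria alone.
- Differential-expression engines are out of scope; `clonemapr` exports
  per-group raw submatrices for them instead.
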