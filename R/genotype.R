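#' Sum library-size-normalized expression over CNV regions
#'
#' For each CNV candidate region, sums the CPM of its member genes in each
#' cell. Copy-number changes that span hundreds of genes shift this sum
#' even though individual genes are noisy. Region genes are resolved
#' against the matrix by identifier when the region table has a `genes`
#' column, otherwise by genomic-interval overlap (0-based half-open).
#'
#' @param x a CPM [expr_matrix].
#' @param regions data.frame of regions with `region_id`, `direction`, and
#'   either `genes` (comma-separated ids) or `chrom`, `start`, `end`.
#' @return object of class `region_scores`: list with `scores` (regions x
#'   cells matrix), `regions` (the input table), `n_genes_used`, and
#'   `flagged` (region ids resolving to zero genes, excluded from calling).
#' @export
score_regions <- function(x, regions) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$norm != "cpm") stop("score_regions needs a CPM-normalized matrix")
  regions <- as.data.frame(regions)
  if (!"region_id" %in% names(regions)) {
    stop("region table needs a 'region_id' column")
  }
  if (!"direction" %in% names(regions)) {
    stop("region table needs a 'direction' column")
  }
  idx <- resolve_region_genes(x, regions)
  n_used <- vapply(idx, length, integer(1))
  flagged <- regions$region_id[n_used == 0]
  if (length(flagged)) {
    warning("region(s) with no detected genes: ",
            paste(flagged, collapse = ", "))
  }
  scores <- t(vapply(idx, function(i) {
    if (!length(i)) rep(0, ncol(x$counts)) else
      colSums(x$counts[i, , drop = FALSE])
  }, numeric(ncol(x$counts))))
  dimnames(scores) <- list(regions$region_id, x$cells)
  structure(list(scores = scores, regions = regions,
                 n_genes_used = stats::setNames(n_used, regions$region_id),
                 flagged = flagged),
            class = "region_scores")
}

# per region: integer indices of matrix genes belonging to it
resolve_region_genes <- function(x, regions) {
  has_genes <- "genes" %in% names(regions) &&
    any(nzchar(regions$genes) & !is.na(regions$genes))
  lapply(seq_len(nrow(regions)), function(i) {
    if (has_genes) {
      ids <- split_genes(regions$genes[i])
      hit <- match(ids, rownames(x$counts))
      miss <- ids[is.na(hit)]
      if (length(miss)) {
        message("region ", regions$region_id[i], ": ", length(miss),
                " gene(s) not in matrix, skipped")
      }
      hit[!is.na(hit)]
    } else {
      if (!all(c("chrom", "start", "end") %in% names(x$genes))) {
        stop("matrix genes lack coordinates; provide a 'genes' column ",
             "in the region table")
      }
      which(x$genes$chrom == regions$chrom[i] &
              x$genes$end > regions$start[i] &
              x$genes$start < regions$end[i])
    }
  })
}

#' Build a control reference for CNV calling
#'
#' Stores, per region, the score distribution over CNV-free control cells
#' and the direction-appropriate 5% threshold (95th percentile for gains,
#' 5th for losses) used for presence/absence calling.
#'
#' @param control_scores a [score_regions()] result on control cells.
#' @param sig_level tail mass defining the threshold (default 0.05).
#' @return object of class `control_reference`.
#' @export
build_control_reference <- function(control_scores, sig_level = 0.05) {
  stopifnot(inherits(control_scores, "region_scores"))
  sc <- control_scores$scores
  if (ncol(sc) < 10) stop("need at least 10 control cells")
  dir <- control_scores$regions$direction
  thr <- vapply(seq_len(nrow(sc)), function(r) {
    if (dir[r] == "gain") {
      stats::quantile(sc[r, ], 1 - sig_level, names = FALSE)
    } else {
      stats::quantile(sc[r, ], sig_level, names = FALSE)
    }
  }, numeric(1))
  structure(list(scores = sc, directions = stats::setNames(dir, rownames(sc)),
                 thresholds = stats::setNames(thr, rownames(sc)),
                 sig_level = sig_level),
            class = "control_reference")
}

#' Direction-consistent empirical p-values for region scores
#'
#' One-tailed add-one empirical p-value of every cell x region score
#' against the control distribution, in the direction of the candidate
#' CNV: for a gain, small p means the score exceeds the controls; for a
#' loss, small p means it falls below them.
#'
#' @param scores a [score_regions()] result on the cells to genotype.
#' @param ref a [build_control_reference()].
#' @return cells x regions matrix of p-values.
#' @export
empirical_pvalues <- function(scores, ref) {
  stopifnot(inherits(scores, "region_scores"),
            inherits(ref, "control_reference"))
  regs <- rownames(scores$scores)
  if (length(scores$flagged)) {
    message("excluding unresolvable region(s) from calling: ",
            paste(scores$flagged, collapse = ", "))
    regs <- setdiff(regs, scores$flagged)
  }
  miss <- setdiff(regs, rownames(ref$scores))
  if (length(miss)) {
    stop("region(s) missing from control reference: ",
         paste(miss, collapse = ", "))
  }
  p <- vapply(regs, function(r) {
    tail <- if (ref$directions[r] == "gain") "upper" else "lower"
    empirical_p(scores$scores[r, ], ref$scores[r, ], tail = tail)
  }, numeric(ncol(scores$scores)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(colnames(scores$scores), regs))
  p  # cells x regions
}

#' Call per-cell CNV genotypes
#'
#' Benjamini-Hochberg correction applied jointly over all cell x region
#' tests; a region is called present in a cell when its adjusted q-value
#' falls below `alpha`. Regions flagged as unresolvable (zero genes) can
#' be excluded upstream.
#'
#' @param pvals cells x regions p-value matrix from [empirical_pvalues()].
#' @param alpha q-value threshold for a call (default 0.05, the same 5%
#'   level as the empirical threshold); any `alpha >= 1` is the degenerate
#'   everything-called setting.
#' @return object of class `genotype_matrix`: list with `calls` (cells x
#'   regions 0/1), `pvals`, `qvals`, `alpha`.
#' @export
call_genotypes <- function(pvals, alpha = 0.05) {
  stopifnot(is.matrix(pvals), all(pvals >= 0 & pvals <= 1))
  q <- bh_adjust(pvals)
  calls <- (q < alpha | alpha >= 1) * 1L
  structure(list(calls = calls, pvals = pvals, qvals = q, alpha = alpha),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d cells x %d regions, %d calls (alpha = %g)\n",
              nrow(x$calls), ncol(x$calls), sum(x$calls), x$alpha))
  invisible(x)
}

#' Cross-validated false-call rate of the CNV genotyper
#'
#' Ten-fold cross-validation on CNV-free control cells: each fold's
#' reference is built from the 90% training tranche and genotypes are
#' called on the held-out 10%; since every held-out test is null, the
#' fold's (positive calls) / (total tests) estimates the classifier's
#' false-call rate.
#'
#' @param control_matrix raw or CPM [expr_matrix] of control cells.
#' @param regions region table (see [score_regions()]).
#' @param folds number of folds (default 10).
#' @param alpha call threshold passed to [call_genotypes()].
#' @param seed seed for the fold assignment.
#' @return list with `per_fold` (false-call rate per fold), `max_fold`,
#'   `overall` (pooled across folds), `folds` (per-cell fold index).
#' @export
crossval_fdr <- function(control_matrix, regions, folds = 10, alpha = 0.05,
                         seed = 1) {
  stopifnot(inherits(control_matrix, "expr_matrix"))
  if (control_matrix$norm == "raw") {
    control_matrix <- cpm_normalize(control_matrix)
  }
  n <- ncol(control_matrix$counts)
  if (n < folds * 2) stop("need at least ", folds * 2, " control cells")
  sc <- score_regions(control_matrix, regions)
  fold <- local_seed(seed, sample(rep_len(seq_len(folds), n)))
  per_fold <- vapply(seq_len(folds), function(f) {
    train <- sc
    train$scores <- sc$scores[, fold != f, drop = FALSE]
    test <- sc
    test$scores <- sc$scores[, fold == f, drop = FALSE]
    ref <- build_control_reference(train)
    p <- empirical_pvalues(test, ref)
    gt <- call_genotypes(p, alpha = alpha)
    mean(gt$calls)
  }, numeric(1))
  list(per_fold = per_fold, max_fold = max(per_fold),
       overall = mean(per_fold),
       folds = stats::setNames(fold, control_matrix$cells))
}

# single-level Haar transform with soft-thresholded detail coefficients;
# universal threshold sigma * sqrt(2 log n), sigma from the MAD of the
# detail coefficients. Odd-length tails pass through unsmoothed.
haar_denoise <- function(v) {
  n <- length(v)
  if (n < 4) return(v)
  m <- n - n %% 2L
  x1 <- v[seq(1, m, 2)]
  x2 <- v[seq(2, m, 2)]
  a <- (x1 + x2) / sqrt(2)
  d <- (x1 - x2) / sqrt(2)
  sigma <- stats::mad(d)
  thr <- sigma * sqrt(2 * log(length(d)))
  d <- sign(d) * pmax(abs(d) - thr, 0)
  out <- v
  out[seq(1, m, 2)] <- (a + d) / sqrt(2)
  out[seq(2, m, 2)] <- (a - d) / sqrt(2)
  out
}

#' Wavelet-smoothed expression-ratio track per cell
#'
#' For heatmap rendering of CNVs along the genome: per gene, the log2
#' ratio of the cell's CPM to the median control CPM (pseudo-count 1
#' CPM), denoised along genomic order within each chromosome by a
#' single-level Haar soft-threshold filter, then z-scored per cell.
#'
#' @param x CPM [expr_matrix] of tumour cells; genes need coordinates.
#' @param control CPM `expr_matrix` of control cells on a shared gene
#'   universe.
#' @param eps pseudo-count in CPM units (default 1).
#' @param smooth apply the Haar denoiser (`TRUE`); `FALSE` returns the raw
#'   z-scored ratio track for side-by-side comparison.
#' @return list with `track` (genes x cells matrix, genomic order) and
#'   `genes` (ordered gene annotation).
#' @export
wavelet_smooth_track <- function(x, control, eps = 1, smooth = TRUE) {
  stopifnot(inherits(x, "expr_matrix"), inherits(control, "expr_matrix"))
  if (x$norm != "cpm" || control$norm != "cpm") {
    stop("both matrices must be CPM-normalized")
  }
  shared <- intersect(rownames(x$counts), rownames(control$counts))
  x <- x[shared, ]
  control <- control[shared, ]
  has_pos <- !is.na(x$genes$chrom) & !is.na(x$genes$start)
  if (!all(has_pos)) {
    warning(sum(!has_pos), " gene(s) lack coordinates and were dropped")
    x <- x[which(has_pos), ]
    control <- control[which(has_pos), ]
  }
  ord <- order(x$genes$chrom, x$genes$start)
  x <- x[ord, ]
  control <- control[ord, ]
  ctrl_med <- apply(control$counts, 1, stats::median)
  ratio <- log2((x$counts + eps) / (ctrl_med + eps))
  if (smooth) {
    chrom <- x$genes$chrom
    for (chr in unique(chrom)) {
      i <- which(chrom == chr)
      ratio[i, ] <- apply(ratio[i, , drop = FALSE], 2, haar_denoise)
    }
  }
  track <- apply(ratio, 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) v * 0 else (v - mean(v)) / s
  })
  list(track = track, genes = x$genes)
}

#' Flag putative stromal (non-malignant) cells
#'
#' A cell is called putative stromal when it carries none of the CNV
#' calls, none of the expressed somatic mutations, and its
#' hierarchical-clustering assignment (correlation distance, average
#' linkage, on marker-panel log-CPM) falls in a cluster whose majority is
#' CNV-free. With an empty marker panel the clustering criterion is
#' skipped with a warning and only the genomic criteria apply.
#'
#' @param genotypes a [call_genotypes()] result.
#' @param mutation_evidence named per-cell counts of expressed somatic
#'   SNVs/indels (missing cells treated as 0).
#' @param x raw or CPM [expr_matrix] over the same cells.
#' @param marker_panel character vector of marker gene ids.
#' @param n_clusters clusters to cut the dendrogram into (default 2).
#' @return data.frame with `cell`, `n_cnv_calls`, `n_mutations`,
#'   `cluster`, `label` (`"tumor"` / `"putative-stromal"`).
#' @export
flag_stromal <- function(genotypes, mutation_evidence, x, marker_panel,
                         n_clusters = 2) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(x, "expr_matrix"))
  cells <- rownames(genotypes$calls)
  stopifnot(all(cells %in% x$cells))
  n_cnv <- rowSums(genotypes$calls)
  n_mut <- rep(0, length(cells))
  if (!is.null(mutation_evidence)) {
    hit <- match(cells, names(mutation_evidence))
    n_mut[!is.na(hit)] <- mutation_evidence[hit[!is.na(hit)]]
  }
  panel <- intersect(marker_panel, rownames(x$counts))
  cluster <- rep(NA_integer_, length(cells))
  cluster_ok <- rep(TRUE, length(cells))
  if (length(panel) < 2) {
    warning("marker panel empty after matching; ",
            "clustering criterion skipped")
  } else {
    lc <- log_cpm(x[panel, cells])
    cc <- suppressWarnings(stats::cor(lc))
    cc[!is.finite(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    cluster <- stats::cutree(hc, k = min(n_clusters, length(cells)))
    zero <- n_cnv == 0
    stromal_clusters <- which(vapply(seq_len(max(cluster)), function(k) {
      mean(zero[cluster == k]) > 0.5
    }, logical(1)))
    cluster_ok <- cluster %in% stromal_clusters
  }
  label <- ifelse(n_cnv == 0 & n_mut == 0 & cluster_ok,
                  "putative-stromal", "tumor")
  data.frame(cell = cells, n_cnv_calls = as.numeric(n_cnv),
             n_mutations = n_mut, cluster = cluster, label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}
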