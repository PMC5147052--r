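#' Backbone path of clonal progression through the phylogeny
#'
#' Orders genotype classes along the main line of clonal progression:
#' starting from the CNV-free root, repeatedly step to the unused class
#' whose genotype contains everything acquired so far, choosing at each
#' level the newly acquired region carried by the most cells (ties: the
#' larger class, then lexicographic class id). Classes on the path are
#' then binned into early / mid / late terciles of path position (ties
#' favour earlier bins).
#'
#' @param phylogeny a [fitch_margoliash_fit()] result (kept for interface
#'   symmetry and validated against the classes; the walk itself operates
#'   on the nested genotype sets that the tree was built from).
#' @param classes a [collapse_genotypes()] result.
#' @return object of class `backbone_path`: data.frame with `position`,
#'   `class_id`, `n_cells`, `n_regions`, `acquired` (regions added at the
#'   step) and `bin`.
#' @export
backbone_path <- function(phylogeny, classes) {
  stopifnot(inherits(classes, "genotype_classes"))
  if (!is.null(phylogeny)) {
    stopifnot(inherits(phylogeny, "clone_phylogeny"))
    stopifnot(all(classes$classes$class_id %in%
                    phylogeny$unrooted$tip.label))
  }
  sets <- classes$genotype_sets
  tab <- classes$classes
  # cells carrying each region, across all classes
  region_freq <- function(r) {
    sum(tab$n_cells[vapply(sets, function(g) r %in% g, logical(1))])
  }
  used <- rep(FALSE, nrow(tab))
  S <- character(0)
  path <- integer(0)
  # a CNV-free class, if present, anchors the path at the root
  empty_cls <- which(!nzchar(tab$genotype))
  if (length(empty_cls)) {
    path <- empty_cls
    used[empty_cls] <- TRUE
  }
  repeat {
    cand <- which(!used & vapply(sets, function(g) {
      all(S %in% g) && length(g) > length(S)
    }, logical(1)))
    if (!length(cand)) break
    # step only to minimal supersets: a candidate containing another
    # candidate's genotype is further down the same lineage
    minimal <- vapply(cand, function(i) {
      !any(vapply(setdiff(cand, i), function(j) {
        all(sets[[j]] %in% sets[[i]]) &&
          length(sets[[j]]) < length(sets[[i]])
      }, logical(1)))
    }, logical(1))
    cand <- cand[minimal]
    score <- vapply(cand, function(i) {
      max(vapply(setdiff(sets[[i]], S), region_freq, numeric(1)))
    }, numeric(1))
    pick <- cand[order(-score, -tab$n_cells[cand], tab$class_id[cand])][1]
    path <- c(path, pick)
    used[pick] <- TRUE
    S <- sets[[pick]]
  }
  k <- length(path)
  if (k == 0) stop("no classes to order")
  if (k == 1) warning("single-class path; one bin only")
  bin_idx <- if (k >= 3) {
    floor(3 * (seq_len(k) - 1) / k) + 1
  } else if (k == 2) c(1L, 3L) else 1L
  bins <- c("early", "mid", "late")[bin_idx]
  prev <- c(list(character(0)), sets[tab$class_id[path]])[seq_len(k)]
  acquired <- vapply(seq_len(k), function(i) {
    paste(setdiff(sets[[tab$class_id[path[i]]]] %||% character(0),
                  prev[[i]]), collapse = "+")
  }, character(1))
  out <- data.frame(position = seq_len(k),
                    class_id = tab$class_id[path],
                    n_cells = tab$n_cells[path],
                    n_regions = vapply(sets[tab$class_id[path]], length,
                                       integer(1)),
                    acquired = acquired,
                    bin = bins, stringsAsFactors = FALSE)
  class(out) <- c("backbone_path", "data.frame")
  out
}

#' Genes with monotone expression along the backbone
#'
#' Assigns every cell of a backbone class to its early/mid/late bin and
#' flags genes whose bin means are strictly ordered in the requested
#' direction across the bins. The per-bin mean and SD used for the
#' decision are returned.
#'
#' @param x CPM [expr_matrix].
#' @param path a [backbone_path()].
#' @param classes the [collapse_genotypes()] result holding class
#'   membership.
#' @param direction `"increasing"` or `"decreasing"`.
#' @param min_fold optional fold-change floor between successive bin means
#'   (on top of strict ordering).
#' @return data.frame with one row per gene: per-bin `mean_*` / `sd_*` /
#'   `n_*` columns and a logical `monotone` flag.
#' @export
monotone_genes <- function(x, path, classes,
                           direction = c("increasing", "decreasing"),
                           min_fold = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(x, "expr_matrix"), inherits(path, "backbone_path"),
            inherits(classes, "genotype_classes"))
  if (x$norm != "cpm") stop("monotone_genes needs a CPM matrix")
  bins_present <- unique(path$bin)
  cells_by_bin <- lapply(bins_present, function(b) {
    cls <- path$class_id[path$bin == b]
    intersect(unlist(classes$members[cls], use.names = FALSE), x$cells)
  })
  names(cells_by_bin) <- bins_present
  sizes <- vapply(cells_by_bin, length, integer(1))
  if (sum(sizes >= 2) < 2) stop("need at least 2 bins with >= 2 cells")
  stats_by_bin <- lapply(cells_by_bin, function(cl) {
    m <- x$counts[, cl, drop = FALSE]
    list(mean = rowMeans(m), sd = apply(m, 1, stats::sd))
  })
  means <- do.call(cbind, lapply(stats_by_bin, `[[`, "mean"))
  sds <- do.call(cbind, lapply(stats_by_bin, `[[`, "sd"))
  cmp <- if (direction == "increasing") `>` else `<`
  mono <- rep(TRUE, nrow(means))
  for (j in seq_len(ncol(means) - 1)) {
    mono <- mono & cmp(means[, j + 1], means[, j])
    if (!is.null(min_fold)) {
      hi <- pmax(means[, j + 1], means[, j])
      lo <- pmin(means[, j + 1], means[, j])
      mono <- mono & hi >= min_fold * lo
    }
  }
  out <- data.frame(gene_id = rownames(x$counts), stringsAsFactors = FALSE)
  for (b in bins_present) {
    out[[paste0("mean_", b)]] <- means[, b]
    out[[paste0("sd_", b)]] <- sds[, b]
    out[[paste0("n_", b)]] <- length(cells_by_bin[[b]])
  }
  out$monotone <- mono
  out
}

#' Dose-response gene ranking against a focal transcript
#'
#' Ranks every gene by the Spearman correlation of its expression with
#' the per-cell expression of a focal transcript (for instance a receptor
#' deletion mutant), and reports the top and bottom 5% tails as the
#' positively and negatively responding gene sets.
#'
#' @param x CPM [expr_matrix], ideally prefiltered with
#'   [de_gene_filter()].
#' @param focal a gene id present in `x`, or a named numeric vector of
#'   per-cell focal expression.
#' @param tail_quantile tail size for each gene set (default 0.05).
#' @return object of class `dose_response`: list with `table` (gene, rho,
#'   rank), `positive`, `negative`, `focal`.
#' @export
dose_response <- function(x, focal, tail_quantile = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$norm != "cpm") stop("dose_response needs a CPM matrix")
  if (is.character(focal) && length(focal) == 1) {
    if (!focal %in% rownames(x$counts)) stop("focal gene not in matrix")
    fvec <- x$counts[focal, ]
    fname <- focal
  } else {
    stopifnot(is.numeric(focal))
    fvec <- focal[x$cells]
    if (anyNA(fvec)) stop("focal vector missing values for some cells")
    fname <- "focal"
  }
  if (sum(fvec > 0) < 10) stop("focal transcript expressed in < 10 cells")
  if (stats::sd(fvec) == 0) stop("focal vector is constant")
  rho <- suppressWarnings(
    as.vector(stats::cor(t(x$counts), fvec, method = "spearman")))
  tab <- data.frame(gene_id = rownames(x$counts), rho = rho,
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$rho), , drop = FALSE]
  tab <- tab[order(-tab$rho, tab$gene_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  k <- ceiling(tail_quantile * nrow(tab))
  structure(list(table = tab,
                 positive = tab$gene_id[seq_len(k)],
                 negative = tab$gene_id[seq(nrow(tab) - k + 1, nrow(tab))],
                 focal = fname, tail_quantile = tail_quantile,
                 set_size = k),
            class = "dose_response")
}

#' Expression prefilter for differential and dose-response analyses
#'
#' Drops genes expressed below `cpm_floor` in more than
#' `max_lowexpr_frac` of cells.
#'
#' @param x CPM [expr_matrix].
#' @param max_lowexpr_frac drop a gene when the fraction of cells below
#'   the floor exceeds this (default 0.8).
#' @param cpm_floor expression floor in CPM (default 1).
#' @return character vector of retained gene ids.
#' @export
de_gene_filter <- function(x, max_lowexpr_frac = 0.8, cpm_floor = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$norm != "cpm") stop("de_gene_filter needs a CPM matrix")
  low_frac <- rowMeans(x$counts < cpm_floor)
  rownames(x$counts)[low_frac <= max_lowexpr_frac]
}

#' Export per-group raw count submatrices for an external DE engine
#'
#' Splits the raw counts into one submatrix per group — either carriers
#' vs. wild-type of one CNV region, or one submatrix per genotype class —
#' with a membership manifest, suitable for DESeq-style tools that treat
#' each cell as a replicate.
#'
#' @param x raw [expr_matrix].
#' @param genotypes a [call_genotypes()] result.
#' @param grouping a region id (carriers vs. wild-type) or `"class"`
#'   (one group per genotype class).
#' @param classes required when `grouping = "class"`: a
#'   [collapse_genotypes()] result.
#' @return list with `matrices` (named list of `expr_matrix`) and
#'   `manifest` (data.frame `cell`, `group`).
#' @export
export_clone_submatrices <- function(x, genotypes, grouping,
                                     classes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$norm != "raw") stop("export_clone_submatrices needs raw counts")
  if (identical(grouping, "class")) {
    stopifnot(inherits(classes, "genotype_classes"))
    groups <- classes$members
  } else {
    stopifnot(inherits(genotypes, "genotype_matrix"))
    if (!grouping %in% colnames(genotypes$calls)) {
      stop("unknown region '", grouping, "'")
    }
    carrier <- rownames(genotypes$calls)[genotypes$calls[, grouping] == 1]
    wild <- setdiff(rownames(genotypes$calls), carrier)
    groups <- list(carrier = carrier, wildtype = wild)
  }
  groups <- lapply(groups, intersect, y = x$cells)
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small)) {
    warning("group(s) with < 2 cells: ", paste(small, collapse = ", "))
  }
  mats <- lapply(groups, function(cl) x[, cl])
  manifest <- data.frame(
    cell = unlist(groups, use.names = FALSE),
    group = rep(names(groups), vapply(groups, length, integer(1))),
    stringsAsFactors = FALSE)
  list(matrices = mats, manifest = manifest)
}

#' Centroid-regression molecular subtype classification
#'
#' Per cell, fits ordinary least squares of the cell's standardized
#' log2(CPM+1) profile over the signature genes on the (standardized)
#' subtype centroids, without intercept, and assigns the subtype whose
#' coefficient is largest in magnitude.
#'
#' @param x raw or CPM [expr_matrix].
#' @param centroids numeric matrix, signature genes x subtypes, with gene
#'   row names and subtype column names.
#' @return data.frame with `cell`, one coefficient column per subtype,
#'   and `label`.
#' @export
verhaak_classify <- function(x, centroids) {
  stopifnot(inherits(x, "expr_matrix"), is.matrix(centroids))
  lc <- log_cpm(x)
  genes <- intersect(rownames(lc), rownames(centroids))
  if (length(genes) < 10) stop("fewer than 10 signature genes in matrix")
  X <- apply(centroids[genes, , drop = FALSE], 2, function(v) {
    (v - mean(v)) / stats::sd(v)
  })
  if (qr(X)$rank < ncol(X)) stop("centroid matrix is rank deficient")
  Y <- apply(lc[genes, , drop = FALSE], 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) v * 0 else (v - mean(v)) / s
  })
  coefs <- qr.coef(qr(X), Y)  # subtypes x cells
  label <- colnames(centroids)[apply(abs(coefs), 2, which.max)]
  out <- data.frame(cell = colnames(lc), t(coefs), label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[1 + seq_len(ncol(centroids))] <- colnames(centroids)
  out
}

#' Two-module expression classifier
#'
#' Averages log2(CPM+1) over two gene modules per cell and assigns the
#' module whose average is more than `fold` times the other; otherwise
#' the cell is ambiguous.
#'
#' @param x raw or CPM [expr_matrix].
#' @param module_a,module_b character vectors of gene ids.
#' @param fold required fold difference (default 2; "more than twofold"
#'   is strict).
#' @param labels labels assigned when module A / module B dominates.
#' @return data.frame with `cell`, `mean_a`, `mean_b`, `label`.
#' @export
sun_classify <- function(x, module_a, module_b, fold = 2,
                         labels = c("PDGFRA-module", "EGFR-module")) {
  stopifnot(inherits(x, "expr_matrix"))
  lc <- log_cpm(x)
  a <- intersect(module_a, rownames(lc))
  b <- intersect(module_b, rownames(lc))
  if (!length(a) || !length(b)) {
    stop("a module is empty after intersecting with matrix genes")
  }
  mean_a <- colMeans(lc[a, , drop = FALSE])
  mean_b <- colMeans(lc[b, , drop = FALSE])
  label <- ifelse(mean_a > fold * mean_b, labels[1],
                  ifelse(mean_b > fold * mean_a, labels[2], "ambiguous"))
  data.frame(cell = colnames(lc), mean_a = mean_a, mean_b = mean_b,
             label = label, stringsAsFactors = FALSE, row.names = NULL)
}
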