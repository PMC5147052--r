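#' Per-cell library complexity and coverage metrics
#'
#' Computes, per cell, the Gini-Simpson diversity of the gene-proportion
#' vector, `1 - sum(p_i^2)` (0 when a single gene carries the whole
#' library, `1 - 1/k` for k equally expressed genes), and the Good-Turing
#' coverage estimate `1 - singletons / library size` (the estimated
#' probability that the next read comes from an already-seen gene). Both
#' flag low-complexity, low-coverage libraries.
#'
#' @param x a raw [expr_matrix].
#' @return data.frame with `cell`, `library_size`, `gini_simpson`,
#'   `good_turing_coverage`; metrics are `NA` for zero-library cells.
#' @export
qc_metrics <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$norm != "raw") stop("qc_metrics needs raw counts")
  ls <- colSums(x$counts)
  gs <- rep(NA_real_, ncol(x$counts))
  gt <- rep(NA_real_, ncol(x$counts))
  ok <- ls > 0
  if (any(ok)) {
    p <- sweep(x$counts[, ok, drop = FALSE], 2, ls[ok], `/`)
    gs[ok] <- 1 - colSums(p^2)
    gt[ok] <- 1 - colSums(x$counts[, ok, drop = FALSE] == 1) / ls[ok]
  }
  data.frame(cell = x$cells, library_size = as.numeric(ls),
             gini_simpson = gs, good_turing_coverage = gt,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Lorenz curve of a count/proportion vector: cumulative expression share
# with genes sorted ascending; returned at each of the G gene positions.
lorenz_curve <- function(v) {
  s <- sum(v)
  if (s == 0) return(rep(NA_real_, length(v)))
  cumsum(sort(v)) / s
}

# sup-deviation of a cell's Lorenz curve *above* the reference curve:
# excess uniformity relative to the reference (background signal)
lorenz_stat <- function(cell_counts, ref_curve) {
  lc <- lorenz_curve(cell_counts)
  if (anyNA(lc)) return(NA_real_)
  max(c(lc - ref_curve, 0))
}

#' Filter cells with significantly high background by a Lorenz statistic
#'
#' Degraded single-cell libraries have an abnormally uniform ("flat")
#' expression profile: background reads spread across many genes. Per
#' cell, the statistic is the maximum vertical deviation of the cell's
#' Lorenz curve (cumulative sorted expression shares) above the pooled
#' reference curve. P-values are empirical ranks of the statistic among
#' the reference cells' own statistics (add-one convention), corrected
#' across cells by Benjamini-Hochberg; cells with `q < q_threshold` fail.
#'
#' @param x raw [expr_matrix] of cells to triage.
#' @param reference raw `expr_matrix` of reference cells (>= 10), or
#'   `NULL` to use `x` itself as its own reference pool.
#' @param q_threshold BH q-value below which a cell is failed.
#' @return data.frame with `cell`, `lorenz_stat`, `lorenz_p`, `lorenz_q`,
#'   `pass`.
#' @export
lorenz_filter <- function(x, reference = NULL, q_threshold = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$norm != "raw") stop("lorenz_filter needs raw counts")
  reference <- reference %||% x
  stopifnot(inherits(reference, "expr_matrix"))
  if (ncol(reference$counts) < 10) {
    stop("need at least 10 reference cells")
  }
  if (!identical(rownames(reference$counts), rownames(x$counts))) {
    shared <- intersect(rownames(x$counts), rownames(reference$counts))
    if (length(shared) < 2) stop("no shared gene universe with reference")
    x <- x[shared, ]
    reference <- reference[shared, ]
  }
  pooled <- rowSums(reference$counts)
  ref_curve <- lorenz_curve(pooled)
  ref_stats <- apply(reference$counts, 2, lorenz_stat, ref_curve = ref_curve)
  stat <- apply(x$counts, 2, lorenz_stat, ref_curve = ref_curve)
  p <- rep(NA_real_, length(stat))
  p[!is.na(stat)] <- empirical_p(stat[!is.na(stat)],
                                 ref_stats[!is.na(ref_stats)],
                                 tail = "upper")
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  data.frame(cell = x$cells, lorenz_stat = as.numeric(stat),
             lorenz_p = p, lorenz_q = q,
             pass = !is.na(q) & q >= q_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
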