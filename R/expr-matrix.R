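#' Gene-by-cell expression matrix
#'
#' Lightweight container (in the spirit of edgeR's `DGEList`) holding a
#' genes x cells count matrix together with per-gene genomic intervals,
#' per-cell library sizes and the normalization state. All genomic
#' intervals are 0-based half-open (BED convention).
#'
#' @param counts numeric matrix, genes in rows, cells in columns. Must be
#'   non-negative; `norm = "raw"` additionally expects integer-valued
#'   entries. Row names are gene identifiers, column names cell identifiers
#'   (generated when absent).
#' @param genes optional `data.frame` of gene annotation with columns
#'   `gene_id` and optionally `chrom`, `start`, `end`. Matched to the rows
#'   of `counts`.
#' @param norm `"raw"` or `"cpm"`.
#' @param lib_sizes per-cell library sizes. For raw matrices these are the
#'   column sums and are computed when omitted; CPM matrices must carry the
#'   library sizes of the raw counts they came from.
#' @return an object of class `expr_matrix`: a list with elements `counts`,
#'   `genes`, `cells`, `norm`, `lib_sizes`.
#' @examples
#' m <- expr_matrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("c1", "c2"))))
#' m$lib_sizes
#' @export
expr_matrix <- function(counts, genes = NULL, norm = c("raw", "cpm"),
                        lib_sizes = NULL) {
  norm <- match.arg(norm)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', cell '%s'",
                 rownames(counts)[bad[1]] %||% bad[1],
                 colnames(counts)[bad[2]] %||% bad[2]))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell_%d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (is.null(genes)) {
    genes <- data.frame(gene_id = rownames(counts),
                        stringsAsFactors = FALSE)
  } else {
    genes <- as.data.frame(genes)
    if (!"gene_id" %in% names(genes)) {
      stop("gene annotation needs a 'gene_id' column")
    }
    genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
    rownames(genes) <- NULL
    if (anyNA(genes$gene_id)) stop("gene annotation missing for some genes")
  }
  if (is.null(lib_sizes)) {
    if (norm == "cpm") stop("CPM matrices must carry raw library sizes")
    lib_sizes <- colSums(counts)
  }
  lib_sizes <- stats::setNames(as.numeric(lib_sizes), colnames(counts))
  structure(list(counts = counts, genes = genes, cells = colnames(counts),
                 norm = norm, lib_sizes = lib_sizes),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells [%s]\n",
              nrow(x$counts), ncol(x$counts), x$norm))
  cat(sprintf("  median library size: %.0f\n", stats::median(x$lib_sizes)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Subset an expression matrix
#'
#' @param x an [expr_matrix].
#' @param i gene index (names, logical or integer).
#' @param j cell index.
#' @param ... unused.
#' @return an `expr_matrix` over the selected genes/cells. Library sizes
#'   are carried over unchanged (they describe whole cells, not subsets).
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  cnt <- x$counts[i, j, drop = FALSE]
  gi <- match(rownames(cnt), x$genes$gene_id)
  structure(list(counts = cnt,
                 genes = x$genes[gi, , drop = FALSE],
                 cells = colnames(cnt), norm = x$norm,
                 lib_sizes = x$lib_sizes[colnames(cnt)]),
            class = "expr_matrix")
}

#' Read a count matrix from TSV or MatrixMarket files
#'
#' Wide TSV: first column gene identifiers (header `gene_id`; optional
#' `chrom`, `start`, `end` annotation columns may precede the cell
#' columns), one column per cell. MTX: `path` is the `.mtx` file; gene and
#' cell identifiers are read from `<stem>_genes.tsv` and `<stem>_cells.tsv`
#' next to it (as written by [write_counts()]).
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"tsv"` or `"mtx"`.
#' @return an [expr_matrix] in raw state.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    mat <- as.matrix(Matrix::readMM(path))
    gtab <- utils::read.delim(paste0(stem, "_genes.tsv"),
                              stringsAsFactors = FALSE)
    ctab <- utils::read.delim(paste0(stem, "_cells.tsv"),
                              stringsAsFactors = FALSE)
    if (nrow(gtab) != nrow(mat) || nrow(ctab) != ncol(mat)) {
      stop("MTX sidecar dimensions do not match the matrix")
    }
    rownames(mat) <- gtab$gene_id
    colnames(mat) <- ctab$cell_id
    return(expr_matrix(mat, genes = gtab))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"gene_id" %in% names(tab)) {
    stop("TSV count file needs a 'gene_id' first column")
  }
  anno_cols <- intersect(c("gene_id", "chrom", "start", "end"), names(tab))
  cell_cols <- setdiff(names(tab), anno_cols)
  if (!length(cell_cols)) stop("no cell columns found in ", path)
  mat <- as.matrix(tab[, cell_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- cell_cols[!vapply(tab[cell_cols], is.numeric, logical(1))][1]
    stop("non-numeric counts in column '", bad, "'")
  }
  rownames(mat) <- tab$gene_id
  expr_matrix(mat, genes = tab[, anno_cols, drop = FALSE])
}

#' Write a count matrix as TSV or MatrixMarket
#'
#' @param x an [expr_matrix].
#' @param path output file; for MTX the gene/cell sidecars are written as
#'   `<stem>_genes.tsv` / `<stem>_cells.tsv`.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_matrix"))
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    paste0(stem, ".mtx"))
    utils::write.table(x$genes, paste0(stem, "_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(cell_id = x$cells),
                       paste0(stem, "_cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    tab <- cbind(x$genes, as.data.frame(x$counts, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Counts-per-million normalization
#'
#' Scales every cell to one million total counts, as is standard for
#' single-cell libraries of very different depths. Cells with an empty
#' library are left all-zero and recorded in the `zero_library` attribute.
#'
#' @param x a raw [expr_matrix]. Re-normalizing a CPM matrix is an error.
#' @return an `expr_matrix` in `cpm` state carrying the original library
#'   sizes.
#' @examples
#' m <- expr_matrix(matrix(c(1, 1, 2), 3, dimnames = list(c("a", "b", "c"), "c1")))
#' cpm_normalize(m)$counts[, 1]
#' @export
cpm_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$norm != "raw") stop("matrix is already CPM-normalized")
  ls <- colSums(x$counts)
  zero <- ls == 0
  scale_by <- ifelse(zero, 0, 1e6 / ifelse(zero, 1, ls))
  cpm <- sweep(x$counts, 2, scale_by, `*`)
  out <- expr_matrix(cpm, genes = x$genes, norm = "cpm", lib_sizes = ls)
  attr(out, "zero_library") <- x$cells[zero]
  out
}

# shared helper: log2(CPM + 1), accepting raw (normalized on the fly) or cpm
log_cpm <- function(x) {
  if (x$norm == "raw") x <- cpm_normalize(x)
  log2(x$counts + 1)
}
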