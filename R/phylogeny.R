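#' Jaccard distance between two CNV genotypes
#'
#' `1 - |intersection| / |union|` of the two region sets: the number of
#' shared CNV calls as a fraction of the calls present in either cell.
#' Two empty genotypes are at distance 0.
#'
#' @param g1,g2 vectors of region identifiers (treated as sets).
#' @return distance in `[0, 1]`.
#' @examples
#' jaccard_distance(c("A", "B"), "A")  # 0.5
#' @export
jaccard_distance <- function(g1, g2) {
  g1 <- unique(g1)
  g2 <- unique(g2)
  u <- length(union(g1, g2))
  if (u == 0) return(0)
  1 - length(intersect(g1, g2)) / u
}

#' Collapse cells into genotype classes and compute their distances
#'
#' Cells sharing an identical set of CNV calls form one genotype class
#' (one tree leaf); a CNV-free `"normal"` out-group class is appended.
#' Pairwise Jaccard distances between class genotypes give the matrix fed
#' to the tree fit.
#'
#' @param genotypes a [call_genotypes()] result, or a cells x regions 0/1
#'   matrix.
#' @param outgroup_label label for the appended CNV-free out-group.
#' @return object of class `genotype_classes`: list with `classes`
#'   (data.frame `class_id`, `n_cells`, `genotype`), `genotype_sets`
#'   (named list of region-id sets), `members` (named list of cell ids)
#'   and `dist` (labels x labels Jaccard matrix including the out-group).
#' @export
collapse_genotypes <- function(genotypes, outgroup_label = "normal") {
  calls <- if (inherits(genotypes, "genotype_matrix")) genotypes$calls
           else as.matrix(genotypes)
  stopifnot(all(calls %in% c(0, 1)))
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("region_%02d", seq_len(ncol(calls)))
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("cell_%03d", seq_len(nrow(calls)))
  }
  key <- apply(calls, 1, function(r) paste(colnames(calls)[r == 1],
                                           collapse = "+"))
  tab <- table(key)
  # deterministic class order: larger classes first, then genotype string
  ord <- order(-as.integer(tab), names(tab))
  keys <- names(tab)[ord]
  sizes <- as.integer(tab)[ord]
  ids <- sprintf("gc%d", seq_along(keys))
  sets <- lapply(keys, function(k) if (nzchar(k)) strsplit(k, "\\+")[[1]]
                                   else character(0))
  names(sets) <- ids
  members <- lapply(keys, function(k) rownames(calls)[key == k])
  names(members) <- ids
  classes <- data.frame(class_id = ids, n_cells = sizes,
                        genotype = keys, stringsAsFactors = FALSE)
  all_sets <- c(sets, stats::setNames(list(character(0)), outgroup_label))
  labs <- names(all_sets)
  D <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (j > i) {
        D[i, j] <- D[j, i] <- jaccard_distance(all_sets[[i]], all_sets[[j]])
      }
    }
  }
  structure(list(classes = classes, genotype_sets = sets,
                 members = members, dist = D,
                 outgroup = outgroup_label),
            class = "genotype_classes")
}

# ---- Fitch-Margoliash machinery -------------------------------------------
#
# Unrooted binary topologies are held as plain 2-column edge matrices over
# nodes 1..(2n - 2), tips first (1..n in distance-matrix label order).
# Branch lengths for a fixed topology minimize the weighted least-squares
# objective sum w_ij (d_ij - p_ij)^2 with the classic weights w = 1/d^2,
# solved exactly by non-negative least squares on the path-membership
# design matrix.

# 3-tip star over a label universe of n tips; internal nodes are n+1..2n-2
star3_edges <- function(n) cbind(rep(n + 1L, 3), 1:3)

# split edge `e` of `edges` and hang tip `tip` off the new internal node
add_tip_to_edge <- function(edges, e, tip, new_internal) {
  u <- edges[e, 1]; v <- edges[e, 2]
  edges[e, ] <- c(u, new_internal)
  rbind(edges, c(new_internal, v), c(new_internal, tip))
}

# all unrooted binary topologies over n tips ((2n-5)!! of them)
enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  acc <- list(star3_edges(n))
  if (n == 3) return(acc)
  for (tip in 4:n) {
    new_int <- n + tip - 2L  # internal nodes n+1 .. 2n-2
    acc <- unlist(lapply(acc, function(ed) {
      lapply(seq_len(nrow(ed)), function(e) {
        add_tip_to_edge(ed, e, tip, new_int)
      })
    }), recursive = FALSE)
  }
  acc
}

# pair-path edge-incidence matrix: rows = tip pairs (i < j in tip_ids
# order), columns = edges
path_incidence <- function(edges, tip_ids) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  n <- length(tip_ids)
  A <- matrix(FALSE, n * (n - 1) / 2, nrow(edges))
  row <- 0L
  for (i in seq_len(n - 1)) {
    # BFS from tip i recording the incoming edge of every node
    parent_edge <- rep(NA_integer_, n_nodes)
    parent_node <- rep(NA_integer_, n_nodes)
    seen <- rep(FALSE, n_nodes)
    queue <- tip_ids[i]
    seen[queue] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- adj[[u]]
      for (k in seq_len(NROW(nb))) {
        v <- nb[k, 1]
        if (!seen[v]) {
          seen[v] <- TRUE
          parent_edge[v] <- nb[k, 2]
          parent_node[v] <- u
          queue <- c(queue, v)
        }
      }
    }
    for (j in (i + 1):n) {
      row <- row + 1L
      v <- tip_ids[j]
      while (v != tip_ids[i]) {
        A[row, parent_edge[v]] <- TRUE
        v <- parent_node[v]
      }
    }
  }
  A
}

# weighted NNLS branch-length fit; returns objective and lengths
fm_objective <- function(A, d, w) {
  sw <- sqrt(w)
  fit <- pracma::lsqnonneg(A * sw, d * sw)
  b <- fit$x
  r <- d - as.vector(A %*% b)
  list(objective = sum(w * r^2), lengths = b)
}

fm_weights <- function(d) {
  pos <- d[d > 0]
  if (!length(pos)) return(rep(1, length(d)))
  cap <- min(pos)
  1 / pmax(d, cap)^2
}

# the two nearest-neighbour-interchange rearrangements of every internal
# edge, as edge matrices
nni_neighbors <- function(edges, n_tips) {
  out <- list()
  other <- function(r, node) {
    if (edges[r, 1] == node) edges[r, 2] else edges[r, 1]
  }
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    if (u <= n_tips || v <= n_tips) next
    u_rows <- setdiff(which(edges[, 1] == u | edges[, 2] == u), e)
    v_rows <- setdiff(which(edges[, 1] == v | edges[, 2] == v), e)
    a_row <- u_rows[2]
    a <- other(a_row, u)
    for (b_row in v_rows) {
      b <- other(b_row, v)
      ne <- edges
      ne[a_row, ] <- c(u, b)
      ne[b_row, ] <- c(v, a)
      out[[length(out) + 1L]] <- ne
    }
  }
  out
}

# orient an edge matrix into an ape "phylo" object; tips keep ids 1..n
edges_to_phylo <- function(edges, n_tips, labels, lengths = NULL) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  root <- n_tips + 1L
  new_id <- integer(n_nodes)
  new_id[seq_len(n_tips)] <- seq_len(n_tips)
  next_int <- n_tips + 1L
  edge_out <- matrix(0L, nrow(edges), 2)
  len_out <- numeric(nrow(edges))
  cnt <- 0L
  # iterative preorder DFS
  stack <- list(c(root, NA, NA))  # node, parent, via-edge
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]; par <- top[2]; via <- top[3]
    if (node > n_tips) {
      new_id[node] <- next_int
      next_int <- next_int + 1L
    }
    if (!is.na(par)) {
      cnt <- cnt + 1L
      edge_out[cnt, ] <- c(new_id[par], new_id[node])
      if (!is.null(lengths)) len_out[cnt] <- lengths[via]
    }
    nb <- adj[[node]]
    for (k in rev(seq_len(NROW(nb)))) {
      if (is.na(par) || nb[k, 1] != par) {
        stack[[length(stack) + 1L]] <- c(nb[k, 1], node, nb[k, 2])
      }
    }
  }
  phy <- structure(list(edge = edge_out,
                        tip.label = labels,
                        Nnode = n_nodes - n_tips,
                        edge.length = if (is.null(lengths)) NULL else len_out),
                   class = "phylo", order = "cladewise")
  phy
}

lower_pairs <- function(D) {
  n <- nrow(D)
  d <- numeric(n * (n - 1) / 2)
  row <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    row <- row + 1L
    d[row] <- D[i, j]
  }
  d
}

#' Fit a Fitch-Margoliash least-squares phylogeny
#'
#' Minimizes the weighted least-squares objective
#' `sum_{i<j} (d_ij - p_ij)^2 / d_ij^2` over tree topologies and
#' non-negative branch lengths, where `p_ij` is the path length between
#' leaves i and j. For a fixed topology the branch lengths are solved
#' exactly by non-negative least squares on the path-membership design
#' matrix. Up to `max_exhaustive` leaves the topology search enumerates
#' every unrooted binary topology; beyond that, greedy stepwise addition
#' followed by nearest-neighbour-interchange refinement (the objective
#' never increases during NNI). The tree is rooted on the branch to the
#' out-group leaf.
#'
#' @param D symmetric distance matrix with labelled rows/columns
#'   (typically `collapse_genotypes()$dist`).
#' @param outgroup label of the out-group leaf used for rooting, or `NULL`
#'   to return an unrooted fit.
#' @param search `"auto"` (exhaustive up to `max_exhaustive` leaves, else
#'   heuristic), `"exhaustive"` or `"heuristic"`.
#' @param max_exhaustive largest leaf count for exhaustive search.
#' @return object of class `clone_phylogeny`: list with `tree` (rooted
#'   `phylo`), `unrooted` (`phylo`), `residual` (the FM objective at the
#'   optimum), `search`, `outgroup`.
#' @export
fitch_margoliash_fit <- function(D, outgroup = "normal",
                                 search = c("auto", "exhaustive", "heuristic"),
                                 max_exhaustive = 8) {
  search <- match.arg(search)
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D), isSymmetric(unname(D)))
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- sprintf("leaf_%d", seq_len(nrow(D)))
  }
  labels <- rownames(D)
  n <- length(labels)
  if (n < 3) stop("need at least 3 labels")
  if (!is.null(outgroup) && !outgroup %in% labels) {
    stop("outgroup '", outgroup, "' not among labels")
  }
  dvec <- lower_pairs(D)
  degenerate <- max(dvec) == 0
  if (degenerate) {
    warning("all distances are zero; returning a degenerate star-like tree")
  }
  w <- fm_weights(dvec)
  if (search == "auto") {
    search <- if (n <= max_exhaustive) "exhaustive" else "heuristic"
  }
  if (search == "exhaustive") {
    topos <- enumerate_topologies(n)
    best <- NULL
    for (ed in topos) {
      A <- path_incidence(ed, seq_len(n))
      fit <- fm_objective(A, dvec, w)
      if (is.null(best) || fit$objective < best$objective - 1e-12) {
        best <- c(fit, list(edges = ed))
      }
    }
    phy <- edges_to_phylo(best$edges, n, labels, best$lengths)
    objective <- best$objective
  } else {
    # stepwise addition in label order
    ed <- star3_edges(n)
    for (tip in seq(4, length.out = max(n - 3, 0))) {
      new_int <- n + tip - 2L
      sub_ids <- seq_len(tip)
      dsub <- lower_pairs(D[sub_ids, sub_ids, drop = FALSE])
      wsub <- fm_weights(dsub)
      best <- NULL
      for (e in seq_len(nrow(ed))) {
        cand <- add_tip_to_edge(ed, e, tip, new_int)
        A <- path_incidence(cand, sub_ids)
        fit <- fm_objective(A, dsub, wsub)
        if (is.null(best) || fit$objective < best$objective - 1e-12) {
          best <- c(fit, list(edges = cand))
        }
      }
      ed <- best$edges
    }
    A <- path_incidence(ed, seq_len(n))
    fit <- fm_objective(A, dvec, w)
    objective <- fit$objective
    # NNI refinement; the objective is monotone non-increasing
    if (n >= 4 && !degenerate) {
      repeat {
        improved <- FALSE
        for (ne in nni_neighbors(ed, n)) {
          A <- path_incidence(ne, seq_len(n))
          fit_ne <- fm_objective(A, dvec, w)
          if (fit_ne$objective < objective - 1e-12) {
            ed <- ne
            fit <- fit_ne
            objective <- fit_ne$objective
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
    phy <- edges_to_phylo(ed, n, labels, fit$lengths)
  }
  rooted <- NULL
  if (!is.null(outgroup)) {
    rooted <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  structure(list(tree = rooted %||% phy, unrooted = phy,
                 residual = objective, search = search,
                 outgroup = outgroup),
            class = "clone_phylogeny")
}

#' @export
print.clone_phylogeny <- function(x, ...) {
  cat(sprintf("clone_phylogeny: %d leaves, FM residual %.3g (%s search)\n",
              length(x$unrooted$tip.label), x$residual, x$search))
  invisible(x)
}

#' Serialize a fitted phylogeny as newick text
#'
#' @param x a [fitch_margoliash_fit()] result (or a `phylo`).
#' @param file optional path; when given the newick string is written
#'   there.
#' @param classes optional [collapse_genotypes()] result; when given,
#'   leaf labels are suffixed with their member-cell counts
#'   (`gc1_n12`).
#' @return the newick string, invisibly when written to file.
#' @export
to_newick <- function(x, file = NULL, classes = NULL) {
  phy <- if (inherits(x, "clone_phylogeny")) x$tree else x
  stopifnot(inherits(phy, "phylo"))
  if (!is.null(classes)) {
    stopifnot(inherits(classes, "genotype_classes"))
    hit <- match(phy$tip.label, classes$classes$class_id)
    lab <- phy$tip.label
    lab[!is.na(hit)] <- sprintf("%s_n%d", lab[!is.na(hit)],
                                classes$classes$n_cells[hit[!is.na(hit)]])
    phy$tip.label <- lab
  }
  reserved <- grepl("[(),:;\\[\\]\\s']", phy$tip.label, perl = TRUE)
  phy$tip.label[reserved] <- sprintf("'%s'",
                                     gsub("'", "_", phy$tip.label[reserved]))
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
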