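make_classes <- function(genotypes, sizes) {
  # build a genotype_classes object from explicit per-class genotypes
  calls <- do.call(rbind, lapply(seq_along(genotypes), function(i) {
    row <- as.integer(paste0("r", 1:6) %in% genotypes[[i]])
    matrix(rep(row, sizes[i]), nrow = sizes[i], byrow = TRUE)
  }))
  dimnames(calls) <- list(sprintf("c%03d", seq_len(nrow(calls))),
                          paste0("r", 1:6))
  collapse_genotypes(calls)
}

test_that("backbone path follows the most frequent mutation at each level", {
  # linear 3-class chain: one class per bin
  cl <- make_classes(list("r1", c("r1", "r2"), c("r1", "r2", "r3")),
                     c(10, 10, 10))
  bp <- backbone_path(NULL, cl)
  expect_equal(bp$bin, c("early", "mid", "late"))
  expect_equal(bp$n_regions, 1:3)
  # fork: the clade whose newly acquired region has 40 cells wins over 10
  cl2 <- make_classes(list("r1", c("r1", "r2"), c("r1", "r3")),
                      c(20, 40, 10))
  bp2 <- backbone_path(NULL, cl2)
  expect_equal(bp2$acquired, c("r1", "r2"))
  # simulated linear clone tree: recovered order equals acquisition order
  cfg <- sim_config(n_genes = 1500, n_regions = 5, genes_per_region = 100,
                    cells_per_clone = 8, n_control_cells = 10, seed = 41)
  tr <- simulate_truth(cfg)
  cl3 <- collapse_genotypes(tr$genotypes)
  bp3 <- backbone_path(NULL, cl3)
  expect_equal(bp3$acquired,
               sprintf("region_%02d", 1:5))
})

test_that("monotone gene detection uses strictly ordered bin means", {
  cl <- make_classes(list("r1", c("r1", "r2"), c("r1", "r2", "r3")),
                     c(4, 4, 4))
  bp <- backbone_path(NULL, cl)
  cells <- unlist(cl$members[bp$class_id])
  # gene means per bin: g_up 1,5,9 ; g_jump 1,9,5 ; g_flat 5,5,5
  bin_of <- rep(bp$bin, each = 4)
  base <- rbind(g_up = c(1, 5, 9), g_jump = c(1, 9, 5), g_flat = c(5, 5, 5))
  cnt <- base[, match(bin_of, c("early", "mid", "late"))]
  colnames(cnt) <- cells
  m <- expr_matrix(cnt, norm = "cpm", lib_sizes = rep(1e6, length(cells)))
  mg <- monotone_genes(m, bp, cl)
  expect_equal(mg$monotone[mg$gene_id == "g_up"], TRUE)
  expect_equal(mg$monotone[mg$gene_id == "g_jump"], FALSE)
  expect_equal(mg$monotone[mg$gene_id == "g_flat"], FALSE)
  expect_equal(mg$mean_mid[mg$gene_id == "g_jump"], 9)
  expect_equal(mg$sd_early[mg$gene_id == "g_up"], 0)
  mg_dec <- monotone_genes(m, bp, cl, direction = "decreasing")
  expect_false(any(mg_dec$monotone[mg_dec$gene_id == "g_up"]))
})

test_that("null genes pass the strict three-bin ordering at chance rate", {
  cl <- make_classes(list("r1", c("r1", "r2"), c("r1", "r2", "r3")),
                     c(30, 30, 30))
  bp <- backbone_path(NULL, cl)
  cells <- unlist(cl$members[bp$class_id])
  withr::with_seed(55, {
    cnt <- matrix(rpois(3000 * 90, 20), 3000, 90,
                  dimnames = list(sprintf("g%04d", 1:3000), cells))
    m <- expr_matrix(cnt, norm = "cpm", lib_sizes = rep(1e6, 90))
    mg <- monotone_genes(m, bp, cl)
    rate <- mean(mg$monotone)
    se <- sqrt((1 / 6) * (5 / 6) / 3000)
    # strict ordering of 3 exchangeable means: 1/6, shaved by ties
    expect_lt(abs(rate - 1 / 6), 3 * se + 0.01)
  })
})

test_that("dose-response ranking matches a brute-force Spearman oracle", {
  f <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10, 11, 12)
  cnt <- rbind(focal = f,
               copy = f * 3,
               anti = 13 - f,
               g4 = c(4, 4, 2, 8, 1, 3, 9, 2, 5, 7, 1, 6),
               g5 = c(1, 1, 2, 2, 3, 3, 1, 2, 3, 1, 2, 3))
  colnames(cnt) <- paste0("c", 1:12)
  m <- expr_matrix(cnt, norm = "cpm", lib_sizes = rep(1e6, 12))
  dr <- dose_response(m, "focal", tail_quantile = 0.2)
  tab <- dr$table
  for (g in rownames(cnt)) {
    expect_equal(tab$rho[tab$gene_id == g],
                 spearman_brute(cnt[g, ], cnt["focal", ]),
                 tolerance = 1e-12)
  }
  expect_equal(tab$rho[tab$gene_id == "copy"], 1)
  expect_true("copy" %in% dr$positive)
  expect_equal(tab$rho[tab$gene_id == "anti"], -1)
  expect_true("anti" %in% dr$negative)
  expect_equal(dr$set_size, ceiling(0.2 * 5))
})

test_that("dose-response rejects weak or constant focal vectors", {
  cnt <- rbind(gA = rep(5, 12), gB = rep(0, 12))
  colnames(cnt) <- paste0("c", 1:12)
  m <- expr_matrix(cnt, norm = "cpm", lib_sizes = rep(1e6, 12))
  expect_error(dose_response(m, "gB"), "10 cells")
  expect_error(dose_response(m, "gA"), "constant")
})

test_that("the low-expression prefilter applies the 80% / 1 CPM rule", {
  # 10 cells; gene kept unless > 80% of cells sit below 1 CPM
  cnt <- rbind(all_zero = rep(0, 10),
               in_25pct = c(rep(2, 3), rep(0, 7)),      # 70% low: kept
               at_80pct = c(rep(2, 2), rep(0, 8)),      # exactly 80%: kept
               over_80 = c(2, rep(0, 9)))               # 90% low: dropped
  colnames(cnt) <- paste0("c", 1:10)
  m <- expr_matrix(cnt, norm = "cpm", lib_sizes = rep(1e6, 10))
  kept <- de_gene_filter(m)
  expect_setequal(kept, c("in_25pct", "at_80pct"))
  # hand-counted toy: 10 random genes
  withr::with_seed(77, {
    r <- matrix(rexp(100) * 2, 10, 10,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
    mr <- expr_matrix(r, norm = "cpm", lib_sizes = rep(1e6, 10))
    hand <- rownames(r)[apply(r, 1, function(v) sum(v < 1) <= 8)]
    expect_setequal(de_gene_filter(mr), hand)
  })
})

test_that("clone submatrix export partitions cells and preserves counts", {
  calls <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 0), c(0, 0), c(0, 0))
  dimnames(calls) <- list(paste0("c", 1:6), c("rA", "rB"))
  gt <- structure(list(calls = calls, pvals = calls * 0, qvals = calls * 0,
                       alpha = 0.05), class = "genotype_matrix")
  withr::with_seed(3, {
    cnt <- matrix(rpois(30, 8), 5, 6,
                  dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  })
  m <- expr_matrix(cnt)
  ex <- export_clone_submatrices(m, gt, "rA")
  expect_equal(sort(unname(unlist(lapply(ex$matrices, function(x) x$cells)))),
               paste0("c", 1:6))
  expect_equal(ex$matrices$carrier$counts, cnt[, 1:3])
  expect_equal(anyDuplicated(ex$manifest$cell), 0)
  expect_error(export_clone_submatrices(m, gt, "rX"), "unknown region")
  small <- gt
  small$calls[, "rB"] <- c(1, 0, 0, 0, 0, 0)
  expect_warning(export_clone_submatrices(m, small, "rB"), "< 2 cells")
})

test_that("centroid regression classifies by largest coefficient magnitude", {
  withr::with_seed(13, {
    centroids <- matrix(rnorm(80), 20, 4,
                        dimnames = list(paste0("g", 1:20),
                                        c("PN", "NL", "CL", "MES")))
    # cells equal to a centroid (on the log scale) recover that subtype
    lcpm <- pmax(centroids + 5, 0)  # log2(cpm+1) scale, positive
    cnt <- (2^lcpm - 1)             # back to CPM
    m <- expr_matrix(cnt, norm = "cpm", lib_sizes = rep(1e6, 4))
    colnames(m$counts) <- paste0("cell_", colnames(centroids))
    m$cells <- colnames(m$counts)
    names(m$lib_sizes) <- m$cells
    out <- verhaak_classify(m, centroids)
    expect_equal(out$label, colnames(centroids))
    # coefficients match an explicit normal-equations solve
    Xs <- scale(centroids)
    y <- scale(log2(cnt[, 1] + 1))
    beta <- solve(t(Xs) %*% Xs, t(Xs) %*% y)
    expect_equal(unname(as.numeric(out[1, colnames(centroids)])),
                 unname(as.vector(beta)), tolerance = 1e-8)
    # a cell anti-correlated with a centroid still maps to it (|coef| rule)
    anti <- 2^pmax(5 - centroids[, "MES", drop = FALSE], 0) - 1
    colnames(anti) <- "anti"
    m2 <- expr_matrix(anti, norm = "cpm", lib_sizes = 1e6)
    expect_equal(verhaak_classify(m2, centroids)$label, "MES")
    # classification is invariant to positive rescaling of the CPM vector
    m3 <- expr_matrix(cnt * 7, norm = "cpm", lib_sizes = rep(1e6, 4))
    colnames(m3$counts) <- m$cells
    m3$cells <- m$cells
    names(m3$lib_sizes) <- m$cells
    out3 <- verhaak_classify(m3, centroids)
    expect_equal(out3$label, out$label)
    # rank-deficient centroids are rejected
    bad <- centroids
    bad[, 2] <- bad[, 1]
    expect_error(verhaak_classify(m, bad), "rank deficient")
  })
})

test_that("two-module classification requires a strict twofold difference", {
  lc <- rbind(a1 = c(4, 3, 2.0, 1), a2 = c(4, 3, 2.0, 1),
              b1 = c(1, 2, 1.0, 1), b2 = c(1, 2, 1.0, 1))
  cnt <- 2^lc - 1
  colnames(cnt) <- c("cA", "amb1", "amb2", "equal")
  m <- expr_matrix(cnt, norm = "cpm", lib_sizes = rep(1e6, 4))
  out <- sun_classify(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(out$label,
               c("PDGFRA-module", "ambiguous", "ambiguous", "ambiguous"))
  expect_error(sun_classify(m, "missing_gene", c("b1", "b2")), "empty")
})
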