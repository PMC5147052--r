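cpm_fixture <- function(cnt) {
  expr_matrix(cnt, norm = "cpm", lib_sizes = rep(1e6, ncol(cnt)))
}

test_that("region scores sum CPM over in-region genes", {
  cnt <- cbind(c1 = c(100, 300, 7), c2 = c(0, 50, 7))
  rownames(cnt) <- c("gA", "gB", "gC")
  m <- cpm_fixture(cnt)
  regions <- data.frame(region_id = c("r1", "r2"),
                        direction = c("gain", "loss"),
                        genes = c("gA,gB", "gC"))
  sc <- score_regions(m, regions)
  expect_equal(sc$scores["r1", "c1"], 400)
  expect_equal(sc$scores["r2", "c2"], 7)
  # a region whose genes are absent is flagged and excluded from calling
  regions2 <- rbind(regions,
                    data.frame(region_id = "r3", direction = "gain",
                               genes = "gX,gY"))
  expect_warning(sc2 <- score_regions(m, regions2), "no detected genes")
  expect_equal(sc2$flagged, "r3")
  ref <- build_control_reference(
    suppressWarnings(score_regions(cpm_fixture(matrix(
      rep(cnt, 10), nrow = 3, dimnames = list(rownames(cnt), NULL))),
      regions2)))
  expect_message(p <- empirical_pvalues(sc2, ref), "excluding")
  expect_false("r3" %in% colnames(p))
})

test_that("region scores are additive over a partition of the region", {
  withr::with_seed(3, {
    cnt <- matrix(rpois(80, 50), 8, 10,
                  dimnames = list(paste0("g", 1:8), NULL))
    m <- cpm_fixture(cnt)
    parts <- data.frame(region_id = c("p1", "p2"),
                        direction = "gain",
                        genes = c("g1,g2,g3", "g4,g5"))
    whole <- data.frame(region_id = "w", direction = "gain",
                        genes = "g1,g2,g3,g4,g5")
    sp <- score_regions(m, parts)$scores
    sw <- score_regions(m, whole)$scores
    expect_equal(unname(sp["p1", ] + sp["p2", ]), unname(sw["w", ]))
  })
})

test_that("empirical p-values agree with an exhaustive rank-count oracle", {
  # spec example: loss region, cell score 0, 19 controls above 0
  expect_equal(empirical_p(0, seq(1, 19), tail = "lower"), 1 / 20)
  withr::with_seed(7, {
    for (i in 1:20) {
      ref <- round(runif(17, 0, 10), 1)
      x <- round(runif(5, 0, 10), 1)
      expect_equal(empirical_p(x, ref, "upper"),
                   vapply(x, empirical_p_brute, numeric(1), ref = ref,
                          upper = TRUE))
      expect_equal(empirical_p(x, ref, "lower"),
                   vapply(x, empirical_p_brute, numeric(1), ref = ref,
                          upper = FALSE))
    }
    # score at the control median has p near 0.5
    ref <- rnorm(999)
    expect_equal(empirical_p(stats::median(ref), ref, "upper"), 0.5,
                 tolerance = 0.01)
  })
})

test_that("genotype calls follow BH over all cell-by-region tests jointly", {
  p1 <- matrix(0.01, 1, 1, dimnames = list("c1", "r1"))
  gt <- call_genotypes(p1)
  expect_equal(gt$qvals[1, 1], 0.01)
  expect_equal(gt$calls[1, 1], 1L)
  p5 <- matrix(c(0.001, 0.012, 0.03, 0.04, 0.9), 1,
               dimnames = list("c1", paste0("r", 1:5)))
  gt5 <- call_genotypes(p5)
  expect_equal(as.vector(gt5$qvals), bh_brute(as.vector(p5)))
})

test_that("carriers of simulated CNVs are recovered; null cells are not called", {
  cfg <- sim_config(n_genes = 2000, n_regions = 4, genes_per_region = 300,
                    cells_per_clone = 25, n_control_cells = 80, seed = 19)
  tr <- simulate_truth(cfg)
  tum <- simulate_cells(tr)
  ctl <- simulate_controls(cfg)
  gt <- genotype_simulated(tr, tum, ctl)
  # carriers score beyond non-carriers for a gain region (region 3 is a
  # gain acquired mid-chain, so both carrier groups are populated)
  sc <- score_regions(cpm_normalize(tum), region_table(tr))
  carrier <- tr$genotypes[, 3] == 1
  expect_gt(mean(sc$scores[3, carrier]), mean(sc$scores[3, !carrier]))
  expect_gt(mean(gt$calls == tr$genotypes), 0.9)
  # all-null cells tested against an independent control tranche:
  # per-test call rate well below alpha
  gt0 <- call_genotypes(empirical_pvalues(
    score_regions(cpm_normalize(ctl[, 1:40]), region_table(tr)),
    build_control_reference(
      score_regions(cpm_normalize(ctl[, 41:80]), region_table(tr)))))
  expect_lt(mean(gt0$calls), 0.05)
})

test_that("cross-validated false-call rate behaves at the extremes", {
  cfg <- sim_config(n_genes = 1200, n_regions = 4, genes_per_region = 300,
                    cells_per_clone = 5, n_control_cells = 60, seed = 23)
  ctl <- simulate_controls(cfg)
  regions <- region_table(simulate_truth(cfg))
  cv1 <- crossval_fdr(ctl, regions, folds = 5, alpha = 1, seed = 2)
  expect_equal(cv1$per_fold, rep(1, 5))  # everything is called
  cv2 <- crossval_fdr(ctl, regions, folds = 5, seed = 2)
  cv3 <- crossval_fdr(ctl, regions, folds = 5, seed = 2)
  expect_identical(cv2, cv3)
  expect_true(all(cv2$per_fold <= 0.05))
  expect_error(crossval_fdr(ctl[, 1:8], regions, folds = 5), "at least")
})

test_that("smoothed ratio tracks are flat for control-like cells and elevated over gains", {
  cfg <- sim_config(n_genes = 1500, n_regions = 2, genes_per_region = 300,
                    clone_tree = list(parent = c(0L, 1L),
                                      regions = list(integer(0), 1L)),
                    cells_per_clone = 40, n_control_cells = 60,
                    base_mean = 5, region_directions = c("gain", "loss"),
                    seed = 29)
  tr <- simulate_truth(cfg)
  tum0 <- simulate_cells(tr)
  ctl0 <- simulate_controls(cfg)
  tum <- cpm_normalize(tum0)
  ctl <- cpm_normalize(ctl0)
  # a pseudo-cell equal to the control median gives an all-zero track
  med <- apply(ctl$counts, 1, stats::median)
  mcell <- expr_matrix(cbind(m = med), genes = ctl$genes, norm = "cpm",
                       lib_sizes = 1e6)
  flat <- wavelet_smooth_track(mcell, ctl)
  expect_true(all(abs(flat$track) < 1e-12))
  # carriers of the gain show an elevated plateau over the region block
  wt <- wavelet_smooth_track(tum, ctl)
  in_reg <- wt$genes$gene_id %in%
    sprintf("gene_%04d", tr$region_gene_map[[1]])
  carrier <- colnames(wt$track) %in% names(tr$clone)[tr$clone == 2]
  lift <- mean(wt$track[in_reg, carrier]) - mean(wt$track[!in_reg, carrier])
  expect_gt(lift, 0.3)
  # presence/absence triage is unaffected by the smoothing: classifying
  # cells by their mean in-region track (split at the cohort mean) agrees
  # between the smoothed and raw tracks, and with the genotyper calls
  raw <- wavelet_smooth_track(tum, ctl, smooth = FALSE)
  tcs <- colMeans(wt$track[in_reg, ])
  tcr <- colMeans(raw$track[in_reg, ])
  call_sm <- tcs > mean(tcs)
  call_raw <- tcr > mean(tcr)
  gt <- genotype_simulated(tr, tum0, ctl0)
  expect_gt(mean(call_sm == call_raw), 0.95)
  expect_gt(mean(call_sm == (gt$calls[names(tcs), 1] == 1)), 0.95)
})

test_that("stromal triage combines genotype, mutation and clustering evidence", {
  # cells with CNV calls are tumor regardless of clustering
  calls <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3, byrow = TRUE,
                  dimnames = list(c("c1", "c2"), paste0("r", 1:3)))
  gt <- structure(list(calls = calls, pvals = calls * 0, qvals = calls * 0,
                       alpha = 0.05), class = "genotype_matrix")
  cnt <- matrix(rpois(20, 10), 10, 2, dimnames = list(paste0("g", 1:10),
                                                      c("c1", "c2")))
  m <- expr_matrix(cnt)
  out <- suppressWarnings(flag_stromal(gt, NULL, m, character(0)))
  expect_equal(out$label, c("tumor", "putative-stromal"))
  # mutation evidence alone blocks the stromal call
  out2 <- suppressWarnings(
    flag_stromal(gt, c(c2 = 3), m, character(0)))
  expect_equal(out2$label[2], "tumor")
})

test_that("spiked-in control cells are recovered as stromal", {
  withr::with_seed(31, {
    cfg <- sim_config(n_genes = 2000, n_regions = 3,
                      genes_per_region = 300, cells_per_clone = 30,
                      n_control_cells = 120,
                      region_directions = rep("gain", 3), seed = 31)
    tr <- simulate_truth(cfg)
    tum <- simulate_cells(tr)
    ctl <- simulate_controls(cfg)
    # spiked-in normal cells carry a shared marker program, as real
    # stromal (immune / oligodendrocyte) cells do
    spike <- ctl[, 101:120]
    colnames(spike$counts) <- sprintf("spike_%02d", 1:20)
    markers <- sprintf("gene_%04d", 1901:2000)
    spike$counts[markers, ] <- spike$counts[markers, ] + rpois(100, 20)
    mixed <- expr_matrix(cbind(tum$counts, spike$counts), genes = tum$genes)
    ref <- ctl[, 1:100]
    regions <- region_table(tr)
    gt <- call_genotypes(empirical_pvalues(
      score_regions(cpm_normalize(mixed), regions),
      build_control_reference(score_regions(cpm_normalize(ref), regions))))
    # clustering panel spans the marker program and the dosage-affected
    # genes, so both populations are coherent
    panel <- c(markers, sprintf("gene_%04d", unlist(tr$region_gene_map)))
    out <- flag_stromal(gt, NULL, cpm_normalize(mixed), panel)
    is_spike <- grepl("^spike", out$cell)
    expect_gt(mean(out$label[is_spike] == "putative-stromal"), 0.8)
    expect_gt(mean(out$label[!is_spike] == "tumor"), 0.9)
    # degenerate case: all-zero genotypes make every cell putative stromal
    gt0 <- gt
    gt0$calls[] <- 0L
    out0 <- flag_stromal(gt0, NULL, cpm_normalize(mixed), panel)
    expect_true(all(out0$label == "putative-stromal"))
  })
})
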