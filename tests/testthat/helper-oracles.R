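# Brute-force oracles, kept deliberately independent of the package's
# implementation paths.

# textbook BH step-up: sort ascending, q_(i) = min_{j >= i} m p_(j) / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- pmin(1, p[o] * m / seq_len(m))
  if (m > 1) {
    for (i in seq(m - 1, 1)) qs[i] <- min(qs[i], qs[i + 1])
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# average ranks by explicit counting
rank_brute <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

# Spearman rho as Pearson correlation of brute-force ranks
spearman_brute <- function(x, y) {
  rx <- rank_brute(x)
  ry <- rank_brute(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# add-one empirical tail p by explicit counting
empirical_p_brute <- function(x, ref, upper = TRUE) {
  cnt <- if (upper) sum(ref >= x) else sum(ref <= x)
  (cnt + 1) / (length(ref) + 1)
}

# Lorenz curve by explicit loop on a sorted copy
lorenz_brute <- function(v) {
  s <- sort(v)
  out <- numeric(length(v))
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    out[i] <- acc / sum(v)
  }
  out
}

# small deterministic expression fixture; counts chosen by hand
toy_matrix <- function() {
  cnt <- matrix(c(10, 0, 5,
                  20, 0, 5,
                  30, 0, 0,
                  40, 8, 0), 4, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  expr_matrix(cnt)
}

# region table in gene-list form from a simulation truth
region_table <- function(truth) {
  data.frame(
    region_id = names(truth$region_gene_map),
    direction = truth$region_directions,
    genes = vapply(truth$region_gene_map, function(i) {
      paste(sprintf("gene_%04d", i), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
}

# genotype calls straight from simulated data, one call
genotype_simulated <- function(truth, tumor, controls, alpha = 0.05) {
  regions <- region_table(truth)
  sc_t <- score_regions(cpm_normalize(tumor), regions)
  sc_c <- score_regions(cpm_normalize(controls), regions)
  call_genotypes(empirical_pvalues(sc_t, build_control_reference(sc_c)),
                 alpha = alpha)
}
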