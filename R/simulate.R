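#' Simulation configuration for a clonal CNV study
#'
#' Bundles the parameters of the synthetic study: a clone tree whose clones
#' sequentially acquire copy-number regions, negative-binomial count noise,
#' log-normal library-size variation, and a CNV-free control population.
#' Defaults describe a mid-size tumour biopsy profiled at modest depth:
#' regions of 300 contiguous genes (large CNVs span hundreds of genes),
#' a 1.5x expression dose for a single-copy gain and 0.5x for a
#' single-copy loss (expression linear in copy number), mean 0.5 counts
#' per gene per cell and NB size 2.
#'
#' @param n_genes total number of genes in the universe.
#' @param n_regions number of CNV regions; regions are disjoint, contiguous
#'   gene blocks laid out from gene 1 upward.
#' @param genes_per_region genes per region (default 300).
#' @param clone_tree list with `parent` (integer vector, 0 = attached to
#'   the CNV-free ancestor) and `regions` (list of integer vectors: the
#'   *cumulative* set of regions acquired by each clone). A child's set
#'   must contain its parent's. Default: a linear chain of `n_regions`
#'   clones, clone k having acquired regions `1:k`.
#' @param cells_per_clone tumour cells sampled per clone.
#' @param n_control_cells cells in the CNV-free control population.
#' @param base_mean expected raw count per gene per cell at copy number 2.
#' @param nb_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed); `Inf` gives Poisson counts.
#' @param dosage_gain_factor mean multiplier for genes in a gained region.
#' @param dosage_loss_factor mean multiplier for genes in a lost region.
#' @param libsize_sigma standard deviation of log library-size factors
#'   (log-normal, unit mean).
#' @param region_directions character vector (`"gain"`/`"loss"`) per
#'   region; default alternates gain, loss, gain, ...
#' @param focal_gene optional gene index designated as a focal transcript
#'   (e.g. a receptor deletion mutant) with its own per-clone dose.
#' @param focal_dose per-clone multiplier for `focal_gene`'s mean
#'   (length = number of clones); default ramps linearly 1 .. 3.
#' @param seed RNG seed; every generator draws from a stream derived from
#'   it, so equal configs give identical data.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 8000, n_regions = 10, genes_per_region = 300,
                       clone_tree = NULL, cells_per_clone = 20,
                       n_control_cells = 200, base_mean = 0.5,
                       nb_dispersion = 2, dosage_gain_factor = 1.5,
                       dosage_loss_factor = 0.5, libsize_sigma = 0.2,
                       region_directions = NULL, focal_gene = NULL,
                       focal_dose = NULL, seed = 1) {
  if (is.null(clone_tree)) {
    clone_tree <- list(parent = c(0L, seq_len(max(n_regions - 1L, 0L))),
                       regions = lapply(seq_len(n_regions), seq_len))
    if (n_regions == 0L) {
      clone_tree <- list(parent = 0L, regions = list(integer(0)))
    }
  }
  if (is.null(region_directions)) {
    region_directions <- rep(c("gain", "loss"), length.out = n_regions)
  }
  cfg <- structure(list(n_genes = as.integer(n_genes),
                        n_regions = as.integer(n_regions),
                        genes_per_region = as.integer(genes_per_region),
                        clone_tree = clone_tree,
                        cells_per_clone = as.integer(cells_per_clone),
                        n_control_cells = as.integer(n_control_cells),
                        base_mean = base_mean, nb_dispersion = nb_dispersion,
                        dosage_gain_factor = dosage_gain_factor,
                        dosage_loss_factor = dosage_loss_factor,
                        libsize_sigma = libsize_sigma,
                        region_directions = region_directions,
                        focal_gene = focal_gene, focal_dose = focal_dose,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_genes > 0, n_regions >= 0, genes_per_region > 0,
              cells_per_clone > 0, n_control_cells > 0, base_mean > 0,
              nb_dispersion > 0, dosage_gain_factor > 0,
              dosage_loss_factor > 0, libsize_sigma >= 0)
    if (n_regions * genes_per_region > n_genes) {
      stop("n_regions * genes_per_region exceeds n_genes")
    }
    if (length(region_directions) != n_regions ||
        !all(region_directions %in% c("gain", "loss"))) {
      stop("region_directions must be 'gain'/'loss', one per region")
    }
    k <- length(clone_tree$regions)
    if (length(clone_tree$parent) != k) {
      stop("clone_tree$parent and clone_tree$regions lengths differ")
    }
    for (i in seq_len(k)) {
      r <- clone_tree$regions[[i]]
      if (length(r) && (any(r < 1) || any(r > n_regions))) {
        stop("clone ", i, " acquires an unknown region")
      }
      p <- clone_tree$parent[i]
      if (p > 0 && !all(clone_tree$regions[[p]] %in% r)) {
        stop("clone_tree is not nested: clone ", i,
             " lacks regions acquired by its parent ", p)
      }
    }
    if (!is.null(focal_dose) && length(focal_dose) != k) {
      stop("focal_dose must give one multiplier per clone")
    }
  })
  invisible(cfg)
}

#' Ground-truth genotypes implied by a simulation config
#'
#' Expands the clone tree into a per-cell binary genotype matrix, the
#' region-to-gene map (contiguous disjoint blocks), and the per-cell focal
#' transcript dose, without drawing any counts.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`: list with `genotypes` (cells x
#'   regions 0/1 matrix), `clone` (per-cell clone index), `region_gene_map`
#'   (list of gene-index vectors), `region_directions`,
#'   `focal_gene_profile` (per-cell expected focal dose, or `NULL`) and the
#'   originating `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  k <- length(config$clone_tree$regions)
  n_cells <- k * config$cells_per_clone
  clone <- rep(seq_len(k), each = config$cells_per_clone)
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  gt <- matrix(0L, n_cells, config$n_regions,
               dimnames = list(cells, region_ids(config$n_regions)))
  for (i in seq_len(n_cells)) {
    gt[i, config$clone_tree$regions[[clone[i]]]] <- 1L
  }
  rgm <- lapply(seq_len(config$n_regions), function(r) {
    ((r - 1L) * config$genes_per_region + 1L):(r * config$genes_per_region)
  })
  names(rgm) <- region_ids(config$n_regions)
  focal <- NULL
  if (!is.null(config$focal_gene)) {
    dose <- config$focal_dose %||% seq(1, 3, length.out = k)
    focal <- stats::setNames(dose[clone], cells)
  }
  structure(list(genotypes = gt, clone = stats::setNames(clone, cells),
                 region_gene_map = rgm,
                 region_directions = config$region_directions,
                 focal_gene_profile = focal, config = config),
            class = "sim_truth")
}

region_ids <- function(n) sprintf("region_%02d", seq_len(n))

# genes x cells matrix of expected counts (before library-size factors)
expected_means <- function(truth, config) {
  g <- config$n_genes
  cells <- rownames(truth$genotypes)
  mu <- matrix(config$base_mean, g, length(cells),
               dimnames = list(sprintf("gene_%04d", seq_len(g)), cells))
  for (r in seq_len(config$n_regions)) {
    fac <- if (truth$region_directions[r] == "gain") {
      config$dosage_gain_factor
    } else {
      config$dosage_loss_factor
    }
    carriers <- truth$genotypes[, r] == 1L
    if (any(carriers)) {
      mu[truth$region_gene_map[[r]], carriers] <-
        mu[truth$region_gene_map[[r]], carriers] * fac
    }
  }
  if (!is.null(truth$focal_gene_profile)) {
    mu[config$focal_gene, ] <- config$base_mean * truth$focal_gene_profile
  }
  mu
}

draw_nb_matrix <- function(mu, size, libsize_sigma) {
  lf <- exp(stats::rnorm(ncol(mu), -libsize_sigma^2 / 2, libsize_sigma))
  mu <- sweep(mu, 2, lf, `*`)
  cnt <- if (is.finite(size)) {
    stats::rnbinom(length(mu), size = size, mu = as.vector(mu))
  } else {
    stats::rpois(length(mu), as.vector(mu))
  }
  matrix(cnt, nrow(mu), ncol(mu), dimnames = dimnames(mu))
}

sim_gene_table <- function(config) {
  g <- config$n_genes
  # one synthetic chromosome per region plus one holding the remainder,
  # 10 kb per gene, so genomic ordering equals gene-index ordering
  chrom <- rep("chrUnassigned", g)
  for (r in seq_len(config$n_regions)) {
    idx <- ((r - 1L) * config$genes_per_region + 1L):(r * config$genes_per_region)
    chrom[idx] <- sprintf("chr%d", r)
  }
  data.frame(gene_id = sprintf("gene_%04d", seq_len(g)),
             chrom = chrom,
             start = (seq_len(g) - 1L) * 10000L,
             end = seq_len(g) * 10000L - 1000L,
             stringsAsFactors = FALSE)
}

#' Simulate tumour-cell counts under a clone tree
#'
#' Draws a genes x cells raw count matrix: counts are negative-binomial
#' with mean `base_mean` times the dosage factor of the cell's copy state
#' for the gene's region times a log-normal per-cell library factor. Genes
#' outside every region are unaffected by genotype.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the same [sim_config()].
#' @return raw [expr_matrix] with genomic gene annotation (each region on
#'   its own synthetic chromosome, genes in genomic order).
#' @export
simulate_cells <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  mu <- expected_means(truth, config)
  cnt <- local_seed(config$seed, draw_nb_matrix(mu, config$nb_dispersion,
                                                config$libsize_sigma))
  expr_matrix(cnt, genes = sim_gene_table(config))
}

#' Simulate CNV-free control cells
#'
#' Same generative law as [simulate_cells()] with an all-normal (copy 2)
#' genotype and the same gene universe; stands in for a non-malignant
#' control population.
#'
#' @param config a [sim_config()] (`n_control_cells >= 2`).
#' @return raw [expr_matrix] of control cells.
#' @export
simulate_controls <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_control_cells >= 2)
  mu <- matrix(config$base_mean, config$n_genes, config$n_control_cells,
               dimnames = list(sprintf("gene_%04d", seq_len(config$n_genes)),
                               sprintf("ctrl_%03d",
                                       seq_len(config$n_control_cells))))
  cnt <- local_seed(config$seed + 1L,
                    draw_nb_matrix(mu, config$nb_dispersion,
                                   config$libsize_sigma))
  expr_matrix(cnt, genes = sim_gene_table(config))
}

#' Simulate per-exon coverage with and without focal exon depletion
#'
#' Emulates exon-level read counts of one gene across a tumour cohort and
#' a blood-control cohort. Controls (and non-depleted tumours) have full
#' coverage of all exons; a `depleted_fraction` of tumours have their
#' target-exon counts suppressed by `suppression` (partial suppression
#' models heterozygous/subclonal deletions).
#'
#' @param n_exons number of exons (default 23, a typical receptor gene).
#' @param target_exons integer indices of the exons deleted in carriers.
#' @param n_tumor,n_control cohort sizes.
#' @param depleted_fraction proportion of tumours truly depleted.
#' @param depth expected reads per exon.
#' @param suppression multiplier applied to target-exon means in depleted
#'   tumours (0 = complete loss; default 0.02, a strong suppression).
#' @param dispersion NB size for exon counts; `Inf` (default) = Poisson.
#' @param seed RNG seed.
#' @return list with `profiles` (long data.frame: `sample`, `cohort`,
#'   `exon`, `count`) and `truth` (data.frame: `sample`, `depleted`).
#' @export
simulate_exon_coverage <- function(n_exons = 23, target_exons = c(8, 9),
                                   n_tumor = 100, n_control = 50,
                                   depleted_fraction = 0.16, depth = 200,
                                   suppression = 0.02, dispersion = Inf,
                                   seed = 1) {
  if (!length(target_exons)) stop("target_exons must be non-empty")
  if (any(target_exons < 1) || any(target_exons > n_exons)) {
    stop("target_exons outside 1..n_exons")
  }
  stopifnot(depleted_fraction >= 0, depleted_fraction <= 1, n_exons >= 2)
  local_seed(seed, {
    n_dep <- round(n_tumor * depleted_fraction)
    depleted <- c(rep(TRUE, n_dep), rep(FALSE, n_tumor - n_dep))
    draw <- function(mu_mat) {
      cnt <- if (is.finite(dispersion)) {
        stats::rnbinom(length(mu_mat), size = dispersion,
                       mu = as.vector(mu_mat))
      } else {
        stats::rpois(length(mu_mat), as.vector(mu_mat))
      }
      matrix(cnt, nrow(mu_mat), ncol(mu_mat))
    }
    mu_t <- matrix(depth, n_exons, n_tumor)
    mu_t[target_exons, depleted] <- depth * suppression
    tum <- draw(mu_t)
    ctl <- draw(matrix(depth, n_exons, n_control))
    t_ids <- sprintf("tumor_%03d", seq_len(n_tumor))
    c_ids <- sprintf("blood_%03d", seq_len(n_control))
    profiles <- rbind(
      data.frame(sample = rep(t_ids, each = n_exons), cohort = "tumor",
                 exon = rep(seq_len(n_exons), n_tumor),
                 count = as.vector(tum), stringsAsFactors = FALSE),
      data.frame(sample = rep(c_ids, each = n_exons), cohort = "control",
                 exon = rep(seq_len(n_exons), n_control),
                 count = as.vector(ctl), stringsAsFactors = FALSE))
    list(profiles = profiles,
         truth = data.frame(sample = t_ids, depleted = depleted,
                            stringsAsFactors = FALSE))
  })
}
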