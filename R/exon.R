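#' Fraction of a gene's reads mapping to target exons
#'
#' @param counts per-exon read counts of one gene in one sample (vector,
#'   exon order 1..E).
#' @param target_exons integer indices of the exons of interest.
#' @return sum of target-exon counts over all exon counts; `NA` (with a
#'   warning) when the sample has zero reads on the gene.
#' @examples
#' exon_fraction(rep(10, 23), c(8, 9))  # 2/23
#' @export
exon_fraction <- function(counts, target_exons) {
  stopifnot(length(counts) >= 2, all(counts >= 0))
  if (any(target_exons < 1) || any(target_exons > length(counts))) {
    stop("target_exons outside exon range")
  }
  tot <- sum(counts)
  if (tot == 0) {
    warning("zero total reads; fraction undefined")
    return(NA_real_)
  }
  sum(counts[target_exons]) / tot
}

# long profile table -> per-sample fractions
exon_fractions <- function(profiles, target_exons) {
  stopifnot(all(c("sample", "cohort", "exon", "count") %in% names(profiles)))
  samples <- unique(profiles$sample)
  frac <- vapply(samples, function(s) {
    p <- profiles[profiles$sample == s, ]
    suppressWarnings(exon_fraction(p$count[order(p$exon)], target_exons))
  }, numeric(1))
  cohort <- profiles$cohort[match(samples, profiles$sample)]
  data.frame(sample = samples, cohort = cohort, exon_fraction = frac,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test tumour samples for focal exon depletion
#'
#' Compares each tumour's target-exon read fraction against the
#' distribution over blood controls: lower-tail add-one empirical
#' p-values, Benjamini-Hochberg correction across tumours, significance
#' at adjusted p below `alpha` (default 0.25, the conventional CNV
#' threshold in large-cohort work). The fixed-threshold variant — tumour
#' fraction below the controls' 10th percentile — is reported alongside.
#'
#' @param profiles long data.frame (`sample`, `cohort`, `exon`, `count`)
#'   as from [simulate_exon_coverage()], with cohorts `"tumor"` and
#'   `"control"`.
#' @param target_exons exon indices tested for depletion.
#' @param alpha adjusted-p significance threshold.
#' @param ctrl_quantile control quantile for the fixed-threshold call.
#' @return object of class `depletion_calls`: data.frame with `sample`,
#'   `exon_fraction`, `pval`, `qval`, `significant`,
#'   `below_ctrl_quantile`; attributes `prevalence_bh`,
#'   `prevalence_threshold`, `n_controls`, `ctrl_threshold`.
#' @export
depletion_test <- function(profiles, target_exons, alpha = 0.25,
                           ctrl_quantile = 0.1) {
  fr <- exon_fractions(profiles, target_exons)
  ctrl <- fr$exon_fraction[fr$cohort == "control"]
  dropped <- sum(is.na(ctrl))
  if (dropped) {
    warning(dropped, " control sample(s) with undefined fraction dropped")
    ctrl <- ctrl[!is.na(ctrl)]
  }
  if (length(ctrl) < 10) stop("need at least 10 usable control profiles")
  tum <- fr[fr$cohort == "tumor", , drop = FALSE]
  ok <- !is.na(tum$exon_fraction)
  if (any(!ok)) {
    warning(sum(!ok), " tumour sample(s) with undefined fraction excluded")
  }
  p <- rep(NA_real_, nrow(tum))
  p[ok] <- empirical_p(tum$exon_fraction[ok], ctrl, tail = "lower")
  q <- rep(NA_real_, nrow(tum))
  q[ok] <- bh_adjust(p[ok])
  thr <- stats::quantile(ctrl, ctrl_quantile, names = FALSE)
  out <- data.frame(sample = tum$sample,
                    exon_fraction = tum$exon_fraction,
                    pval = p, qval = q,
                    significant = !is.na(q) & q < alpha,
                    below_ctrl_quantile = !is.na(tum$exon_fraction) &
                      tum$exon_fraction < thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("depletion_calls", "data.frame")
  attr(out, "prevalence_bh") <- mean(out$significant[ok])
  attr(out, "prevalence_threshold") <- mean(out$below_ctrl_quantile[ok])
  attr(out, "n_controls") <- length(ctrl)
  attr(out, "ctrl_threshold") <- thr
  out
}

#' Three-way co-occurrence of receptor lesions across a cohort
#'
#' Counts every region of the three-set Venn diagram of samples carrying
#' an amplification, a focal exon depletion, and a small intragenic
#' deletion, and reports containment relations (e.g. whether every small
#' deletion occurred in an amplified sample).
#'
#' @param depletion_calls,amplification_calls,small_deletion_calls
#'   character vectors of sample ids (duplicate ids are an error).
#' @param universe optional full cohort; defaults to the union of the
#'   three sets. Sets must be subsets of it.
#' @return list with `counts` (named 7-region Venn counts plus `none`
#'   when a universe is given), `n`, and `nesting` (logical containment
#'   flags).
#' @export
cooccurrence_report <- function(depletion_calls, amplification_calls,
                                small_deletion_calls, universe = NULL) {
  sets <- list(depletion = depletion_calls,
               amplification = amplification_calls,
               small_deletion = small_deletion_calls)
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]])) {
      stop("duplicate sample ids in ", nm, " set")
    }
  }
  universe <- universe %||% unique(unlist(sets))
  if (anyDuplicated(universe)) stop("duplicate sample ids in universe")
  bad <- unlist(lapply(sets, setdiff, y = universe))
  if (length(bad)) {
    stop("sample id(s) outside the universe: ", paste(bad, collapse = ", "))
  }
  inA <- universe %in% sets$depletion
  inB <- universe %in% sets$amplification
  inC <- universe %in% sets$small_deletion
  counts <- c(
    depletion_only = sum(inA & !inB & !inC),
    amplification_only = sum(!inA & inB & !inC),
    small_deletion_only = sum(!inA & !inB & inC),
    depletion_amplification = sum(inA & inB & !inC),
    depletion_small_deletion = sum(inA & !inB & inC),
    amplification_small_deletion = sum(!inA & inB & inC),
    all_three = sum(inA & inB & inC),
    none = sum(!inA & !inB & !inC))
  nesting <- c(
    small_deletion_in_amplification =
      all(sets$small_deletion %in% sets$amplification),
    small_deletion_in_depletion =
      all(sets$small_deletion %in% sets$depletion),
    depletion_in_amplification =
      all(sets$depletion %in% sets$amplification))
  list(counts = counts, n = length(universe), nesting = nesting)
}
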