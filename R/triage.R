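#' Post-caller triage of somatic SNV candidates
#'
#' Applies the exclusion rules used downstream of a somatic SNV caller on
#' a tumour / matched-normal pair. A record is excluded when its tumour
#' VAF is below 10%, the matched normal has more than five variant reads
#' or a VAF above 10%, or the annotation is neither protein-coding nor
#' splice-site; exclusions are strict, so boundary records (exactly 10%
#' VAF, exactly five normal reads) are retained.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `tumor_vaf`, `normal_variant_reads`, `normal_vaf`, `annotation`.
#' @return the input with two added columns: logical `retained` and
#'   `reason` (the first failing rule, `NA` for retained records).
#' @export
filter_snvs <- function(records) {
  need <- c("tumor_vaf", "normal_variant_reads", "normal_vaf", "annotation")
  check_fields(records, need, "SNV")
  stopifnot(all(records$tumor_vaf >= 0 & records$tumor_vaf <= 1),
            all(records$normal_vaf >= 0 & records$normal_vaf <= 1),
            all(records$normal_variant_reads >= 0))
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$tumor_vaf < 0.10] <- "tumor_vaf_low"
  reason[is.na(reason) & records$normal_variant_reads > 5] <- "normal_variant_reads"
  reason[is.na(reason) & records$normal_vaf > 0.10] <- "normal_vaf_high"
  reason[is.na(reason) &
           !records$annotation %in% c("protein-coding", "splice-site")] <-
    "non_coding"
  records$retained <- is.na(reason)
  records$reason <- reason
  records
}

#' Post-caller triage of small indel candidates
#'
#' Excludes indels with fewer than six supporting reads in the tumour, any
#' supporting reads in the matched normal, fewer than 14 total reads in
#' the normal, replacements whose deleted and inserted sequences have
#' equal length, and non-coding annotations. Exclusions are strict;
#' boundary records are retained.
#'
#' @param records data.frame with columns `chrom`, `pos`, `type`
#'   (`deletion`/`insertion`/`replacement`), `tumor_support_reads`,
#'   `normal_support_reads`, `normal_total_reads`, `deletion_len`,
#'   `inserted_len`, `annotation`.
#' @return the input plus `retained` and `reason` columns.
#' @export
filter_indels <- function(records) {
  need <- c("type", "tumor_support_reads", "normal_support_reads",
            "normal_total_reads", "deletion_len", "inserted_len",
            "annotation")
  check_fields(records, need, "indel")
  stopifnot(all(records$deletion_len >= 0), all(records$inserted_len >= 0),
            all(records$normal_support_reads <= records$normal_total_reads))
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$tumor_support_reads < 6] <- "tumor_support_low"
  reason[is.na(reason) & records$normal_support_reads > 0] <- "normal_support"
  reason[is.na(reason) & records$normal_total_reads < 14] <- "normal_depth_low"
  reason[is.na(reason) & records$type == "replacement" &
           records$deletion_len == records$inserted_len] <-
    "same_length_replacement"
  reason[is.na(reason) &
           !records$annotation %in% c("protein-coding", "splice-site")] <-
    "non_coding"
  records$retained <- is.na(reason)
  records$reason <- reason
  records
}

check_fields <- function(records, need, what) {
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(what, " table missing field(s): ", paste(miss, collapse = ", "))
  }
  for (f in need) {
    if (anyNA(records[[f]])) {
      stop(what, " record ", which(is.na(records[[f]]))[1],
           " has missing '", f, "'")
    }
  }
  invisible(TRUE)
}

#' Merge, size-filter and classify bulk CNV segments
#'
#' Post-processes a BED-like table of copy-number segments from a bulk
#' caller: (1) directions are assigned from the tumour/control read-count
#' ratio (gain above `gain_ratio`, loss below `loss_ratio`; segments in
#' between are dropped as neutral); (2) proximal same-direction segments
#' on one chromosome (gap below `merge_gap`) are merged — exon counts
#' summed, gene lists unioned, ratio the exon-count-weighted mean; (3)
#' merged segments with `n_exons <= min_exons` are dropped ("more than
#' `min_exons` exons" is strict).
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `n_exons`, `ratio`, and optionally `genes`
#'   (comma-separated identifiers).
#' @param min_exons retain only segments with more exons than this.
#' @param merge_gap merge same-direction segments closer than this (bp).
#' @param gain_ratio,loss_ratio ratio thresholds for gain/loss calls.
#' @return list with `segments` (retained, merged segments with
#'   `region_id`, `direction`) and `dropped` (input rows with a `reason`).
#' @export
triage_cnv_segments <- function(segments, min_exons = 100, merge_gap = 1e6,
                                gain_ratio = 1.3, loss_ratio = 0.7) {
  need <- c("chrom", "start", "end", "n_exons", "ratio")
  check_fields(segments, need, "CNV segment")
  stopifnot(all(segments$end > segments$start))
  if (!"genes" %in% names(segments)) segments$genes <- ""
  segments$direction <- ifelse(segments$ratio > gain_ratio, "gain",
                               ifelse(segments$ratio < loss_ratio, "loss",
                                      "neutral"))
  dropped <- list()
  neutral <- segments$direction == "neutral"
  if (any(neutral)) {
    d <- segments[neutral, , drop = FALSE]
    d$reason <- "neutral_ratio"
    dropped <- c(dropped, list(d))
  }
  seg <- segments[!neutral, , drop = FALSE]
  merged <- list()
  if (nrow(seg)) {
    for (chr in unique(seg$chrom)) {
      s <- seg[seg$chrom == chr, , drop = FALSE]
      s <- s[order(s$start, s$end), , drop = FALSE]
      # mixed-direction overlap is uninterpretable
      if (nrow(s) > 1) {
        for (i in seq_len(nrow(s) - 1)) {
          ov <- s$end[i] > s$start[i + 1]
          if (ov && s$direction[i] != s$direction[i + 1]) {
            stop("overlapping segments of opposite direction on ", chr)
          }
        }
      }
      for (dir in unique(s$direction)) {
        sd <- s[s$direction == dir, , drop = FALSE]
        cur <- sd[1, , drop = FALSE]
        for (i in seq_len(nrow(sd))[-1]) {
          gap <- sd$start[i] - cur$end
          if (gap < 0) {
            warning("merging overlapping same-direction segments on ", chr)
          }
          if (gap < merge_gap) {
            w <- c(cur$n_exons, sd$n_exons[i])
            cur$ratio <- sum(w * c(cur$ratio, sd$ratio[i])) / sum(w)
            cur$end <- max(cur$end, sd$end[i])
            cur$n_exons <- sum(w)
            gl <- union(split_genes(cur$genes), split_genes(sd$genes[i]))
            cur$genes <- paste(gl, collapse = ",")
          } else {
            merged <- c(merged, list(cur))
            cur <- sd[i, , drop = FALSE]
          }
        }
        merged <- c(merged, list(cur))
      }
    }
  }
  out <- if (length(merged)) do.call(rbind, merged) else seg[0, , drop = FALSE]
  small <- out$n_exons <= min_exons
  if (any(small)) {
    d <- out[small, , drop = FALSE]
    d$reason <- "too_few_exons"
    dropped <- c(dropped, list(d))
  }
  out <- out[!small, , drop = FALSE]
  # re-derive direction from the merged ratio; drop if it went neutral
  if (nrow(out)) {
    out$direction <- ifelse(out$ratio > gain_ratio, "gain",
                            ifelse(out$ratio < loss_ratio, "loss", "neutral"))
    neu <- out$direction == "neutral"
    if (any(neu)) {
      d <- out[neu, , drop = FALSE]
      d$reason <- "neutral_after_merge"
      dropped <- c(dropped, list(d))
      out <- out[!neu, , drop = FALSE]
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  if (nrow(out)) {
    out$region_id <- sprintf("%s:%d-%d_%s", out$chrom, out$start, out$end,
                             out$direction)
  } else {
    out$region_id <- character(0)
  }
  rownames(out) <- NULL
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    cbind(segments[0, , drop = FALSE], reason = character(0))
  rownames(dropped) <- NULL
  list(segments = out, dropped = dropped)
}

split_genes <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",")[[1]]
}
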