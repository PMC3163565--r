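#' Accuracy statistics: MPE, error fraction, false positive rate
#'
#' Compares estimated against true abundances using the standard triple:
#' the **median percent error** (MPE) of entries with positive truth, the
#' **error fraction** (EF; fraction of those entries with percent error
#' above `ef_threshold`), and the **false positive rate** (FP; fraction of
#' entries with true abundance below `fp_cutoff` that are estimated at or
#' above it).  Percent error is `100 |est - true| / true`; entries with
#' zero truth contribute only to FP.
#'
#' @param est,truth aligned non-negative abundance vectors (any common
#'   scale for MPE/EF; the TPM scale for the `fp_cutoff` to mean 1 TPM).
#' @param ef_threshold percent-error threshold of the EF statistic.
#' @param fp_cutoff abundance cutoff of the FP statistic.
#' @return data frame row with columns `mpe`, `ef`, `fp` (in percent;
#'   `NA` when a statistic's eligible set is empty).
#' @export
accuracy_stats <- function(est, truth, ef_threshold = 10, fp_cutoff = 1) {
  stopifnot(length(est) == length(truth), all(truth >= 0))
  pos <- truth > 0
  if (any(pos)) {
    pe <- 100 * abs(est[pos] - truth[pos]) / truth[pos]
    mpe <- median(pe)
    ef <- 100 * mean(pe > ef_threshold)
  } else {
    mpe <- ef <- NA_real_
  }
  low <- truth < fp_cutoff
  fp <- if (any(low)) 100 * mean(est[low] >= fp_cutoff) else NA_real_
  data.frame(mpe = mpe, ef = ef, fp = fp)
}

#' Three-level accuracy report
#'
#' Evaluates estimated transcript fractions against truth at the three
#' customary levels: gene relative abundances, global isoform relative
#' abundances, and within-gene isoform relative abundances (genes with
#' positive true abundance and at least two isoforms).  Fractions are
#' scaled by 1e6 per level so the FP cutoff reads as 1 TPM.
#'
#' @param est_tau,truth_tau transcript fraction vectors in transcript-set
#'   order.
#' @param gene_map named list of member transcript ids.
#' @param ids transcript ids matching the vectors.
#' @param ef_threshold,fp_cutoff as in [accuracy_stats()].
#' @return data frame with rows `gene`, `isoform`, `within_gene`.
#' @export
accuracy_report <- function(est_tau, truth_tau, gene_map, ids,
                            ef_threshold = 10, fp_cutoff = 1) {
  stopifnot(length(est_tau) == length(ids),
            length(truth_tau) == length(ids))
  names(est_tau) <- names(truth_tau) <- ids
  ge <- gene_and_isopct(est_tau, gene_map)
  gt <- gene_and_isopct(truth_tau, gene_map)
  rows <- list(
    gene = accuracy_stats(1e6 * ge$gene_tau, 1e6 * gt$gene_tau,
                          ef_threshold, fp_cutoff),
    isoform = accuracy_stats(1e6 * est_tau, 1e6 * truth_tau,
                             ef_threshold, fp_cutoff))
  keep_gene <- names(gt$gene_tau)[gt$gene_tau > 0 &
                                    lengths(gene_map) >= 2]
  sel <- intersect(ids, unlist(gene_map[keep_gene], use.names = FALSE))
  rows$within_gene <- accuracy_stats(1e4 * ge$isopct[sel],
                                     1e4 * gt$isopct[sel],
                                     ef_threshold, fp_cutoff)
  out <- do.call(rbind, rows)
  out$level <- rownames(out)
  out[, c("level", "mpe", "ef", "fp")]
}

#' Credibility-interval coverage
#'
#' The percentage of transcripts with true abundance at least `min_abund`
#' whose truth lies inside the reported interval.
#'
#' @param truth true abundances (same scale as the intervals, typically
#'   TPM).
#' @param lower,upper interval endpoints.
#' @param min_abund eligibility threshold on the truth.
#' @return a percentage (`NA` if no transcript is eligible).
#' @export
ci_coverage <- function(truth, lower, upper, min_abund = 1) {
  stopifnot(length(truth) == length(lower), length(truth) == length(upper))
  eligible <- truth >= min_abund
  if (!any(eligible)) return(NA_real_)
  100 * mean(truth[eligible] >= lower[eligible] &
               truth[eligible] <= upper[eligible])
}

#' Sequence mappability of isoforms and genes
#'
#' Generates every possible read of `read_len` bases from each isoform and
#' aligns it to the entire transcript set allowing `max_mismatch`
#' mismatches (either strand, full-length match).  An isoform's
#' mappability is the fraction of its reads that align only to isoforms of
#' its own gene; a gene's mappability is the mean of its isoforms'.
#'
#' @param ts a [transcript_set()].
#' @param read_len read length in bases.
#' @param max_mismatch mismatch budget (at most 2).
#' @return list with `isoform` (named vector; `NA` for transcripts shorter
#'   than `read_len`) and `gene` (named vector of means).
#' @export
mappability <- function(ts, read_len = 35, max_mismatch = 2) {
  gene_idx <- match(ts$gene_id, names(ts$gene_map))
  r <- cpp_mappability(ts$seq, gene_idx, as.integer(read_len),
                       as.integer(max_mismatch))
  iso <- ifelse(r$n_windows > 0, r$n_within / r$n_windows, NA_real_)
  names(iso) <- ts$id
  gene <- tapply(iso, factor(ts$gene_id, levels = names(ts$gene_map)),
                 function(x) mean(x, na.rm = TRUE))
  list(isoform = iso, gene = setNames(as.numeric(gene), names(gene)))
}
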