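#' Write isoform- and gene-level result tables
#'
#' Emits the two standard tab-separated result files.  The isoform table
#' has columns `transcript_id`, `gene_id`, `length`, `effective_length`,
#' `expected_count`, `TPM`, `tau`, `IsoPct` (and, when a posterior summary
#' is supplied, `pme_TPM`, `TPM_ci_lower`, `TPM_ci_upper`); the gene table
#' aggregates member transcripts.  Numeric columns use fixed 6-decimal
#' formatting.
#'
#' @param ml an [run_em()] result.
#' @param ts the [transcript_set()].
#' @param file_isoform,file_gene output paths (`NULL` skips writing).
#' @param post optional [summarize_posterior()] result.
#' @return invisibly, a list with the two data frames.
#' @export
write_results <- function(ml, ts, file_isoform = NULL, file_gene = NULL,
                          post = NULL) {
  iso <- data.frame(transcript_id = ts$id, gene_id = ts$gene_id,
                    length = ts$length,
                    effective_length = unname(ml$eff_len),
                    expected_count = unname(ml$expected_counts[-1]),
                    TPM = unname(ml$tpm), tau = unname(ml$tau),
                    IsoPct = unname(ml$isopct))
  if (!is.null(post)) {
    stopifnot(identical(post$isoform$id, ts$id))
    iso$pme_TPM <- post$isoform$pme_tpm
    iso$TPM_ci_lower <- post$isoform$ci_lower
    iso$TPM_ci_upper <- post$isoform$ci_upper
  }
  g <- factor(ts$gene_id, levels = names(ts$gene_map))
  agg <- function(x) as.numeric(rowsum(x, g))
  wmean <- function(x, w) {
    tot <- agg(w)
    ifelse(tot > 0, agg(x * w) / tot, agg(x) / tabulate(g))
  }
  ec <- unname(ml$expected_counts[-1])
  gene <- data.frame(gene_id = names(ts$gene_map),
                     transcript_ids = vapply(ts$gene_map, paste, "",
                                             collapse = ","),
                     length = wmean(ts$length, ec),
                     effective_length = wmean(unname(ml$eff_len), ec),
                     expected_count = agg(ec),
                     TPM = 1e6 * unname(ml$gene_tau),
                     tau = unname(ml$gene_tau))
  if (!is.null(post)) {
    stopifnot(identical(post$gene$id, names(ts$gene_map)))
    gene$pme_TPM <- post$gene$pme_tpm
    gene$TPM_ci_lower <- post$gene$ci_lower
    gene$TPM_ci_upper <- post$gene$ci_upper
  }
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE) &
      !vapply(df, is.integer, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
    df
  }
  if (!is.null(file_isoform)) {
    write.table(fmt(iso), file_isoform, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(file_gene)) {
    write.table(fmt(gene), file_gene, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(isoform = iso, gene = gene))
}

#' Write posterior-weighted alignments as SAM
#'
#' One record per candidate alignment of each unfiltered read, in
#' transcript coordinates.  The posterior probability that the alignment
#' is the true one (given the ML parameters) is stored losslessly in the
#' `ZW:f` tag and encoded in MAPQ as `round(-10 log10(1 - p))`, capped at
#' 100 (`p = 1` maps to the cap).
#'
#' @param ml an [run_em()] result (responsibilities are computed at its
#'   ML parameters).
#' @param ts the [transcript_set()].
#' @param file output SAM path.
#' @return invisibly, the path.
#' @export
write_posterior_alignments <- function(ml, ts, file) {
  comp <- ml$data
  r <- cpp_responsibilities(comp$offsets, comp$cand_tid, comp$w,
                            comp$noise_w, ml$theta)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ts$id, ts$length))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (length(comp$cand_read) == 0) return(invisible(file))
  post <- r$post
  mapq <- pmin(100L, as.integer(round(-10 * log10(pmax(1 - post, 1e-10)))))
  reads <- comp$cand_read
  ids <- comp$src_reads$id[comp$keep][reads]
  revstr <- function(x) vapply(strsplit(x, ""), function(v)
    paste(rev(v), collapse = ""), "")
  mk_mate <- function(s, q, p, rc, flag_extra, pn, tl) {
    sr <- s[reads]
    L <- nchar(sr)
    sr[rc] <- cpp_revcomp(sr[rc])
    qr <- if (is.null(q)) rep("*", length(reads)) else q[reads]
    if (!is.null(q) && any(rc)) qr[rc] <- revstr(qr[rc])
    flag <- ifelse(rc, 16L, 0L) + flag_extra
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t%s\t%s\tZW:f:%.6g",
            ids, flag, ts$id[comp$cand_tid], p + 1L, mapq, L,
            if (is.null(pn)) "*" else "=",
            if (is.null(pn)) 0L else pn + 1L,
            if (is.null(tl)) 0L else tl, sr, qr, post)
  }
  q1 <- comp$src_reads$qual1
  q1 <- if (is.null(q1)) NULL else q1[comp$keep]
  s1 <- comp$src_reads$seq1[comp$keep]
  if (!comp$paired) {
    lines <- mk_mate(s1, q1, comp$cand_pos, comp$cand_orient == 1L, 0L,
                     NULL, NULL)
  } else {
    s2 <- comp$src_reads$seq2[comp$keep]
    q2 <- comp$src_reads$qual2
    q2 <- if (is.null(q2)) NULL else q2[comp$keep]
    L1 <- nchar(s1)[reads]
    L2 <- nchar(s2)[reads]
    p1 <- ifelse(comp$cand_orient == 0L, comp$cand_pos,
                 comp$cand_pos + comp$cand_flen - L1)
    p2 <- ifelse(comp$cand_orient == 0L, comp$cand_pos + comp$cand_flen - L2,
                 comp$cand_pos)
    rc1 <- comp$cand_orient == 1L
    rc2 <- comp$cand_orient == 0L
    lines <- c(mk_mate(s1, q1, p1, rc1, 1L + 64L + 32L * (!rc1), p2,
                       ifelse(rc1, -comp$cand_flen, comp$cand_flen)),
               mk_mate(s2, q2, p2, rc2, 1L + 128L + 32L * (!rc2), p1,
                       ifelse(rc2, -comp$cand_flen, comp$cand_flen)))
  }
  writeLines(lines, con)
  invisible(file)
}

#' Transcript-coordinate read depth track (wiggle)
#'
#' For each transcript position, the expected number of reads overlapping
#' it: the sum of the posterior weights of all candidate alignments whose
#' read (or mate) covers the position.  Written as fixedStep wiggle
#' records, one block per covered transcript.
#'
#' @param ml an [run_em()] result.
#' @param ts the [transcript_set()].
#' @param file output wiggle path.
#' @return invisibly, a list of per-transcript depth vectors.
#' @export
depth_track <- function(ml, ts, file = NULL) {
  comp <- ml$data
  r <- cpp_responsibilities(comp$offsets, comp$cand_tid, comp$w,
                            comp$noise_w, ml$theta)
  post <- r$post
  depth <- vector("list", n_transcripts(ts))
  names(depth) <- ts$id
  add_segment <- function(tid, from, to, wt) {
    # difference-array accumulation per transcript
    for (i in which(wt > 0)) {
      t <- tid[i]
      if (is.null(depth[[t]])) depth[[t]] <<- numeric(ts$length[t] + 1L)
      depth[[t]][from[i] + 1L] <<- depth[[t]][from[i] + 1L] + wt[i]
      depth[[t]][to[i] + 1L] <<- depth[[t]][to[i] + 1L] - wt[i]
    }
  }
  if (length(comp$cand_read) > 0) {
    if (!comp$paired) {
      L <- comp$L1[comp$cand_read]
      add_segment(comp$cand_tid, comp$cand_pos, comp$cand_pos + L, post)
    } else {
      L1 <- comp$L1[comp$cand_read]
      L2 <- comp$L2[comp$cand_read]
      p1 <- ifelse(comp$cand_orient == 0L, comp$cand_pos,
                   comp$cand_pos + comp$cand_flen - L1)
      p2 <- ifelse(comp$cand_orient == 0L, comp$cand_pos + comp$cand_flen - L2,
                   comp$cand_pos)
      add_segment(comp$cand_tid, p1, p1 + L1, post)
      add_segment(comp$cand_tid, p2, p2 + L2, post)
    }
  }
  out <- lapply(seq_along(depth), function(i) {
    d <- depth[[i]]
    if (is.null(d)) return(NULL)
    cumsum(d)[seq_len(ts$length[i])]
  })
  names(out) <- ts$id
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con))
    for (i in seq_along(out)) {
      if (is.null(out[[i]]) || all(out[[i]] == 0)) next
      writeLines(sprintf("fixedStep chrom=%s start=1 step=1", ts$id[i]), con)
      writeLines(sprintf("%.6g", out[[i]]), con)
    }
  }
  invisible(out)
}
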