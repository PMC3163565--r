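# Internal: compile an alignment_set + model_params into the flat arrays
# used by the EM and Gibbs kernels.  Candidate weights factor as
#   w = pos_factor * emission
# where pos_factor collects the orientation / fragment-length / RSPD /
# read-length terms (recomputed only when those distributions change) and
# emission collects the error-model terms (recomputed when the error
# tables are re-estimated).  Emissions are stored as a per-read base
# product (all positions scored as matches) plus per-candidate mismatch
# adjustments, so re-scoring after an error-model update is cheap.

compile_alignments <- function(aset, ts, params) {
  stopifnot(inherits(aset, "alignment_set"), inherits(ts, "transcript_set"))
  keep <- which(aset$filtered == "none")
  reads <- aset$reads
  n <- length(keep)
  if (n == 0) stop("no unfiltered reads")
  paired <- isTRUE(reads$paired)

  cand <- aset$cand
  cand$read <- match(cand$read, keep)
  stopifnot(!anyNA(cand$read))
  cand <- cand[order(cand$read), , drop = FALSE]
  offsets <- c(0L, cumsum(tabulate(cand$read, n)))

  seq1 <- reads$seq1[keep]
  L1 <- nchar(seq1)
  enc1 <- cpp_encode_seqs(seq1)
  has_q <- !is.null(reads$qual1)
  encq1 <- if (has_q) cpp_encode_quals(reads$qual1[keep], 33L) else NULL

  rl_read <- rep.int(seq_len(n), L1)
  rl_pos <- sequence(L1)                      # 1-based position within mate
  rl_char <- enc1$codes
  rl_qual <- if (has_q) encq1$codes else integer(length(rl_char))

  if (paired) {
    seq2 <- reads$seq2[keep]
    L2 <- nchar(seq2)
    enc2 <- cpp_encode_seqs(seq2)
    encq2 <- if (has_q) cpp_encode_quals(reads$qual2[keep], 33L) else NULL
    rl_read <- c(rl_read, rep.int(seq_len(n), L2))
    rl_pos <- c(rl_pos, sequence(L2))
    rl_char <- c(rl_char, enc2$codes)
    rl_qual <- c(rl_qual, if (has_q) encq2$codes else integer(sum(L2)))
  } else {
    seq2 <- NULL
    L2 <- NULL
  }

  # mismatches per candidate (read coordinates, per mate)
  qual_at <- function(enc, read, pos) {
    if (is.null(enc)) integer(length(read)) else
      enc$codes[enc$offsets[read] + pos + 1L]
  }
  if (nrow(cand) > 0) {
    if (!paired) {
      mm <- cpp_mismatches(seq1, cand$read, cand$tid, cand$pos, cand$orient,
                           ts$seq)
      mm_cand <- mm$cand
      mm_pos <- mm$pos
      mm_r <- mm$read_char
      mm_c <- mm$ref_char
      mm_qual <- qual_at(encq1, cand$read[mm$cand], mm$pos)
    } else {
      p1 <- ifelse(cand$orient == 0L, cand$pos,
                   cand$pos + cand$flen - L1[cand$read])
      p2 <- ifelse(cand$orient == 0L, cand$pos + cand$flen - L2[cand$read],
                   cand$pos)
      mmA <- cpp_mismatches(seq1, cand$read, cand$tid, as.integer(p1),
                            cand$orient, ts$seq)
      mmB <- cpp_mismatches(seq2, cand$read, cand$tid, as.integer(p2),
                            1L - cand$orient, ts$seq)
      mm_cand <- c(mmA$cand, mmB$cand)
      mm_pos <- c(mmA$pos, mmB$pos)
      mm_r <- c(mmA$read_char, mmB$read_char)
      mm_c <- c(mmA$ref_char, mmB$ref_char)
      mm_qual <- c(qual_at(encq1, cand$read[mmA$cand], mmA$pos),
                   qual_at(encq2, cand$read[mmB$cand], mmB$pos))
    }
  } else {
    mm_cand <- mm_pos <- mm_r <- mm_c <- mm_qual <- integer(0)
  }

  comp <- list(n = n, M = n_transcripts(ts), keep = keep, paired = paired,
               src_reads = reads,
               offsets = offsets,
               cand_read = cand$read, cand_tid = cand$tid,
               cand_pos = cand$pos, cand_orient = cand$orient,
               cand_flen = cand$flen, L1 = L1, L2 = L2,
               tlen = ts$length, has_qual = has_q,
               rl_read = rl_read, rl_pos = rl_pos, rl_char = rl_char,
               rl_qual = rl_qual,
               mm_cand = mm_cand, mm_pos = mm_pos, mm_r = mm_r,
               mm_c = mm_c, mm_qual = mm_qual)
  comp$pos_factor <- comp_pos_factors(comp, params)
  comp$emis <- comp_emissions(comp, params)
  comp$w <- comp$pos_factor * comp$emis
  comp$noise_w <- comp_noise_weights(comp, params)
  comp
}

comp_pos_factors <- function(comp, params) {
  if (length(comp$cand_read) == 0) return(numeric(0))
  fd <- params$frag_dist
  rd <- params$read_dist
  if (!comp$paired) {
    cpp_se_pos_factors(comp$tlen[comp$cand_tid], comp$cand_pos,
                       comp$cand_orient, comp$L1[comp$cand_read],
                       fd$min, fd$pmf, rd$min, rd$pmf, params$rspd,
                       params$strand_specific)
  } else {
    cpp_pe_pos_factors(comp$tlen[comp$cand_tid], comp$cand_pos,
                       as.integer(comp$cand_flen), comp$cand_orient,
                       comp$L1[comp$cand_read], comp$L2[comp$cand_read],
                       fd$min, fd$pmf, rd$min, rd$pmf, params$rspd,
                       params$strand_specific)
  }
}

# log emission lookup vectors for the active error model
comp_emissions <- function(comp, params) {
  em <- params$error
  K1 <- dim(em$eps)[1]
  logeps <- log(em$eps)
  min_log <- log(error_model_min(em))
  logeps[!is.finite(logeps)] <- min_log + log(1e-12)
  key_of <- function(qual, pos) {
    if (em$type == "quality") pmin(pmax(qual, 0L), K1 - 1L) + 1L
    else pmin(pos, K1)
  }
  # per-read product of match emissions
  key <- key_of(comp$rl_qual, comp$rl_pos)
  r <- comp$rl_char
  lp <- ifelse(r > 3L, min_log, logeps[cbind(key, r + 1L, r + 1L)])
  base_log <- as.vector(rowsum(lp, comp$rl_read,
                               reorder = TRUE))  # groups 1..n all present
  if (length(comp$mm_cand) > 0) {
    keym <- key_of(comp$mm_qual, comp$mm_pos + 1L)
    rm_ <- comp$mm_r
    cm <- comp$mm_c
    match_term <- ifelse(rm_ > 3L, min_log,
                         logeps[cbind(keym, rm_ + 1L, rm_ + 1L)])
    mm_term <- ifelse(rm_ > 3L | cm > 3L, min_log,
                      logeps[cbind(keym, pmin(cm, 3L) + 1L,
                                   pmin(rm_, 3L) + 1L)])
    adj <- numeric(length(comp$cand_read))
    s <- rowsum(mm_term - match_term, comp$mm_cand)
    adj[as.integer(rownames(s))] <- s[, 1]
  } else {
    adj <- numeric(length(comp$cand_read))
  }
  exp(base_log[comp$cand_read] + adj)
}

comp_noise_weights <- function(comp, params) {
  bg <- params$noise_background
  mn <- min(bg[bg > 0])
  lb <- ifelse(comp$rl_char > 3L, log(mn), log(bg)[comp$rl_char + 1L])
  nl <- as.vector(rowsum(lb, comp$rl_read, reorder = TRUE))
  w <- exp(nl) * dist_mass(params$read_dist, comp$L1)
  if (comp$paired) w <- w * dist_mass(params$read_dist, comp$L2)
  w
}

# refresh candidate weights after a parameter update
comp_refresh <- function(comp, params, pos_changed) {
  if (pos_changed) comp$pos_factor <- comp_pos_factors(comp, params)
  comp$emis <- comp_emissions(comp, params)
  comp$w <- comp$pos_factor * comp$emis
  comp$noise_w <- comp_noise_weights(comp, params)
  comp
}
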