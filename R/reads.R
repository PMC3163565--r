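#' Read sets
#'
#' A `read_set` holds single-end or paired-end reads in file order:
#' sequences, optional Phred+33 quality strings, and mate fields for
#' paired data.
#'
#' @param seq1 character vector of read (mate 1) sequences.
#' @param id read identifiers (defaults to `read1..readN`).
#' @param qual1 optional quality strings matching `seq1`.
#' @param seq2,qual2 optional mate 2 fields.
#' @return an object of class `read_set`.
#' @export
read_set <- function(seq1, id = NULL, qual1 = NULL, seq2 = NULL,
                     qual2 = NULL) {
  seq1 <- toupper(as.character(seq1))
  n <- length(seq1)
  if (is.null(id)) id <- paste0("read", seq_len(n))
  paired <- !is.null(seq2)
  if (paired) {
    seq2 <- toupper(as.character(seq2))
    if (length(seq2) != n) stop("mate files have different record counts")
  }
  for (pair in list(list(seq1, qual1), list(seq2, qual2))) {
    if (!is.null(pair[[2]]) && !is.null(pair[[1]]) &&
        any(nchar(pair[[2]]) != nchar(pair[[1]]))) {
      stop("sequence and quality lengths differ")
    }
  }
  structure(list(id = as.character(id), seq1 = seq1, qual1 = qual1,
                 seq2 = seq2, qual2 = qual2, paired = paired),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set: %d %s reads%s>\n", length(x$seq1),
              if (x$paired) "paired-end" else "single-end",
              if (is.null(x$qual1)) "" else ", with qualities"))
  invisible(x)
}

#' @rdname read_set
#' @param reads a `read_set`.
#' @export
n_reads <- function(reads) length(reads$seq1)

#' Read sequencing reads from FASTA or FASTQ
#'
#' @param path file of reads (mate 1 for paired data).
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension/content).
#' @param mate2 optional mate 2 file, aligned record-for-record.
#' @return a [read_set()]; quality strings are retained for FASTQ input.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           mate2 = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  rd <- function(p) {
    if (format == "fastq") {
      x <- Biostrings::readDNAStringSet(p, format = "fastq",
                                        with.qualities = TRUE)
      qual <- as.character(S4Vectors::mcols(x)$qualities)
      if (any(nchar(qual) != nchar(as.character(x)))) {
        stop("malformed FASTQ: sequence and quality lengths differ in ", p)
      }
      list(seq = as.character(x), qual = qual,
           id = sub("\\s.*$", "", names(x)))
    } else {
      x <- Biostrings::readDNAStringSet(p, format = "fasta")
      list(seq = as.character(x), qual = NULL,
           id = sub("\\s.*$", "", names(x)))
    }
  }
  m1 <- rd(path)
  if (is.null(mate2)) {
    read_set(m1$seq, m1$id, m1$qual)
  } else {
    m2 <- rd(mate2)
    if (length(m2$seq) != length(m1$seq)) {
      stop("mate files have different record counts")
    }
    read_set(m1$seq, m1$id, m1$qual, m2$seq, m2$qual)
  }
}

#' Candidate alignment sets
#'
#' An `alignment_set` couples a [read_set()] with the candidate alignments
#' of each read in transcript coordinates (0-based start of the fragment's
#' 5'-most base, orientation, and for paired reads the fragment length).
#' Reads with no candidates are retained -- they are eligible for the
#' noise component -- and `filtered` records the reason a read is excluded
#' from estimation (`"too_many_alignments"`, `"polya_like"` or `"none"`).
#'
#' @param reads a [read_set()].
#' @param cand data frame with columns `read` (index into `reads`), `tid`
#'   (transcript index), `pos`, `orient` (0 forward / 1 reverse) and
#'   `flen` (fragment length; `NA` for single-end).
#' @param nhits candidate count per read before any capping (defaults to
#'   the table counts).
#' @return an object of class `alignment_set`.
#' @export
alignment_set <- function(reads, cand, nhits = NULL) {
  stopifnot(inherits(reads, "read_set"), is.data.frame(cand))
  need <- c("read", "tid", "pos", "orient", "flen")
  stopifnot(all(need %in% names(cand)))
  cand <- cand[order(cand$read, cand$tid, cand$pos, cand$orient), need,
               drop = FALSE]
  rownames(cand) <- NULL
  n <- n_reads(reads)
  if (is.null(nhits)) nhits <- tabulate(cand$read, n)
  structure(list(reads = reads, cand = cand, nhits = as.integer(nhits),
                 filtered = rep("none", n)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf(
    "<alignment_set: %d reads, %d candidate alignments, %d filtered, %d unaligned>\n",
    n_reads(x$reads), nrow(x$cand), sum(x$filtered != "none"),
    sum(x$nhits == 0)))
  invisible(x)
}

#' Align reads to a transcript set with the built-in aligner
#'
#' Seed-based all-hits alignment: a read aligns wherever its first
#' `seed_len` bases (or those of its reverse complement) match with at
#' most `max_mm` mismatches and the read fits inside the transcript,
#' mirroring the policy of short-read aligners configured to report all
#' valid alignments.  Reads reaching `max_hits` candidate alignments stop
#' being collected and are flagged for filtering.
#'
#' @param reads a [read_set()].
#' @param ts a [transcript_set()].
#' @param seed_len seed length in bases.
#' @param max_mm mismatch budget within the seed.
#' @param max_hits collection cap (aligning to at least this many places
#'   marks the read as highly multi-mapping).
#' @param strand_specific only align reads in forward orientation.
#' @param max_frag largest mate span accepted when pairing (paired data).
#' @return an [alignment_set()].
#' @export
align_reads <- function(reads, ts, seed_len = 25, max_mm = 2,
                        max_hits = 200, strand_specific = FALSE,
                        max_frag = 1000) {
  stopifnot(inherits(reads, "read_set"), inherits(ts, "transcript_set"))
  if (!reads$paired) {
    h <- cpp_align_reads(reads$seq1, ts$seq, seed_len, max_mm, max_hits,
                         strand_specific)
    cand <- data.frame(read = h$read, tid = h$tid, pos = h$pos,
                       orient = h$orient,
                       flen = rep(NA_integer_, length(h$read)))
    aset <- alignment_set(reads, cand, nhits = h$nhits)
    return(aset)
  }
  # paired: align each mate, join FR pairs on the same transcript
  h1 <- cpp_align_reads(reads$seq1, ts$seq, seed_len, max_mm, max_hits,
                        FALSE)
  h2 <- cpp_align_reads(reads$seq2, ts$seq, seed_len, max_mm, max_hits,
                        FALSE)
  L1 <- nchar(reads$seq1)
  L2 <- nchar(reads$seq2)
  d1 <- data.frame(read = h1$read, tid = h1$tid, pos = h1$pos,
                   orient = h1$orient)
  d2 <- data.frame(read = h2$read, tid = h2$tid, pos = h2$pos,
                   orient = h2$orient)
  m <- merge(d1, d2, by = c("read", "tid"), suffixes = c("1", "2"))
  # proper FR orientation: mates on opposite strands
  m <- m[m$orient1 != m$orient2, , drop = FALSE]
  s <- ifelse(m$orient1 == 0, m$pos1, m$pos2)
  e <- ifelse(m$orient1 == 0, m$pos2 + L2[m$read], m$pos1 + L1[m$read])
  flen <- e - s
  ok <- flen >= pmax(L1[m$read], L2[m$read]) & flen <= max_frag
  cand <- data.frame(read = m$read[ok], tid = m$tid[ok], pos = s[ok],
                     orient = m$orient1[ok], flen = as.integer(flen[ok]))
  nh <- tabulate(cand$read, n_reads(reads))
  capped <- h1$capped | h2$capped
  nh[capped] <- max_hits
  cand <- cand[!capped[cand$read], , drop = FALSE]
  alignment_set(reads, cand, nhits = nh)
}

#' Enumerate all seed alignments of one read (reference scan)
#'
#' Exhaustive, deterministic enumeration of every (transcript, offset,
#' orientation) at which the first `seed_length` bases of the read (or of
#' its reverse complement) align with at most `max_mismatch` mismatches.
#' Results are ordered by transcript index, then offset, then forward
#' before reverse.  This is the reference implementation of the aligner
#' policy; [align_reads()] is the indexed equivalent.
#'
#' @param read a read sequence (character string).
#' @param ts a [transcript_set()].
#' @param seed_length seed length (defaults to the read length).
#' @param max_mismatch mismatch budget within the seed.
#' @param strand_specific forward orientation only.
#' @return data frame with columns `tid`, `pos`, `orient`.
#' @export
enumerate_alignments <- function(read, ts, seed_length = nchar(read),
                                 max_mismatch = 2,
                                 strand_specific = FALSE) {
  stopifnot(seed_length <= nchar(read))
  h <- cpp_scan_align(toupper(read), ts$seq, seed_length, max_mismatch,
                      strand_specific)
  data.frame(tid = h$tid, pos = h$pos, orient = h$orient)
}

#' Apply the multi-alignment and poly(A) read filters
#'
#' Reads with at least `max_alignments` candidate alignments are excluded
#' from estimation, as are reads likely to derive from poly(A) tails
#' (fraction of `A` -- or of `T`, covering the antisense strand -- at
#' least `polya_fraction`; for paired reads, either mate).  Filtered reads
#' carry no candidates and do not count towards the number of unfiltered
#' fragments N.
#'
#' @param aset an [alignment_set()].
#' @param max_alignments multiplicity threshold (filter when the candidate
#'   count is `>=` this value).
#' @param polya_fraction A/T-content threshold in `[0, 1]`.
#' @return the `alignment_set` with `filtered` flags set and candidates of
#'   filtered reads removed.
#' @export
filter_reads <- function(aset, max_alignments = 200, polya_fraction = 0.9) {
  stopifnot(inherits(aset, "alignment_set"), max_alignments > 0,
            polya_fraction > 0)
  reads <- aset$reads
  pl <- polya_like(reads$seq1, polya_fraction)
  if (reads$paired) pl <- pl | polya_like(reads$seq2, polya_fraction)
  many <- aset$nhits >= max_alignments
  aset$filtered <- ifelse(many, "too_many_alignments",
                          ifelse(pl, "polya_like", "none"))
  aset$cand <- aset$cand[aset$filtered[aset$cand$read] == "none", ,
                         drop = FALSE]
  rownames(aset$cand) <- NULL
  aset
}

# fraction of A (or of T) in each sequence >= thr
polya_like <- function(seqs, thr) {
  n <- nchar(seqs)
  na <- nchar(gsub("[^A]", "", seqs))
  nt <- nchar(gsub("[^T]", "", seqs))
  pmax(na, nt) >= thr * n
}

#' Parse candidate alignments from a SAM file
#'
#' Reads a SAM file of alignments against transcript coordinates (RNAME =
#' transcript id) produced by an aligner configured to report all valid
#' alignments.  1-based POS is converted to the internal 0-based
#' convention; the reverse flag maps to orientation; paired records are
#' joined on QNAME with the fragment length derived from the mate span.
#' Unmapped reads are kept with empty candidate lists.
#'
#' @param path SAM (or BAM) file.
#' @param ts a [transcript_set()]; all reference names must be transcript
#'   ids of this set.
#' @param reads optional [read_set()]; reconstructed from the SAM records
#'   when omitted.
#' @return an [alignment_set()].
#' @export
parse_sam <- function(path, ts, reads = NULL) {
  stopifnot(inherits(ts, "transcript_set"))
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
         else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mpos", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  qname <- b$qname
  paired <- bitwAnd(flag, 1L) > 0
  if (any(paired) && !all(paired)) {
    stop("mixed single-end and paired-end records")
  }
  is_pe <- length(flag) > 0 && all(paired)
  mapped <- bitwAnd(flag, 4L) == 0
  rname <- as.character(b$rname)
  if (any(mapped & !(rname %in% ts$id))) {
    stop("SAM reference names absent from the transcript set: ",
         paste(head(setdiff(rname[mapped], ts$id), 5), collapse = ", "))
  }
  rev_ <- bitwAnd(flag, 16L) > 0
  seqs <- as.character(b$seq)
  # SAM stores reverse-strand records as the reverse complement
  seqs[rev_] <- cpp_revcomp(seqs[rev_])
  quals <- as.character(b$qual)
  quals[rev_] <- vapply(strsplit(quals[rev_], ""), function(x)
    paste(rev(x), collapse = ""), "")
  has_qual <- length(quals) > 0 && !all(quals %in% c("*", ""))

  if (!is_pe) {
    uq <- unique(qname)
    ridx <- match(qname, uq)
    first <- match(uq, qname)
    if (is.null(reads)) {
      reads <- read_set(seqs[first], uq,
                        if (has_qual) quals[first] else NULL)
    } else {
      ridx <- match(qname, reads$id)
      if (anyNA(ridx)) stop("SAM read names absent from the read set")
    }
    keep <- mapped
    cand <- data.frame(read = ridx[keep],
                       tid = match(rname[keep], ts$id),
                       pos = b$pos[keep] - 1L,
                       orient = as.integer(rev_[keep]),
                       flen = NA_integer_)
    return(alignment_set(reads, cand))
  }

  first_mate <- bitwAnd(flag, 64L) > 0
  uq <- unique(qname)
  if (is.null(reads)) {
    i1 <- match(uq, qname[first_mate])
    i2 <- match(uq, qname[!first_mate])
    if (anyNA(i1) || anyNA(i2)) stop("paired records with missing mate")
    s1 <- seqs[first_mate][i1]; s2 <- seqs[!first_mate][i2]
    reads <- read_set(s1, uq, if (has_qual) quals[first_mate][i1] else NULL,
                      s2, if (has_qual) quals[!first_mate][i2] else NULL)
  }
  ridx_all <- match(qname, reads$id)
  if (anyNA(ridx_all)) stop("SAM read names absent from the read set")
  m1 <- which(first_mate & mapped)
  m2 <- which(!first_mate & mapped)
  d1 <- data.frame(key = paste(qname[m1], rname[m1], b$pos[m1], b$mpos[m1]),
                   read = ridx_all[m1],
                   tid = match(rname[m1], ts$id), pos = b$pos[m1] - 1L,
                   orient = as.integer(rev_[m1]), L = nchar(seqs[m1]))
  d2 <- data.frame(key = paste(qname[m2], rname[m2], b$mpos[m2], b$pos[m2]),
                   pos2 = b$pos[m2] - 1L,
                   orient2 = as.integer(rev_[m2]), L2 = nchar(seqs[m2]))
  mm <- merge(d1, d2, by = "key")
  mm <- mm[mm$orient != mm$orient2, , drop = FALSE]
  dropped <- length(m1) - nrow(mm)
  if (dropped > 0) {
    warning(dropped, " paired records without a joinable mate were dropped")
  }
  s <- ifelse(mm$orient == 0, mm$pos, mm$pos2)
  e <- ifelse(mm$orient == 0, mm$pos2 + mm$L2, mm$pos + mm$L)
  cand <- data.frame(read = mm$read, tid = mm$tid, pos = s,
                     orient = mm$orient, flen = as.integer(e - s))
  alignment_set(reads, cand)
}
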