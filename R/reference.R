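#' Reference transcript sets
#'
#' A `transcript_set` holds the reference transcript sequences against
#' which reads are aligned and quantified: sequences, per-transcript gene
#' membership, current lengths (including any appended poly(A) tail) and
#' the gene map.  Transcript order is stable and indexes the abundance
#' vector positions `1..M` (position 0 is the noise component).
#'
#' @param seq character vector of transcript sequences (A/C/G/T/N).
#' @param id unique transcript identifiers.
#' @param gene_id gene identifier per transcript; transcripts without one
#'   become singleton genes named after the transcript.
#' @return an object of class `transcript_set`.
#' @export
transcript_set <- function(seq, id = names(seq), gene_id = NULL) {
  seq <- toupper(as.character(seq))
  if (is.null(id)) stop("transcript ids are required")
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate transcript ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(seq) != length(id)) stop("seq and id lengths differ")
  if (any(nchar(seq) < 1)) stop("transcripts must have length >= 1")
  if (is.null(gene_id)) gene_id <- id
  gene_id <- as.character(gene_id)
  stopifnot(length(gene_id) == length(id))
  gm <- split(id, factor(gene_id, levels = unique(gene_id)))
  structure(list(id = id, gene_id = gene_id, seq = unname(seq),
                 length = nchar(seq), base_length = nchar(seq),
                 polya_length = 0L,
                 gene_map = lapply(gm, as.character)),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf(
    "<transcript_set: %d transcripts, %d genes, lengths %d-%d%s>\n",
    length(x$id), length(x$gene_map), min(x$length), max(x$length),
    if (x$polya_length > 0)
      sprintf(", poly(A) tail %d", x$polya_length) else ""))
  invisible(x)
}

n_transcripts <- function(ts) length(ts$id)

#' Load reference transcripts from FASTA
#'
#' Reads transcript sequences from a FASTA file, optionally with a
#' transcript-to-gene map (a headerless two-column tab-separated file:
#' `gene_id <TAB> transcript_id`).  Transcripts absent from the map become
#' singleton genes.
#'
#' @param fasta_path FASTA file of transcript sequences.
#' @param gene_map_path optional gene-map TSV path.
#' @return a [transcript_set()].
#' @export
load_reference <- function(fasta_path, gene_map_path = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dna))
  seqs <- as.character(dna)
  gene <- ids
  if (!is.null(gene_map_path)) {
    gm <- read.table(gene_map_path, sep = "\t", header = FALSE,
                     col.names = c("gene_id", "transcript_id"),
                     stringsAsFactors = FALSE)
    bad <- setdiff(gm$transcript_id, ids)
    if (length(bad) > 0) {
      stop("gene map references unknown transcripts: ",
           paste(head(bad, 5), collapse = ", "))
    }
    hit <- match(ids, gm$transcript_id)
    gene <- ifelse(is.na(hit), ids, gm$gene_id[hit])
  }
  transcript_set(seqs, ids, gene)
}

#' Extract reference transcripts from a GTF annotation and genome
#'
#' Builds transcript sequences by splicing exon records: each transcript is
#' the concatenation of its exons in transcript order, reverse-complemented
#' for minus-strand transcripts.  Gene membership is taken from the
#' `gene_id` attribute.
#'
#' @param gtf_path GTF file with exon records carrying `transcript_id` and
#'   `gene_id` attributes (1-based inclusive coordinates).
#' @param genome_fasta FASTA file of the genome (chromosome sequences).
#' @return a [transcript_set()].
#' @export
extract_from_gtf <- function(gtf_path, genome_fasta) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon records in GTF")
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (!all(chrom %in% names(genome))) {
    stop("GTF references chromosomes absent from the genome: ",
         paste(head(setdiff(chrom, names(genome)), 5), collapse = ", "))
  }
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  if (any(st < 1) || any(en > nchar(as.character(genome[chrom])))) {
    stop("exon outside chromosome bounds")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  txid <- as.character(gr$transcript_id)
  gid <- as.character(gr$gene_id)
  ord <- order(match(txid, unique(txid)), st)
  pieces <- substr(as.character(genome[chrom[ord]]), st[ord], en[ord])
  sp <- split(pieces, factor(txid[ord], levels = unique(txid[ord])))
  seqs <- vapply(sp, paste0, "", collapse = "")
  tx <- names(seqs)
  tx_strand <- strand[ord][match(tx, txid[ord])]
  minus <- tx_strand == "-"
  if (any(minus)) seqs[minus] <- cpp_revcomp(seqs[minus])
  tx_gene <- gid[ord][match(tx, txid[ord])]
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    warning("skipping transcripts with no exon sequence: ",
            paste(tx[empty], collapse = ", "))
    seqs <- seqs[!empty]; tx <- tx[!empty]; tx_gene <- tx_gene[!empty]
  }
  transcript_set(unname(seqs), tx, tx_gene)
}

#' Append poly(A) tails to reference transcripts
#'
#' For poly(A)+ mRNA analysis the reference transcripts are extended with a
#' tail of `tail_length` `A` characters (default 125), so that reads
#' extending into the tail still align.  `strip_polya()` removes the tail
#' again, recovering the original lengths exactly.
#'
#' @param ts a [transcript_set()].
#' @param tail_length tail length in bases (0 disables).
#' @return the modified `transcript_set`.
#' @export
append_polya <- function(ts, tail_length = 125) {
  stopifnot(inherits(ts, "transcript_set"), tail_length >= 0)
  tail_length <- as.integer(tail_length)
  if (ts$polya_length > 0) ts <- strip_polya(ts)
  if (tail_length == 0) return(ts)
  tail <- strrep("A", tail_length)
  ts$seq <- paste0(ts$seq, tail)
  ts$length <- ts$base_length + tail_length
  ts$polya_length <- tail_length
  ts
}

#' @rdname append_polya
#' @export
strip_polya <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  if (ts$polya_length == 0) return(ts)
  ts$seq <- substr(ts$seq, 1L, ts$base_length)
  ts$length <- ts$base_length
  ts$polya_length <- 0L
  ts
}

#' Effective transcript length
#'
#' The mean number of positions from which a fragment may start within a
#' transcript:
#' \deqn{\tilde\ell = \sum_f \lambda_F(f \mid \ell)\,(\ell - f + 1)}
#' where \eqn{\lambda_F(\cdot \mid \ell)} is the fragment length
#' distribution truncated at the transcript length and renormalized.
#' Returns 0 when no supported fragment length fits.  Lengths are the
#' current (post-poly(A), if appended) lengths.
#'
#' @param len integer vector of transcript lengths.
#' @param frag_dist the fragment [length_dist()].
#' @return numeric vector of effective lengths.
#' @export
effective_length <- function(len, frag_dist) {
  stopifnot(inherits(frag_dist, "length_dist"))
  f <- seq.int(frag_dist$min, length.out = length(frag_dist$pmf))
  cum <- cumsum(frag_dist$pmf)
  part <- cumsum(frag_dist$pmf * (1 - f))   # sum pmf*(1-f) up to limit
  vapply(as.integer(len), function(l) {
    if (l < frag_dist$min) return(0)
    k <- min(l - frag_dist$min + 1L, length(f))
    denom <- cum[k]
    if (denom <= 0) return(0)
    ((l + 1) * cum[k] + part[k] - cum[k]) / denom
  }, numeric(1))
}

#' @rdname effective_length
#' @param ts a [transcript_set()].
#' @export
effective_lengths <- function(ts, frag_dist) {
  setNames(effective_length(ts$length, frag_dist), ts$id)
}
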