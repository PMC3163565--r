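#' Specification of a deterministic toy transcriptome
#'
#' Describes a small synthetic reference with controlled repeat structure
#' for self-contained testing and simulation studies: genes are built from
#' exon blocks, isoforms of a gene share exons (inducing within-gene
#' multireads), optional cross-gene shared blocks induce between-gene
#' multireads, and optional exact repeat copies exercise the repeat-pass
#' correction and mappability.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene isoforms per gene (recycled; at least 1).
#' @param length_range approximate transcript length range in bases.
#' @param shared_block length of a sequence block shared between pairs of
#'   genes (0 disables); applied to ~10% of genes.
#' @param repeat_copies number of extra transcripts that are exact copies
#'   of the first transcript, each in its own gene.
#' @param zero_fraction fraction of transcripts with zero designed
#'   abundance.
#' @param seed RNG seed making the reference and abundances reproducible.
#' @return a list of class `toy_spec`.
#' @export
toy_spec <- function(n_genes = 150, isoforms_per_gene = c(1, 2, 3),
                     length_range = c(500, 3000), shared_block = 0,
                     repeat_copies = 0, zero_fraction = 0.3, seed = 1) {
  stopifnot(n_genes >= 1, all(isoforms_per_gene >= 1),
            length_range[1] >= 100, length_range[2] >= length_range[1],
            shared_block >= 0, shared_block < length_range[1],
            repeat_copies >= 0, zero_fraction >= 0, zero_fraction < 1)
  structure(list(n_genes = n_genes,
                 isoforms_per_gene = isoforms_per_gene,
                 length_range = length_range, shared_block = shared_block,
                 repeat_copies = repeat_copies,
                 zero_fraction = zero_fraction, seed = seed),
            class = "toy_spec")
}

#' Generate a toy reference transcriptome with designed abundances
#'
#' Builds the reference described by a [toy_spec()]: each gene is a set of
#' exon blocks and each isoform a subset of them (the first isoform uses
#' all exons), so isoforms share sequence in a known way.  Designed
#' transcript fractions are drawn log-uniformly over `[1e-6, 1e-2]` and
#' normalized, with `zero_fraction` of transcripts set to zero --
#' emulating the sparse, several-orders-of-magnitude expression profiles
#' of real libraries.
#'
#' @param spec a [toy_spec()].
#' @param out_dir if non-`NULL`, write `reference.fa`, `gene_map.tsv` and
#'   `truth_tau.tsv` there.
#' @return list with `ts` (a [transcript_set()]) and `tau` (named designed
#'   transcript fractions summing to 1).
#' @export
make_toy_reference <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "toy_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")
  iso_per <- rep_len(spec$isoforms_per_gene, spec$n_genes)
  ids <- character(0)
  genes <- character(0)
  seqs <- character(0)
  shared <- if (spec$shared_block > 0) rand_seq(spec$shared_block) else NULL
  for (g in seq_len(spec$n_genes)) {
    glen <- round(runif(1, spec$length_range[1], spec$length_range[2]))
    n_ex <- sample(3:5, 1)
    cuts <- sort(sample(seq(50, glen - 50), n_ex - 1))
    exlen <- diff(c(0, cuts, glen))
    exons <- vapply(exlen, rand_seq, "")
    if (!is.null(shared) && g %% 10 %in% c(0, 1)) {
      exons[1] <- shared        # pairs of genes share their first block
      exlen[1] <- nchar(shared)
    }
    seen <- character(0)
    for (k in seq_len(iso_per[g])) {
      usein <- seq_len(n_ex)
      if (k > 1) {
        # skip exons while the isoform stays within the declared range,
        # retrying until this gene gets a distinct splice form
        for (try in 1:20) {
          cand <- seq_len(n_ex)
          for (drop in sample(n_ex, n_ex - 1)) {
            nxt <- setdiff(cand, drop)
            if (sum(exlen[nxt]) >= spec$length_range[1]) cand <- nxt
            if (length(cand) <= 2 || runif(1) < 0.5) break
          }
          cand <- sort(cand)
          if (!paste(cand, collapse = ",") %in% seen) break
        }
        usein <- cand
        if (paste(usein, collapse = ",") %in% seen) next
      }
      seen <- c(seen, paste(usein, collapse = ","))
      s <- paste(exons[usein], collapse = "")
      ids <- c(ids, sprintf("g%03d.t%d", g, k))
      genes <- c(genes, sprintf("g%03d", g))
      seqs <- c(seqs, s)
    }
  }
  if (spec$repeat_copies > 0) {
    for (r in seq_len(spec$repeat_copies)) {
      ids <- c(ids, sprintf("rep%02d.t1", r))
      genes <- c(genes, sprintf("rep%02d", r))
      seqs <- c(seqs, seqs[1])
    }
  }
  ts <- transcript_set(seqs, ids, genes)

  M <- length(ids)
  tau <- 10^runif(M, -6, -2)
  nz <- floor(spec$zero_fraction * M)
  if (nz > 0) tau[sample.int(M, nz)] <- 0
  if (all(tau == 0)) tau[1] <- 1
  tau <- tau / sum(tau)
  names(tau) <- ids

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(paste0(">", ids, "\n", seqs),
               file.path(out_dir, "reference.fa"))
    write.table(data.frame(genes, ids),
                file.path(out_dir, "gene_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(data.frame(transcript_id = ids, tau = tau),
                file.path(out_dir, "truth_tau.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(ts = ts, tau = tau)
}
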