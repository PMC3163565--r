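# small in-code fixtures shared across the tests

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a tiny two-gene reference with a shared block between t1 and t2
tiny_ts <- function(seed = 42, shared = 40) {
  set.seed(seed)
  block <- rand_dna(shared)
  t1 <- paste0(rand_dna(80), block, rand_dna(60))
  t2 <- paste0(rand_dna(70), block, rand_dna(90))
  t3 <- rand_dna(150)
  transcript_set(c(t1, t2, t3), c("t1", "t2", "t3"),
                 c("gA", "gA", "gB"))
}

# write a FASTA file and return its path
write_fasta <- function(seqs, ids = names(seqs), dir = tempdir()) {
  path <- tempfile("ref", fileext = ".fa", tmpdir = dir)
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# error-free single-end reads drawn deterministically from a transcript set
exact_reads <- function(ts, tid, start, len = 20, orient = 0L) {
  s <- substring(ts$seq[tid], start + 1L, start + len)
  rev <- orient == 1L
  if (any(rev)) s[rev] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s[rev])))
  read_set(s)
}

# quality string of constant phred q
qstr <- function(q, len) strrep(rawToChar(as.raw(q + 33L)), len)

# default model parameters for a small paired/unpaired test alignment set
init_params_for_test <- function(aset) {
  rnaquant:::init_params(aset, quant_control(error_model = "profile",
                                             fragment_length_mean = 55,
                                             fragment_length_sd = 10))
}
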