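test_that("FASTA/FASTQ reading keeps order, qualities and mates", {
  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "TTAA", "+", "!!!!"), fq)
  rs <- read_sequences(fq)
  expect_equal(rs$id, c("r1", "r2"))
  expect_equal(rs$seq1, c("ACGT", "TTAA"))
  expect_equal(rs$qual1, c("IIII", "!!!!"))
  expect_false(rs$paired)

  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">p1", "ACGTAC", ">p2", "GGGTTT"), fa1)
  writeLines(c(">p1", "TTTCCC", ">p2", "AAACCC"), fa2)
  pe <- read_sequences(fa1, mate2 = fa2)
  expect_true(pe$paired)
  expect_null(pe$qual1)
  expect_equal(pe$seq2[1], "TTTCCC")

  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(">only", "AAAA"), fa3)
  expect_error(read_sequences(fa1, mate2 = fa3), "record counts")

  bad <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad)
  expect_error(read_sequences(bad))
})

test_that("scan enumeration equals a brute-force character oracle", {
  ts <- tiny_ts()
  set.seed(8)
  brute <- function(read, seed_len, mm) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(read)))
    out <- NULL
    for (t in seq_along(ts$seq)) {
      sq <- strsplit(ts$seq[t], "")[[1]]
      L <- nchar(read)
      for (p in 0:(length(sq) - L)) {
        for (o in 0:1) {
          q <- strsplit(if (o == 0) read else rc, "")[[1]]
          nmm <- sum(q[1:seed_len] != sq[p + 1:seed_len])
          if (nmm <= mm) out <- rbind(out, data.frame(tid = t, pos = p,
                                                      orient = o))
        }
      }
    }
    out
  }
  for (k in 1:5) {
    t0 <- sample(3, 1)
    p0 <- sample(0:(ts$length[t0] - 30), 1)
    read <- substr(ts$seq[t0], p0 + 1, p0 + 30)
    if (k %% 2 == 0) {  # corrupt two seed bases
      substr(read, 3, 3) <- "A"
      substr(read, 11, 11) <- "C"
    }
    got <- enumerate_alignments(read, ts, seed_length = 20, max_mismatch = 2)
    want <- brute(read, 20, 2)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("indexed aligner agrees with the scan on clean reads", {
  ts <- tiny_ts()
  set.seed(10)
  starts <- sample(0:80, 12, replace = TRUE)
  tids <- sample(3, 12, replace = TRUE)
  orient <- sample(0:1, 12, replace = TRUE)
  reads <- exact_reads(ts, tids, starts, len = 30, orient = orient)
  aset <- align_reads(reads, ts, seed_len = 25, max_mm = 2)
  for (r in seq_len(12)) {
    want <- enumerate_alignments(reads$seq1[r], ts, 25, 2)
    got <- aset$cand[aset$cand$read == r, c("tid", "pos", "orient")]
    expect_equal(got, want, ignore_attr = TRUE)
  }
  # the true origin is always among the candidates
  own <- mapply(function(r, t, p, o) {
    any(aset$cand$read == r & aset$cand$tid == t & aset$cand$pos == p &
          aset$cand$orient == o)
  }, seq_len(12), tids, starts, orient)
  expect_true(all(own))
})

test_that("read with a duplicated site gets both alignments", {
  block <- rand_dna(30, seed = 2)
  ts <- transcript_set(paste0(block, rand_dna(40), block), "t")
  hits <- enumerate_alignments(substr(block, 1, 25), ts, 25, 0)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$pos, c(0, 70))
})

test_that("filters exclude highly multi-mapping and poly(A)-like reads", {
  # 200 transcripts each containing the same 25-mer once
  probe <- rand_dna(25, seed = 3)
  seqs <- vapply(seq_len(200), function(i)
    paste0(rand_dna(10), probe, rand_dna(10)), "")
  ts <- transcript_set(seqs, sprintf("t%03d", seq_len(200)))
  reads <- read_set(c(probe, strrep("A", 25), rand_dna(25, seed = 4)))
  aset <- align_reads(reads, ts, seed_len = 25, max_mm = 0, max_hits = 500)
  aset <- filter_reads(aset, max_alignments = 200, polya_fraction = 0.9)
  expect_equal(aset$filtered[1], "too_many_alignments")  # exactly 200
  expect_equal(aset$filtered[2], "polya_like")
  expect_equal(aset$filtered[3], "none")
  expect_false(any(aset$cand$read %in% c(1, 2)))

  # 199 alignments are retained
  ts199 <- transcript_set(seqs[1:199], sprintf("t%03d", 1:199))
  a199 <- filter_reads(align_reads(read_set(probe), ts199, 25, 0, 500),
                       200, 0.9)
  expect_equal(a199$filtered[1], "none")
  expect_equal(sum(a199$cand$read == 1), 199)
  # poly(T) (antisense) is filtered as well
  aT <- filter_reads(align_reads(read_set(strrep("T", 25)), ts199, 25, 0),
                     200, 0.9)
  expect_equal(aT$filtered[1], "polya_like")
})

test_that("SAM parsing converts coordinates and joins mates", {
  ts <- transcript_set(c(rand_dna(100, seed = 5), rand_dna(80)),
                       c("tx1", "tx2"))
  sam <- tempfile(fileext = ".sam")
  r1 <- substr(ts$seq[1], 1, 20)
  r2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ts$seq[1], 31, 50))))
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", ts$id, ts$length),
    paste("p1", 99, "tx1", 1, 255, "20M", "=", 31, 50, r1,
          strrep("I", 20), sep = "\t"),
    paste("p1", 147, "tx1", 31, 255, "20M", "=", 1, -50,
          r2rc, strrep("I", 20), sep = "\t")), sam)
  aset <- parse_sam(sam, ts)
  expect_equal(nrow(aset$cand), 1)
  expect_equal(aset$cand$pos, 0)        # POS 1 -> 0-based 0
  expect_equal(aset$cand$orient, 0)
  expect_equal(aset$cand$flen, 50)      # rightmost end - leftmost start
  expect_true(aset$reads$paired)

  # single-end with an unmapped read retained
  sam2 <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", ts$id, ts$length),
    paste("s1", 16, "tx2", 5, 255, "20M", "*", 0, 0,
          substr(ts$seq[2], 5, 24), strrep("I", 20), sep = "\t"),
    paste("s2", 4, "*", 0, 0, "*", "*", 0, 0, rand_dna(20),
          strrep("I", 20), sep = "\t")), sam2)
  aset2 <- parse_sam(sam2, ts)
  expect_equal(n_reads(aset2$reads), 2)
  expect_equal(aset2$cand$pos, 4)
  expect_equal(aset2$cand$orient, 1)
  expect_equal(aset2$nhits, c(1L, 0L))  # unmapped read kept, no candidates
})

test_that("unknown SAM reference names are an error", {
  ts <- transcript_set("ACGTACGTACGT", "tx1")
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:other\tLN:50",
               paste("r", 0, "other", 1, 255, "4M", "*", 0, 0, "ACGT",
                     "IIII", sep = "\t")), sam)
  expect_error(parse_sam(sam, ts), "absent")
})
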