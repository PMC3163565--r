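#' First-order Markov chain model of quality score strings
#'
#' Quality strings are simulated with a homogeneous first-order Markov
#' chain: an initial distribution over Phred scores for the first read
#' position and a transition matrix between successive positions.
#'
#' @param init named numeric vector: probability of each starting score
#'   (names are integer Phred values).
#' @param trans square transition matrix (rows = current score, columns =
#'   next score, row-stochastic) with the same score names.
#' @return an object of class `quality_markov`.
#' @export
quality_markov <- function(init, trans) {
  stopifnot(is.numeric(init), is.matrix(trans),
            length(init) == nrow(trans), nrow(trans) == ncol(trans),
            all(init >= 0), all(trans >= 0))
  init <- init / sum(init)
  trans <- trans / rowSums(trans)
  if (is.null(names(init))) stop("scores must be named with Phred values")
  structure(list(init = init, trans = trans,
                 scores = as.integer(names(init))),
            class = "quality_markov")
}

#' @export
print.quality_markov <- function(x, ...) {
  cat(sprintf("<quality_markov: %d scores in [%d, %d]>\n",
              length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Fit the quality-score Markov chain from FASTQ data
#'
#' Estimates the initial distribution from first-position scores and the
#' transition matrix from all adjacent-position score pairs, with add-one
#' smoothing over the observed score range.
#'
#' @param x a FASTQ path or a [read_set()] with quality strings.
#' @return a [quality_markov()].
#' @export
fit_quality_markov <- function(x) {
  if (is.character(x)) x <- read_sequences(x, format = "fastq")
  quals <- c(x$qual1, x$qual2)
  if (is.null(quals) || length(quals) == 0) {
    stop("no quality data to fit")
  }
  enc <- cpp_encode_quals(quals, 33L)
  codes <- enc$codes
  off <- enc$offsets
  lens <- diff(off)
  if (any(lens == 0)) stop("empty quality strings")
  rng <- range(codes)
  ns <- rng[2] - rng[1] + 1L
  first <- codes[off[-length(off)] + 1L]
  init <- tabulate(first - rng[1] + 1L, ns) + 1
  from <- codes[-cumsum(lens)]          # drop last position of each string
  to <- codes[-(off[-length(off)] + 1L)] # drop first position of each string
  trans <- matrix(1, ns, ns)
  if (length(from) > 0) {
    tt <- table(factor(from - rng[1] + 1L, levels = seq_len(ns)),
                factor(to - rng[1] + 1L, levels = seq_len(ns)))
    trans <- trans + unclass(tt)
  }
  sc <- as.character(seq.int(rng[1], rng[2]))
  names(init) <- sc
  dimnames(trans) <- list(sc, sc)
  quality_markov(init, trans)
}

#' Built-in default quality chain
#'
#' A generic Illumina-like chain: qualities start high (around Q38) and
#' drift slowly downwards along the read with occasional dips, giving
#' theoretical per-base error rates of roughly 0.1-1%.  Used when no real
#' training data is supplied.
#'
#' @return a [quality_markov()].
#' @export
default_quality_markov <- function() {
  scores <- 2:40
  ns <- length(scores)
  init <- dnorm(scores, 38, 1.5)
  trans <- outer(scores, scores, function(a, b)
    dnorm(b, a - 0.25, 1.2) + 0.002 * dnorm(b, 15, 4))
  dimnames(trans) <- list(scores, scores)
  names(init) <- scores
  quality_markov(init, trans)
}

# simulate n quality strings of length len (returns integer matrix n x len)
simulate_markov_quals <- function(qm, n, len) {
  ns <- length(qm$scores)
  out <- matrix(0L, n, len)
  cur <- sample.int(ns, n, replace = TRUE, prob = qm$init)
  out[, 1] <- cur
  if (len > 1) {
    for (j in 2:len) {
      nxt <- integer(n)
      for (s in unique(cur)) {
        sel <- cur == s
        nxt[sel] <- sample.int(ns, sum(sel), replace = TRUE,
                               prob = qm$trans[s, ])
      }
      out[, j] <- nxt
      cur <- nxt
    }
  }
  matrix(qm$scores[out], n, len)
}

#' Simulate RNA-Seq reads from the generative model
#'
#' Draws fragments from the model: a source transcript from `theta` (the
#' component 0 share produces noise reads from the background
#' composition), a fragment length from the truncated fragment length
#' distribution, a start from the RSPD, and an orientation; emits the
#' fragment's 5' read (and, for paired data, the reverse complement of its
#' 3' end), generates quality strings from the Markov chain, and injects
#' substitution errors either at the theoretical Phred rate
#' `10^(-q/10)` (uniform among wrong bases) or from the model's learned
#' error table (`"empirical"`).
#'
#' @param params a [model_params()] with `theta` set (length M+1, noise
#'   first).
#' @param ts the [transcript_set()].
#' @param n_reads number of fragments to simulate.
#' @param paired emit read pairs.
#' @param read_len read length in bases.
#' @param qmodel a [quality_markov()] (`NULL` simulates error-free reads
#'   with flat maximal qualities).
#' @param error_mode `"theoretical"` or `"empirical"`.
#' @param out_prefix if non-`NULL`, write `<prefix>.fq` (`_1.fq`/`_2.fq`
#'   for pairs) and `<prefix>_truth.tsv`.
#' @return a list with `reads` (a [read_set()]) and `truth` (data frame:
#'   `read_id`, `tid` (0 = noise), `transcript_id`, `flen`, `start`,
#'   `orient`).
#' @export
simulate_dataset <- function(params, ts, n_reads, paired = FALSE,
                             read_len = 35,
                             qmodel = default_quality_markov(),
                             error_mode = c("theoretical", "empirical"),
                             out_prefix = NULL) {
  error_mode <- match.arg(error_mode)
  theta <- params$theta
  if (is.null(theta)) stop("params$theta is not set")
  M <- n_transcripts(ts)
  stopifnot(length(theta) == M + 1)
  n <- as.integer(n_reads)
  tid <- sample.int(M + 1, n, replace = TRUE, prob = theta) - 1L

  flen <- integer(n)
  start <- integer(n)
  orient <- integer(n)
  fd <- params$frag_dist
  for (i in unique(tid[tid > 0])) {
    sel <- which(tid == i)
    tl <- ts$length[i]
    d <- truncate_length_pmf(fd, tl)
    if (length(d$pmf) == 0) {
      stop(sprintf("transcript %s (length %d) shorter than any supported fragment",
                   ts$id[i], tl))
    }
    f <- d$min - 1L +
      sample.int(length(d$pmf), length(sel), replace = TRUE, prob = d$pmf)
    f <- pmax(f, min(read_len, tl))   # a fragment must carry the read
    if (length(params$rspd) == 1) {   # uniform RSPD fast path
      start[sel] <- as.integer(floor(runif(length(sel)) * (tl - f + 1L)))
    } else {
      for (fl in unique(f)) {
        s2 <- sel[f == fl]
        npos <- tl - fl + 1L
        pp <- rspd_position_probs(params$rspd, npos)
        start[s2] <- sample.int(npos, length(s2), replace = TRUE,
                                prob = pp) - 1L
      }
    }
    flen[sel] <- f
  }
  orient <- if (params$strand_specific) rep(0L, n)
            else sample(0:1, n, replace = TRUE)

  # read windows (read 1 = fragment 5' end; read 2 = revcomp of 3' end)
  seq1 <- character(n)
  seq2 <- if (paired) character(n) else NULL
  tx <- tid > 0
  if (any(tx)) {
    w1s <- ifelse(orient == 0L, start, start + flen - read_len)
    r1 <- substring(ts$seq[tid[tx]], w1s[tx] + 1L, w1s[tx] + read_len)
    rev1 <- orient[tx] == 1L
    r1[rev1] <- cpp_revcomp(r1[rev1])
    seq1[tx] <- r1
    if (paired) {
      w2s <- ifelse(orient == 0L, start + flen - read_len, start)
      r2 <- substring(ts$seq[tid[tx]], w2s[tx] + 1L, w2s[tx] + read_len)
      rev2 <- orient[tx] == 0L
      r2[rev2] <- cpp_revcomp(r2[rev2])
      seq2[tx] <- r2
    }
  }
  if (any(!tx)) {
    bg <- params$noise_background
    mk <- function(k) {
      m <- matrix(sample(BASES, k * read_len, replace = TRUE, prob = bg),
                  k, read_len)
      apply(m, 1, paste, collapse = "")
    }
    seq1[!tx] <- mk(sum(!tx))
    if (paired) seq2[!tx] <- mk(sum(!tx))
  }

  qual1 <- qual2 <- NULL
  if (!is.null(qmodel)) {
    qm1 <- simulate_markov_quals(qmodel, n, read_len)
    seq1 <- inject_errors(seq1, qm1, params, error_mode)
    qual1 <- qual_strings(qm1)
    if (paired) {
      qm2 <- simulate_markov_quals(qmodel, n, read_len)
      seq2 <- inject_errors(seq2, qm2, params, error_mode)
      qual2 <- qual_strings(qm2)
    }
  }
  ids <- sprintf("sim%07d", seq_len(n))
  reads <- read_set(seq1, ids, qual1, seq2, qual2)
  truth <- data.frame(read_id = ids, tid = tid,
                      transcript_id = c("*", ts$id)[tid + 1L],
                      flen = ifelse(tx, flen, NA_integer_),
                      start = ifelse(tx, start, NA_integer_),
                      orient = ifelse(tx, orient, NA_integer_))
  if (!is.null(out_prefix)) {
    write_reads_file(reads, out_prefix)
    write.table(truth, paste0(out_prefix, "_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}

qual_strings <- function(qmat) {
  apply(qmat, 1, function(q) rawToChar(as.raw(q + 33L)))
}

# substitution errors, vectorized over an integer-coded base matrix
inject_errors <- function(seqs, qmat, params, error_mode) {
  n <- length(seqs)
  len <- ncol(qmat)
  codes <- matrix(cpp_encode_seqs(seqs)$codes, n, len, byrow = TRUE)
  if (error_mode == "theoretical") {
    perr <- matrix(10^(-qmat / 10), n, len)
    hit <- matrix(runif(n * len), n, len) < perr
    k <- sum(hit)
    if (k > 0) {
      shift <- sample.int(3, k, replace = TRUE)
      codes[hit] <- (codes[hit] + shift) %% 4L
    }
  } else {
    em <- params$error
    if (em$type != "quality") {
      stop("empirical error injection requires a quality error model")
    }
    K1 <- dim(em$eps)[1]
    key <- pmin(pmax(as.vector(qmat), 0L), K1 - 1L) + 1L
    cc <- as.vector(codes)
    out <- cc
    grp <- key * 5L + cc
    for (g in unique(grp)) {
      sel <- which(grp == g)
      c0 <- cc[sel[1]]
      if (c0 > 3L) next
      p <- em$eps[key[sel[1]], c0 + 1L, ]
      out[sel] <- sample.int(4, length(sel), replace = TRUE, prob = p) - 1L
    }
    codes <- matrix(out, n, len)
  }
  decode_mat(codes)
}

decode_mat <- function(codes) {
  ch <- c("A", "C", "G", "T", "N")[pmin(codes, 4L) + 1L]
  m <- matrix(ch, nrow(codes), ncol(codes))
  do.call(paste0, as.data.frame(m))
}

write_reads_file <- function(reads, prefix) {
  emit <- function(seqs, quals, ids, path) {
    if (is.null(quals)) {
      writeLines(paste0(">", ids, "\n", seqs), path)
    } else {
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
    }
  }
  ext <- if (is.null(reads$qual1)) ".fa" else ".fq"
  if (reads$paired) {
    emit(reads$seq1, reads$qual1, reads$id, paste0(prefix, "_1", ext))
    emit(reads$seq2, reads$qual2, reads$id, paste0(prefix, "_2", ext))
  } else {
    emit(reads$seq1, reads$qual1, reads$id, paste0(prefix, ext))
  }
  invisible(prefix)
}
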