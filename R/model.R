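#' Generative read model parameters
#'
#' Bundles everything needed to score or simulate a read (pair): the
#' component probabilities `theta` (position 1 is the noise component,
#' positions `2..M+1` the transcripts), the global fragment and read
#' length distributions, the read start position distribution (RSPD), the
#' sequencing error model, strand specificity, and the background base
#' composition of noise reads.
#'
#' @param theta numeric vector of `M + 1` probabilities summing to one
#'   (noise first); `NULL` leaves it unset until estimation.
#' @param frag_dist fragment [length_dist()].
#' @param read_dist read [length_dist()] (a point mass for fixed-length
#'   reads).
#' @param rspd numeric vector of RSPD bin weights over relative start
#'   position in `[0, 1)`; a single bin is the uniform RSPD.
#' @param error an `error_model` (see [quality_error_model()]).
#' @param strand_specific if `TRUE`, fragments are only sequenced in
#'   forward orientation (`P(o) = 1`); otherwise each orientation has
#'   probability 1/2.
#' @param noise_background per-base emission probabilities (A, C, G, T)
#'   for noise reads.
#' @return an object of class `model_params`.
#' @export
model_params <- function(theta = NULL,
                         frag_dist = gaussian_length_dist(),
                         read_dist = point_length_dist(35),
                         rspd = 1,
                         error = quality_error_model(),
                         strand_specific = FALSE,
                         noise_background = rep(0.25, 4)) {
  if (!is.null(theta)) {
    stopifnot(all(theta >= 0), abs(sum(theta) - 1) < 1e-8)
  }
  stopifnot(inherits(frag_dist, "length_dist"),
            inherits(read_dist, "length_dist"),
            inherits(error, "error_model"),
            length(noise_background) == 4, all(noise_background >= 0),
            all(rspd >= 0), sum(rspd) > 0)
  structure(list(theta = theta, frag_dist = frag_dist,
                 read_dist = read_dist, rspd = rspd / sum(rspd),
                 error = error, strand_specific = isTRUE(strand_specific),
                 noise_background = noise_background / sum(noise_background)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params: %s, fragments [%d, %d], reads [%d, %d], %d RSPD bins, %s error model>\n",
    if (x$strand_specific) "strand-specific" else "unstranded",
    x$frag_dist$min, x$frag_dist$max, x$read_dist$min, x$read_dist$max,
    length(x$rspd), x$error$type))
  invisible(x)
}

#' Read start position probability under a binned RSPD
#'
#' Maps a fragment start offset to its relative position among the
#' `n_starts` possible starts and returns the probability of that start:
#' each bin's weight is split evenly among the positions falling in the
#' bin, renormalized so the `n_starts` positions sum to one.  A uniform
#' RSPD gives `1 / n_starts`.
#'
#' @param rspd numeric vector of bin weights.
#' @param start 0-based start offset, `0 <= start < n_starts`.
#' @param n_starts number of feasible start positions.
#' @return a probability; `rspd_position_probs()` returns the whole vector
#'   of length `n_starts`.
#' @export
rspd_start_prob <- function(rspd, start, n_starts) {
  stopifnot(start >= 0, start < n_starts)
  cpp_rspd_positions(rspd / sum(rspd), as.integer(n_starts))[start + 1L]
}

#' @rdname rspd_start_prob
#' @export
rspd_position_probs <- function(rspd, n_starts) {
  cpp_rspd_positions(rspd / sum(rspd), as.integer(n_starts))
}

#' Joint weight of a read (pair) under a latent alignment
#'
#' The probability of observing the read (pair) given that its fragment
#' comes from the aligned transcript at the aligned position and
#' orientation -- the product of the orientation probability, the
#' truncated fragment length mass, the RSPD start probability, the
#' truncated read length mass(es), and the sequencing error model emission
#' probability of each mate.  For single-end reads the fragment length is
#' latent and is marginalized over all feasible values.  The `theta`
#' factor is *not* included; callers multiply it in.
#'
#' @param params a [model_params()].
#' @param read a [read_set()] of (at least) one read, or a list with
#'   fields `seq1`, `qual1`, `seq2`, `qual2`.
#' @param aln a list or one-row data frame with fields `tid`, `pos`,
#'   `orient` and, for paired reads, `flen`.
#' @param ts the [transcript_set()].
#' @param read_index which read of `read` to score.
#' @return a probability (0 for infeasible alignments).
#' @export
alignment_weight <- function(params, read, aln, ts, read_index = 1) {
  i <- read_index
  s1 <- read$seq1[i]
  L1 <- nchar(s1)
  tid <- aln$tid
  tl <- ts$length[tid]
  pos <- as.integer(aln$pos)
  orient <- as.integer(aln$orient)
  paired <- isTRUE(read$paired) || (!is.null(read$seq2) && !is.na(read$seq2[i]))
  if (pos < 0 || pos + L1 > tl) return(0)
  emis <- function(rs, qs, ref) read_emission_prob(params, rs, qs, ref)
  q1 <- if (!is.null(read$qual1)) read$qual1[i] else NULL
  if (!paired) {
    pf <- cpp_se_pos_factors(tl, pos, orient, L1,
                             params$frag_dist$min, params$frag_dist$pmf,
                             params$read_dist$min, params$read_dist$pmf,
                             params$rspd, params$strand_specific)
    ref <- substr(ts$seq[tid], pos + 1L, pos + L1)
    if (orient == 1L) ref <- cpp_revcomp(ref)
    return(pf * emis(s1, q1, ref))
  }
  flen <- as.integer(aln$flen)
  s2 <- read$seq2[i]
  L2 <- nchar(s2)
  q2 <- if (!is.null(read$qual2)) read$qual2[i] else NULL
  if (pos + flen > tl) return(0)
  pf <- cpp_pe_pos_factors(tl, pos, flen, orient, L1, L2,
                           params$frag_dist$min, params$frag_dist$pmf,
                           params$read_dist$min, params$read_dist$pmf,
                           params$rspd, params$strand_specific)
  # mate windows on the transcript for this orientation
  p1 <- if (orient == 0L) pos else pos + flen - L1
  p2 <- if (orient == 0L) pos + flen - L2 else pos
  r1 <- substr(ts$seq[tid], p1 + 1L, p1 + L1)
  r2 <- substr(ts$seq[tid], p2 + 1L, p2 + L2)
  if (orient == 0L) r2 <- cpp_revcomp(r2) else r1 <- cpp_revcomp(r1)
  pf * emis(s1, q1, r1) * emis(s2, q2, r2)
}

#' Noise-read weight
#'
#' The probability of a read under the noise component: the product over
#' its positions of the background base emission, times the (marginal)
#' read length mass.  Transcript-independent; multiplied by `theta_0` in
#' the mixture.
#'
#' @param params a [model_params()].
#' @param read a [read_set()] (or compatible list).
#' @param read_index which read to score.
#' @return a probability.
#' @export
noise_weight <- function(params, read, read_index = 1) {
  bg <- params$noise_background
  mn <- min(bg[bg > 0])
  w <- 1
  for (s in c(read$seq1[read_index],
              if (isTRUE(read$paired)) read$seq2[read_index])) {
    codes <- encode_one(s)
    p <- ifelse(codes > 3, mn, bg[codes + 1L])
    w <- w * prod(p) * dist_mass(params$read_dist, nchar(s))
  }
  w
}

# ---- serialization ---------------------------------------------------------

#' Write or read model parameters as a text file
#'
#' Serializes a [model_params()] object to a sectioned, human-readable
#' text file so that a learned model can be inspected and re-used to
#' simulate data (the learn-then-simulate workflow).
#'
#' @param params a [model_params()].
#' @param path file path.
#' @return `read_model()` returns the reconstructed [model_params()].
#' @export
write_model <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  wl <- function(...) writeLines(paste0(...), con)
  wl("# generative read model parameters")
  wl("[strand_specific] ", as.integer(params$strand_specific))
  wl("[frag_dist] ", params$frag_dist$min)
  wl(num(params$frag_dist$pmf))
  wl("[read_dist] ", params$read_dist$min)
  wl(num(params$read_dist$pmf))
  wl("[rspd]")
  wl(num(params$rspd))
  wl("[noise_background]")
  wl(num(params$noise_background))
  if (!is.null(params$theta)) {
    wl("[theta]")
    wl(num(params$theta))
  }
  wl("[error] ", params$error$type, " ", dim(params$error$eps)[1])
  for (k in seq_len(dim(params$error$eps)[1])) {
    wl(num(as.vector(params$error$eps[k, , ])))
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  vals <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  i <- 1
  fields <- list()
  while (i <= length(lines)) {
    hdr <- lines[i]
    if (!grepl("^\\[", hdr)) stop("malformed model file near: ", hdr)
    tag <- sub("^\\[([a-z_]+)\\].*$", "\\1", hdr)
    arg <- trimws(sub("^\\[[a-z_]+\\]", "", hdr))
    if (tag == "strand_specific") {
      fields$strand_specific <- as.integer(arg) == 1
      i <- i + 1
    } else if (tag %in% c("frag_dist", "read_dist")) {
      fields[[tag]] <- length_dist(as.integer(arg), vals(lines[i + 1]))
      i <- i + 2
    } else if (tag %in% c("rspd", "noise_background", "theta")) {
      fields[[tag]] <- vals(lines[i + 1])
      i <- i + 2
    } else if (tag == "error") {
      a <- strsplit(arg, "\\s+")[[1]]
      type <- a[1]
      nk <- as.integer(a[2])
      eps <- array(0, dim = c(nk, 4, 4), dimnames = list(NULL, BASES, BASES))
      for (k in seq_len(nk)) eps[k, , ] <- vals(lines[i + k])
      cls <- if (type == "quality") "quality_error_model" else "profile_error_model"
      fields$error <- structure(list(eps = eps, type = type),
                                class = c(cls, "error_model"))
      i <- i + nk + 1
    } else {
      stop("unknown model file section: ", tag)
    }
  }
  model_params(theta = fields$theta, frag_dist = fields$frag_dist,
               read_dist = fields$read_dist, rspd = fields$rspd,
               error = fields$error,
               strand_specific = fields$strand_specific,
               noise_background = fields$noise_background)
}
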