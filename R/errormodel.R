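#' Sequencing error models
#'
#' Two substitution error models are supported, matching the two ways the
#' emission probability of a read character can be conditioned:
#'
#' * the **quality model** `quality_error_model()`: the probability
#'   `eps(r | q, c)` of observing read character `r` given the Phred
#'   quality score `q` at that position and the reference character `c`;
#' * the **profile model** `profile_error_model()`: the probability of the
#'   observed character given the *read position* and the reference
#'   character, for data whose quality scores are absent or unreliable.
#'
#' Both are stored as 3-dimensional arrays `[key, c, r]` over the four
#' bases, where `key` indexes quality scores (0-based) or read positions
#' (1-based).  Rows `(key, c)` sum to one.  Tables are typically
#' re-estimated during expectation-maximization from responsibility-
#' weighted character confusion counts with add-one smoothing.
#'
#' `'N'` characters in a read or reference never match: their emission
#' probability is the smallest positive mass in the model, so alignments
#' through `N` are penalized but never impossible.
#'
#' @param max_qual number of quality score values modelled (scores are
#'   clamped to `max_qual - 1`).
#' @param init for the quality model, `"phred"` initializes from the
#'   theoretical Phred relationship (error probability `10^(-q/10)`,
#'   split evenly among the three wrong bases).
#' @param error_rate flat initial per-base error rate for the profile model.
#' @param read_len number of read positions modelled by the profile model.
#' @return an object of class `error_model` with subtype
#'   `quality_error_model` or `profile_error_model`.
#' @export
quality_error_model <- function(max_qual = 64, init = "phred") {
  q <- seq_len(max_qual) - 1
  e <- pmin(0.75, 10^(-q / 10))
  eps <- array(0, dim = c(max_qual, 4, 4),
               dimnames = list(NULL, BASES, BASES))
  for (cc in 1:4) for (rr in 1:4) {
    eps[, cc, rr] <- if (cc == rr) 1 - e else e / 3
  }
  structure(list(eps = eps, type = "quality"),
            class = c("quality_error_model", "error_model"))
}

#' @rdname quality_error_model
#' @export
profile_error_model <- function(read_len, error_rate = 0.01) {
  eps <- array(error_rate / 3, dim = c(read_len, 4, 4),
               dimnames = list(NULL, BASES, BASES))
  for (b in 1:4) eps[, b, b] <- 1 - error_rate
  structure(list(eps = eps, type = "profile"),
            class = c("profile_error_model", "error_model"))
}

BASES <- c("A", "C", "G", "T")

# smallest positive emission mass (used for N characters)
error_model_min <- function(em) {
  p <- em$eps[em$eps > 0]
  if (length(p) == 0) stop("error model has no positive mass")
  min(p)
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<%s error model, %d %s levels>\n", x$type, dim(x$eps)[1],
              if (x$type == "quality") "quality" else "position"))
  invisible(x)
}

#' Emission probability of a read against a reference sequence
#'
#' The product over read positions of the per-character emission
#' probability under the model's error table: `eps(r_i | q_i, c_i)` for the
#' quality model, or the position/reference-conditioned probability for the
#' profile model.  This is the error-model factor of an alignment's weight.
#'
#' @param params a [model_params()] object (its `error` field is used).
#' @param read_seq,ref_seq equal-length character strings (A/C/G/T/N).
#' @param quals Phred+33 quality string; required by the quality model and
#'   ignored by the profile model.
#' @return a probability.
#' @export
read_emission_prob <- function(params, read_seq, quals = NULL, ref_seq) {
  em <- params$error
  r <- encode_one(read_seq)
  c_ <- encode_one(ref_seq)
  if (length(r) != length(c_)) stop("read and reference lengths differ")
  if (em$type == "quality") {
    if (is.null(quals)) stop("quality model requires quality scores")
    key <- pmin(utf8ToInt(quals) - 33L, dim(em$eps)[1] - 1L) + 1L
    if (length(key) != length(r)) stop("read and quality lengths differ")
  } else {
    key <- pmin(seq_along(r), dim(em$eps)[1])
  }
  mn <- error_model_min(em)
  p <- numeric(length(r))
  for (i in seq_along(r)) {
    p[i] <- if (r[i] > 3 || c_[i] > 3) mn else em$eps[key[i], c_[i] + 1L, r[i] + 1L]
  }
  prod(p)
}

encode_one <- function(s) {
  chartr2 <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  out <- unname(chartr2[v])
  out[is.na(out)] <- 4L
  out
}
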