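#' Discrete length distributions
#'
#' A `length_dist` is a probability mass function over an integer range of
#' lengths (in bases), used for both the global fragment length
#' distribution and the global read length distribution of the generative
#' read model.  When conditioned on a transcript (or fragment) of finite
#' length the distribution is truncated at that length and renormalized;
#' see [truncate_length_pmf()].
#'
#' @param min_len smallest length with positive support (>= 1).
#' @param pmf numeric vector of masses for lengths `min_len`,
#'   `min_len + 1`, ...; normalized to sum to one.
#' @return an object of class `length_dist` with fields `min`, `max` and
#'   `pmf`.
#' @examples
#' length_dist(1, rep(1, 10))        # uniform on 1..10
#' point_length_dist(35)             # fixed-length reads
#' @export
length_dist <- function(min_len, pmf) {
  min_len <- as.integer(min_len)
  stopifnot(min_len >= 1L, length(pmf) >= 1L, all(pmf >= 0))
  s <- sum(pmf)
  if (s <= 0) stop("length distribution has no positive mass")
  structure(list(min = min_len, max = min_len + length(pmf) - 1L,
                 pmf = as.numeric(pmf) / s),
            class = "length_dist")
}

#' @rdname length_dist
#' @param len the single supported length.
#' @export
point_length_dist <- function(len) length_dist(len, 1)

#' Discretized Gaussian fragment length distribution
#'
#' The conventional prior for fragment lengths: a Gaussian discretized on
#' the integers and truncated below at `min_len`.  The library default
#' (mean 280, sd 17) describes a typical size-selected Illumina library.
#'
#' @param mean,sd Gaussian parameters in bases.
#' @param min_len lower truncation (>= 1).
#' @param max_len upper end of the support; defaults to `mean + 4 sd`.
#' @return a [length_dist()].
#' @export
gaussian_length_dist <- function(mean = 280, sd = 17, min_len = 1,
                                 max_len = NULL) {
  if (is.null(max_len)) max_len <- ceiling(mean + 4 * sd)
  min_len <- max(1L, as.integer(min_len))
  lens <- seq.int(min_len, max_len)
  length_dist(min_len, dnorm(lens, mean, sd) + 1e-300)
}

#' Truncate and renormalize a length distribution
#'
#' Restricts the support to lengths `<= limit` and renormalizes, which is
#' how the global fragment length distribution is conditioned on a
#' transcript of finite length (and the read length distribution on a
#' fragment length).  If no supported length is `<= limit` the empty
#' distribution is returned (all dependent weights become zero).
#'
#' @param d a [length_dist()].
#' @param limit maximum length (>= 1).
#' @return a `length_dist`; the empty distribution has a zero-length `pmf`.
#' @export
truncate_length_pmf <- function(d, limit) {
  stopifnot(inherits(d, "length_dist"), limit >= 1)
  limit <- as.integer(limit)
  if (limit < d$min) {
    return(structure(list(min = d$min, max = d$min - 1L, pmf = numeric(0)),
                     class = "length_dist"))
  }
  keep <- seq_len(min(limit, d$max) - d$min + 1L)
  p <- d$pmf[keep]
  s <- sum(p)
  if (s <= 0) {
    return(structure(list(min = d$min, max = d$min - 1L, pmf = numeric(0)),
                     class = "length_dist"))
  }
  structure(list(min = d$min, max = d$min + length(p) - 1L, pmf = p / s),
            class = "length_dist")
}

# mass at a given length (0 outside the support)
dist_mass <- function(d, len) {
  ifelse(len >= d$min & len <= d$max, d$pmf[pmax(1L, len - d$min + 1L)], 0)
}

dist_mean <- function(d) {
  if (length(d$pmf) == 0) return(NA_real_)
  sum(seq.int(d$min, d$max) * d$pmf)
}

#' @export
print.length_dist <- function(x, ...) {
  if (length(x$pmf) == 0) {
    cat("<length_dist: empty>\n")
  } else {
    cat(sprintf("<length_dist on [%d, %d], mean %.2f>\n", x$min, x$max,
                dist_mean(x)))
  }
  invisible(x)
}

# empirical pmf of observed lengths
empirical_length_dist <- function(lens) {
  lens <- as.integer(lens)
  rng <- range(lens)
  length_dist(rng[1], tabulate(lens - rng[1] + 1L, rng[2] - rng[1] + 1L))
}
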