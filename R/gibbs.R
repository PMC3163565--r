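#' Configuration of the two-stage posterior sampler
#'
#' @param n_count_vectors number of count vectors sampled by the collapsed
#'   Gibbs sampler (one per recorded sweep).
#' @param theta_per_vector number of Dirichlet draws of `theta` per count
#'   vector (the defaults give 1000 x 50 = 50,000 `theta` samples).
#' @param burn_in burn-in sweeps before recording; the chain starts from
#'   the maximum-likelihood responsibilities, so a short burn-in suffices.
#' @param thin record one count vector every `thin` sweeps.
#' @param alpha symmetric Dirichlet prior concentration; 1 makes the prior
#'   uniform and the posterior mode equal to the ML estimate.
#' @param credibility credibility level of the reported intervals.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(n_count_vectors = 1000, theta_per_vector = 50,
                           burn_in = 200, thin = 1, alpha = 1,
                           credibility = 0.95) {
  stopifnot(n_count_vectors > 0, theta_per_vector > 0, burn_in >= 0,
            thin >= 1, alpha > 0, credibility > 0, credibility < 1)
  structure(list(n_count_vectors = as.integer(n_count_vectors),
                 theta_per_vector = as.integer(theta_per_vector),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 alpha = alpha, credibility = credibility),
            class = "sampler_config")
}

#' Collapsed Gibbs sampling of fragment assignment count vectors
#'
#' Samples vectors of per-transcript fragment counts from the posterior of
#' the Bayesian model (Dirichlet prior on `theta`, `theta` integrated
#' out).  Each sweep resamples the latent assignment of every unfiltered
#' read conditional on all others, with probability proportional to
#' `(alpha + c_i) * w` over its candidate alignments (and the noise
#' outcome); the initial mapping is drawn from the maximum-likelihood
#' responsibilities.  Auxiliary parameters stay fixed at their ML values.
#'
#' @param ml an [run_em()] result.
#' @param cfg a [sampler_config()].
#' @return integer matrix with `n_count_vectors` rows and `M + 1` columns
#'   (noise component first); each row sums to the number of unfiltered
#'   reads.
#' @export
gibbs_count_vectors <- function(ml, cfg = sampler_config()) {
  stopifnot(inherits(ml, "ml_estimates"), inherits(cfg, "sampler_config"))
  comp <- ml$data
  res <- cpp_gibbs(comp$offsets, comp$cand_tid, comp$w, comp$noise_w,
                   comp$M, cfg$alpha, ml$theta, cfg$burn_in,
                   cfg$n_count_vectors, cfg$thin)
  counts <- res$counts
  colnames(counts) <- c("noise", ml$ids)
  counts
}

#' Sample theta vectors from count vectors
#'
#' Given a fragment count vector `c`, `theta` has posterior
#' `Dirichlet(c + alpha)`; `theta_per_vector` draws are taken per count
#' vector.
#'
#' @param cv count-vector matrix from [gibbs_count_vectors()].
#' @param cfg a [sampler_config()].
#' @return numeric matrix of `theta` samples
#'   (`n_count_vectors * theta_per_vector` rows, `M + 1` columns).
#' @export
theta_samples_from_counts <- function(cv, cfg = sampler_config()) {
  k <- cfg$theta_per_vector
  n <- nrow(cv) * k
  shape <- cv[rep(seq_len(nrow(cv)), each = k), , drop = FALSE] + cfg$alpha
  g <- matrix(rgamma(length(shape), shape = shape), nrow = n)
  g / rowSums(g)
}

#' Summarize posterior samples into PME and credibility intervals
#'
#' Converts each `theta` sample to transcript fractions (applying the same
#' repeat-pass de-biasing and effective-length normalization as the ML
#' estimate), then reports the posterior mean estimate (PME) and the
#' equal-tailed credibility interval of tau and TPM per transcript and per
#' gene.  Gene values are computed on the summed member fractions of each
#' sample, not by adding isoform interval endpoints.
#'
#' @param theta_samples matrix from [theta_samples_from_counts()].
#' @param ml the [run_em()] result (effective lengths, m, ids, gene map).
#' @param level credibility level in (0, 1).
#' @param return_tau also return the per-sample tau matrix (used for
#'   coverage analyses across several levels).
#' @return an object of class `posterior_summary` with data frames
#'   `isoform` and `gene` (columns `pme_tau`, `pme_tpm`, `ci_lower`,
#'   `ci_upper` in TPM), the level, and optionally `tau_samples`.
#' @export
summarize_posterior <- function(theta_samples, ml, level = 0.95,
                                return_tau = FALSE) {
  stopifnot(level > 0, level < 1)
  tau <- tau_samples_from_theta(theta_samples, ml)
  gene_of <- rep(names(ml$gene_map), lengths(ml$gene_map))
  memb <- match(unlist(ml$gene_map, use.names = FALSE), ml$ids)
  gmat <- matrix(0, length(ml$ids), length(ml$gene_map))
  gmat[cbind(memb, rep(seq_along(ml$gene_map), lengths(ml$gene_map)))] <- 1
  gtau <- tau %*% gmat
  colnames(gtau) <- names(ml$gene_map)
  summ <- function(x, ids) {
    pme <- colMeans(x)
    qs <- apply(x, 2, quantile, probs = c((1 - level) / 2,
                                          1 - (1 - level) / 2),
                names = FALSE)
    data.frame(id = ids, pme_tau = pme, pme_tpm = pme * 1e6,
               ci_lower = qs[1, ] * 1e6, ci_upper = qs[2, ] * 1e6,
               row.names = NULL)
  }
  out <- structure(list(isoform = summ(tau, ml$ids),
                        gene = summ(gtau, names(ml$gene_map)),
                        level = level),
                   class = "posterior_summary")
  if (return_tau) out$tau_samples <- tau
  out
}

# theta samples -> tau samples (de-bias by m, normalize by effective length)
tau_samples_from_theta <- function(theta_samples, ml) {
  adj <- 1 / (ml$m * pmax(ml$eff_len, .Machine$double.xmin))
  adj[ml$eff_len <= 0] <- 0
  x <- sweep(theta_samples[, -1, drop = FALSE], 2, adj, "*")
  sw <- rowSums(x)
  sw[sw <= 0] <- 1
  x / sw
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "<posterior_summary: %d transcripts, %d genes, %.0f%% credibility>\n",
    nrow(x$isoform), nrow(x$gene), 100 * x$level))
  invisible(x)
}
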