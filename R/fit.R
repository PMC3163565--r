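#' Quantify transcript and gene abundances from RNA-Seq reads
#'
#' The main fitting function.  Reads are aligned to the reference (with
#' the built-in all-hits aligner, or via a supplied SAM file /
#' [alignment_set()]), filtered for excessive multi-mapping and poly(A)
#' content, and quantified by expectation-maximization under the
#' generative read model.  With `ci = TRUE`, posterior mean estimates and
#' credibility intervals are added by two-stage collapsed Gibbs sampling.
#'
#' @param reads a [read_set()], or a path to a FASTA/FASTQ file (then
#'   `mate2` may name the second-mate file).
#' @param reference a [transcript_set()], or a path to a transcript FASTA.
#' @param alignments optional: a SAM/BAM path or an [alignment_set()];
#'   when `NULL` the built-in aligner is used.
#' @param ci compute posterior mean estimates and credibility intervals.
#' @param control a [quant_control()].
#' @param sampler a [sampler_config()].
#' @param polya_tail poly(A) tail length appended to the reference before
#'   alignment (0 disables; ignored when `reference` is already a
#'   `transcript_set`, which is used as supplied).
#' @param mate2 second-mate path when `reads` is a file path.
#' @param keep_samples keep the posterior tau sample matrix in the fit
#'   (needed for coverage analyses at several credibility levels).
#' @return an object of class `rnaquant_fit` with components `estimates`
#'   (see [run_em()]), `posterior` (a [summarize_posterior()] result or
#'   `NULL`), `reference`, `alignments`, `control`, `sampler`.
#' @seealso [coef.rnaquant_fit()], [summary.rnaquant_fit()],
#'   [simulate.rnaquant_fit()], [write_results()]
#' @export
quantify <- function(reads, reference, alignments = NULL, ci = FALSE,
                     control = quant_control(),
                     sampler = sampler_config(), polya_tail = 125,
                     mate2 = NULL, keep_samples = FALSE) {
  if (is.character(reference)) {
    reference <- load_reference(reference)
    if (polya_tail > 0) reference <- append_polya(reference, polya_tail)
  }
  stopifnot(inherits(reference, "transcript_set"))
  if (is.character(reads)) reads <- read_sequences(reads, mate2 = mate2)
  if (is.null(alignments)) {
    aset <- align_reads(reads, reference, control$seed_length,
                        control$seed_mismatches, control$max_alignments,
                        control$strand_specific)
  } else if (is.character(alignments)) {
    aset <- parse_sam(alignments, reference, reads)
  } else {
    aset <- alignments
  }
  aset <- filter_reads(aset, control$max_alignments,
                       control$polya_fraction)
  ml <- run_em(aset, reference, control)
  post <- NULL
  if (ci) {
    cv <- gibbs_count_vectors(ml, sampler)
    th <- theta_samples_from_counts(cv, sampler)
    post <- summarize_posterior(th, ml, level = sampler$credibility,
                                return_tau = keep_samples)
  }
  structure(list(estimates = ml, posterior = post, reference = reference,
                 alignments = aset, control = control, sampler = sampler,
                 call = match.call()),
            class = "rnaquant_fit")
}

#' @export
print.rnaquant_fit <- function(x, ...) {
  ml <- x$estimates
  nf <- sum(x$alignments$filtered != "none")
  cat("RNA-Seq abundance fit\n")
  cat(sprintf("  transcripts: %d (%d genes)\n", length(ml$tau),
              length(ml$gene_map)))
  cat(sprintf("  reads: %d total, %d filtered, %.1f expected noise\n",
              n_reads(x$alignments$reads), nf, ml$expected_counts[1]))
  cat(sprintf("  EM: %d iterations%s, logLik %.2f\n", ml$iterations,
              if (ml$converged) "" else " (not converged)", ml$loglik))
  if (!is.null(x$posterior)) {
    cat(sprintf("  posterior: %.0f%% credibility intervals available\n",
                100 * x$posterior$level))
  }
  invisible(x)
}

#' Extract abundance estimates from a fit
#'
#' @param object an [quantify()] fit.
#' @param level `"isoform"` or `"gene"`.
#' @param ... unused.
#' @return a data frame of abundance estimates (expected counts, TPM,
#'   tau, and posterior summaries when available).
#' @export
coef.rnaquant_fit <- function(object, level = c("isoform", "gene"), ...) {
  level <- match.arg(level)
  tabs <- write_results(object$estimates, object$reference,
                        post = object$posterior)
  tabs[[level]]
}

#' @export
summary.rnaquant_fit <- function(object, ...) {
  tabs <- write_results(object$estimates, object$reference,
                        post = object$posterior)
  structure(list(isoform = tabs$isoform, gene = tabs$gene,
                 fit = object), class = "summary.rnaquant_fit")
}

#' @export
print.summary.rnaquant_fit <- function(x, ...) {
  print(x$fit)
  ord <- order(-x$isoform$TPM)
  cat("\nTop transcripts by TPM:\n")
  print(head(x$isoform[ord, ], 10), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
logLik.rnaquant_fit <- function(object, ...) {
  ml <- object$estimates
  structure(ml$loglik, df = length(ml$tau), nobs = ml$n_unfiltered,
            class = "logLik")
}

#' Simulate reads from a fitted model
#'
#' Draws new datasets from the generative model at the fitted parameters
#' (abundances, fragment length distribution, RSPD, error model) -- the
#' learn-then-simulate workflow.
#'
#' @param object an [quantify()] fit.
#' @param nsim number of datasets.
#' @param seed optional RNG seed.
#' @param n_reads reads per dataset (defaults to the fitted read count).
#' @param qmodel a [quality_markov()] for quality strings; fitted from
#'   the input reads when they carry qualities.
#' @param ... passed to [simulate_dataset()].
#' @return a list of [simulate_dataset()] results (length `nsim`).
#' @export
simulate.rnaquant_fit <- function(object, nsim = 1, seed = NULL,
                                  n_reads = NULL, qmodel = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ml <- object$estimates
  if (is.null(n_reads)) n_reads <- ml$n_unfiltered
  if (is.null(qmodel)) {
    qmodel <- if (!is.null(object$alignments$reads$qual1)) {
      fit_quality_markov(object$alignments$reads)
    } else {
      default_quality_markov()
    }
  }
  rl <- round(dist_mean(ml$params$read_dist))
  lapply(seq_len(nsim), function(i) {
    simulate_dataset(ml$params, object$reference, n_reads,
                     paired = object$alignments$reads$paired,
                     read_len = rl, qmodel = qmodel, ...)
  })
}

#' Plot abundance estimates
#'
#' Rank-abundance plot of isoform TPM estimates on a log scale, with the
#' credibility intervals when available.
#'
#' @param x an [quantify()] fit.
#' @param max_points largest number of transcripts drawn.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics plot segments
#' @export
plot.rnaquant_fit <- function(x, max_points = 500, ...) {
  ml <- x$estimates
  tpm <- sort(ml$tpm[ml$tpm > 0], decreasing = TRUE)
  tpm <- head(tpm, max_points)
  plot(seq_along(tpm), pmax(tpm, 1e-2), log = "y", xlab = "rank",
       ylab = "TPM", main = "Estimated isoform abundances", pch = 20,
       ...)
  if (!is.null(x$posterior)) {
    po <- x$posterior$isoform
    idx <- match(names(tpm), po$id)
    segments(seq_along(tpm), pmax(po$ci_lower[idx], 1e-2),
             seq_along(tpm), pmax(po$ci_upper[idx], 1e-2),
             col = "grey60")
  }
  invisible(x)
}
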