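#' Control parameters for quantification
#'
#' Collects the tunable constants of the estimation pipeline: the aligner
#' policy, the read filters, the fragment length prior for single-end
#' data, the EM schedule and convergence rule, and the repeat-pass
#' probability (m) computation.
#'
#' @param strand_specific library is strand-specific (orientation
#'   probability 1 for forward).
#' @param estimate_rspd re-estimate a binned read start position
#'   distribution during EM (default uniform, not estimated).
#' @param rspd_bins number of RSPD bins.
#' @param fragment_length_mean,fragment_length_sd discretized Gaussian
#'   prior for the fragment length distribution; for single-end data this
#'   prior is held fixed (single-end reads carry no direct fragment length
#'   information), for paired-end data it is re-estimated from the data.
#' @param error_model `"auto"` (quality model when qualities are present,
#'   else profile), `"quality"` or `"profile"`.
#' @param max_alignments filter reads with at least this many alignments.
#' @param polya_fraction A/T-content threshold of the poly(A) read filter.
#' @param seed_length,seed_mismatches built-in aligner seed policy.
#' @param conv_theta_min,conv_rel_tol EM stops when all abundances at
#'   least `conv_theta_min` have relative change below `conv_rel_tol`.
#' @param max_iters EM iteration cap.
#' @param aux_first,aux_every auxiliary parameters (fragment length, RSPD,
#'   error model) are re-estimated during the first `aux_first` iterations
#'   and every `aux_every` iterations thereafter.
#' @param m_floor lower bound for the repeat-pass probabilities m.
#' @param m_exact_limit use exact window enumeration for m when transcript
#'   length times fragment-length support is at most this; otherwise
#'   Monte-Carlo.
#' @param m_mc_draws Monte-Carlo draws per transcript for m.
#' @param update_noise re-estimate the noise background composition from
#'   noise-weighted base frequencies during auxiliary updates.
#' @return a list of class `quant_control`.
#' @export
quant_control <- function(strand_specific = FALSE, estimate_rspd = FALSE,
                          rspd_bins = 20, fragment_length_mean = 280,
                          fragment_length_sd = 17,
                          error_model = c("auto", "quality", "profile"),
                          max_alignments = 200, polya_fraction = 0.9,
                          seed_length = 25, seed_mismatches = 2,
                          conv_theta_min = 1e-7, conv_rel_tol = 1e-3,
                          max_iters = 10000, aux_first = 20,
                          aux_every = 100, m_floor = 1e-8,
                          m_exact_limit = 1e6, m_mc_draws = 1e4,
                          update_noise = FALSE) {
  structure(list(strand_specific = strand_specific,
                 estimate_rspd = estimate_rspd, rspd_bins = rspd_bins,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 error_model = match.arg(error_model),
                 max_alignments = max_alignments,
                 polya_fraction = polya_fraction,
                 seed_length = seed_length,
                 seed_mismatches = seed_mismatches,
                 conv_theta_min = conv_theta_min,
                 conv_rel_tol = conv_rel_tol, max_iters = max_iters,
                 aux_first = aux_first, aux_every = aux_every,
                 m_floor = m_floor, m_exact_limit = m_exact_limit,
                 m_mc_draws = m_mc_draws, update_noise = update_noise),
            class = "quant_control")
}

# default model parameters for a data set
init_params <- function(aset, control) {
  reads <- aset$reads
  lens <- nchar(reads$seq1)
  if (reads$paired) lens <- c(lens, nchar(reads$seq2))
  read_dist <- empirical_length_dist(lens)
  frag_dist <- gaussian_length_dist(control$fragment_length_mean,
                                    control$fragment_length_sd)
  has_q <- !is.null(reads$qual1)
  etype <- control$error_model
  if (etype == "auto") etype <- if (has_q) "quality" else "profile"
  if (etype == "quality" && !has_q) {
    stop("quality error model requested but reads carry no quality scores")
  }
  error <- if (etype == "quality") quality_error_model()
           else profile_error_model(max(lens))
  rspd <- if (control$estimate_rspd) rep(1 / control$rspd_bins,
                                         control$rspd_bins) else 1
  model_params(frag_dist = frag_dist, read_dist = read_dist, rspd = rspd,
               error = error, strand_specific = control$strand_specific)
}

#' E-step: posterior responsibilities of candidate alignments
#'
#' For each unfiltered read, the posterior probability of each candidate
#' alignment (proportional to `theta_i` times the alignment weight) and of
#' the noise outcome (proportional to `theta_0` times the noise weight),
#' normalized per read.
#'
#' @param params a [model_params()] with `theta` set.
#' @param aset a filtered [alignment_set()].
#' @param ts the [transcript_set()].
#' @return an object of class `responsibilities` with fields `post`
#'   (per-candidate posterior), `noise_post` (per read), `read`, `tid`,
#'   `loglik`, `n` and `M`.
#' @export
e_step <- function(params, aset, ts) {
  comp <- compile_alignments(aset, ts, params)
  theta <- params$theta
  if (is.null(theta)) stop("params$theta is not set")
  stopifnot(length(theta) == comp$M + 1)
  r <- cpp_responsibilities(comp$offsets, comp$cand_tid, comp$w,
                            comp$noise_w, theta)
  structure(list(post = r$post, noise_post = r$noise_post,
                 read = comp$cand_read, tid = comp$cand_tid,
                 loglik = r$loglik, n = comp$n, M = comp$M),
            class = "responsibilities")
}

#' M-step: update abundances from responsibilities
#'
#' Sets `theta_i` proportional to `c_i / m_i` for transcripts and to `c_0`
#' for the noise component, where `c` are the expected fragment counts
#' (summed responsibilities) and `m` the repeat-pass probabilities -- the
#' bias correction for reads lost to the multi-alignment and poly(A)
#' filters.
#'
#' @param resp a [e_step()] result, or a numeric vector of counts
#'   `c_0..c_M`.
#' @param m repeat-pass probabilities (length M, in `(0, 1]`).
#' @param N total number of unfiltered fragments (defaults to the count
#'   total).
#' @return the updated `theta` vector (sums to one).
#' @export
m_step <- function(resp, m, N = NULL) {
  counts <- if (inherits(resp, "responsibilities")) resp_counts(resp)
            else as.numeric(resp)
  stopifnot(length(counts) == length(m) + 1, all(m > 0), all(m <= 1))
  if (is.null(N)) N <- sum(counts)
  stopifnot(N > 0)
  theta <- c(counts[1], counts[-1] / m) / N
  theta / sum(theta)
}

resp_counts <- function(resp) {
  counts <- numeric(resp$M + 1)
  counts[1] <- sum(resp$noise_post)
  if (length(resp$post) > 0) {
    s <- rowsum(resp$post, resp$tid)
    counts[as.integer(rownames(s)) + 1] <- s[, 1]
  }
  counts
}

#' Re-estimate auxiliary model parameters from responsibilities
#'
#' Updates the error-model tables (responsibility-weighted character
#' confusion counts with add-one smoothing), the fragment length
#' distribution (paired-end data only; the single-end prior is held
#' fixed), the RSPD (when estimation is enabled) and optionally the noise
#' background composition.
#'
#' @param resp responsibilities from [e_step()] (or internal equivalents).
#' @param aset the filtered [alignment_set()].
#' @param params current [model_params()].
#' @param ts the [transcript_set()].
#' @param control a [quant_control()].
#' @return the updated [model_params()].
#' @export
update_auxiliary <- function(resp, aset, params, ts,
                             control = quant_control()) {
  comp <- compile_alignments(aset, ts, params)
  upd <- aux_update(list(post = resp$post, noise_post = resp$noise_post),
                    comp, params, control)
  upd$params
}

# internal form working on a compiled structure
aux_update <- function(resp, comp, params, control) {
  pos_changed <- FALSE
  post <- resp$post
  # --- error model ---
  em <- params$error
  K1 <- dim(em$eps)[1]
  key_of <- function(qual, pos) {
    if (em$type == "quality") pmin(pmax(qual, 0L), K1 - 1L) + 1L
    else pmin(pos, K1)
  }
  cnt <- numeric(K1 * 16L)
  alnw <- 1 - resp$noise_post
  ok <- comp$rl_char <= 3L
  idx <- function(key, c_, r) key + K1 * (c_ + 4L * r)  # 1-based via key
  if (any(ok)) {
    i1 <- idx(key_of(comp$rl_qual[ok], comp$rl_pos[ok]),
              comp$rl_char[ok], comp$rl_char[ok])
    s <- rowsum(alnw[comp$rl_read[ok]], i1)
    cnt[as.integer(rownames(s))] <- cnt[as.integer(rownames(s))] + s[, 1]
  }
  mok <- comp$mm_r <= 3L & comp$mm_c <= 3L
  if (any(mok)) {
    keym <- key_of(comp$mm_qual[mok], comp$mm_pos[mok] + 1L)
    pm <- post[comp$mm_cand[mok]]
    i_from <- idx(keym, comp$mm_r[mok], comp$mm_r[mok])
    i_to <- idx(keym, comp$mm_c[mok], comp$mm_r[mok])
    s <- rowsum(c(-pm, pm), c(i_from, i_to))
    cnt[as.integer(rownames(s))] <- cnt[as.integer(rownames(s))] + s[, 1]
  }
  arr <- array(pmax(cnt, 0) + 1, dim = c(K1, 4, 4),
               dimnames = list(NULL, BASES, BASES))
  tot <- arr[, , 1] + arr[, , 2] + arr[, , 3] + arr[, , 4]
  for (r in 1:4) arr[, , r] <- arr[, , r] / tot
  params$error$eps <- arr

  # --- fragment length distribution (paired-end only) ---
  if (comp$paired && length(post) > 0) {
    fd <- params$frag_dist
    fl <- pmin(pmax(comp$cand_flen, fd$min), fd$max)
    h <- numeric(fd$max - fd$min + 1L)
    s <- rowsum(post, fl - fd$min + 1L)
    h[as.integer(rownames(s))] <- s[, 1]
    if (sum(h) > 0) {
      params$frag_dist <- length_dist(fd$min, h + 1e-8)
      pos_changed <- TRUE
    }
  }

  # --- RSPD ---
  if (control$estimate_rspd && length(post) > 0) {
    B <- control$rspd_bins
    span <- if (comp$paired) comp$cand_flen else comp$L1[comp$cand_read]
    npos <- pmax(comp$tlen[comp$cand_tid] - span + 1L, 1L)
    bin <- pmin(floor(comp$cand_pos * B / npos), B - 1L) + 1L
    h <- numeric(B)
    s <- rowsum(post, bin)
    h[as.integer(rownames(s))] <- s[, 1]
    params$rspd <- (h + 1) / sum(h + 1)
    pos_changed <- TRUE
  }

  # --- noise background ---
  if (control$update_noise && sum(resp$noise_post) > 0) {
    okn <- comp$rl_char <= 3L
    s <- rowsum(resp$noise_post[comp$rl_read[okn]], comp$rl_char[okn] + 1L)
    h <- numeric(4)
    h[as.integer(rownames(s))] <- s[, 1]
    params$noise_background <- (h + 1) / sum(h + 1)
  }
  list(params = params, pos_changed = pos_changed)
}

#' Repeat-pass probabilities m
#'
#' For each transcript, the probability that a fragment generated from it
#' survives the read filters (alignment count below the threshold and not
#' poly(A)-like), under the current fragment length distribution, RSPD,
#' read length and strand-specificity.  Every distinct read window of the
#' transcript is weighted by its generation probability and its survival
#' is checked with the built-in aligner; transcripts whose enumeration
#' would be too large are handled by weighted Monte-Carlo subsampling.
#' Used to de-bias the M-step (`theta_i` proportional to `c_i / m_i`).
#'
#' @param ts a [transcript_set()].
#' @param params a [model_params()].
#' @param control a [quant_control()] (filter thresholds, aligner policy,
#'   enumeration limits).
#' @return numeric vector of length M with values in `(0, 1]`.
#' @export
estimate_repeat_pass_prob <- function(ts, params, control = quant_control()) {
  M <- n_transcripts(ts)
  L <- as.integer(round(dist_mean(params$read_dist)))
  fd <- params$frag_dist
  support <- length(fd$pmf)
  thr <- control$polya_fraction
  m <- rep(1, M)
  q_str <- character(0)
  q_tid <- integer(0)
  q_w <- numeric(0)
  base_w <- vector("list", M)
  surv_polya <- vector("list", M)
  for (i in seq_len(M)) {
    tl <- ts$length[i]
    nw <- tl - L + 1L
    if (nw < 1L) next
    starts <- 0:(nw - 1L)
    wf <- cpp_se_pos_factors(rep(tl, nw), starts, rep(0L, nw), rep(L, nw),
                             fd$min, fd$pmf, params$read_dist$min,
                             params$read_dist$pmf, params$rspd,
                             params$strand_specific)
    wr <- if (params$strand_specific) numeric(nw) else
      cpp_se_pos_factors(rep(tl, nw), starts, rep(1L, nw), rep(L, nw),
                         fd$min, fd$pmf, params$read_dist$min,
                         params$read_dist$pmf, params$rspd,
                         params$strand_specific)
    w <- wf + wr
    if (sum(w) <= 0) next
    # windowed A/T content (a reverse-orientation read is the reverse
    # complement of the window, so max(A, T) covers both orientations)
    code <- as.integer(charToRaw(ts$seq[i]))
    isA <- cumsum(c(0L, code == 65L))
    isT <- cumsum(c(0L, code == 84L))
    nA <- isA[starts + L + 1L] - isA[starts + 1L]
    nT <- isT[starts + L + 1L] - isT[starts + 1L]
    sp <- pmax(nA, nT) < thr * L
    if ((as.numeric(tl) * support) > control$m_exact_limit &&
        nw > control$m_mc_draws) {
      pick <- sample.int(nw, control$m_mc_draws, replace = TRUE, prob = w)
      starts <- starts[pick]
      sp <- sp[pick]
      w <- rep(1, length(pick))
    }
    base_w[[i]] <- w
    surv_polya[[i]] <- sp
    need <- which(sp)
    if (length(need) > 0) {
      q_str <- c(q_str, substring(ts$seq[i], starts[need] + 1L,
                                  starts[need] + L))
      q_tid <- c(q_tid, rep.int(i, length(need)))
      q_w <- c(q_w, w[need])
    }
  }
  if (length(q_str) > 0) {
    counts <- cpp_hit_counts(q_str, ts$seq, control$seed_length,
                             control$seed_mismatches,
                             as.integer(control$max_alignments),
                             params$strand_specific)
    pass <- counts < control$max_alignments
    num <- rowsum(q_w * pass, q_tid)
    for (i in seq_len(M)) {
      if (is.null(base_w[[i]])) next
      tot <- sum(base_w[[i]])
      hit <- match(as.character(i), rownames(num))
      good <- if (is.na(hit)) 0 else num[hit, 1]
      m[i] <- good / tot
    }
  } else {
    for (i in seq_len(M)) if (!is.null(base_w[[i]])) m[i] <- 0
  }
  pmin(pmax(m, control$m_floor), 1)
}

#' Maximum-likelihood quantification by expectation-maximization
#'
#' Alternates E and M steps over the candidate alignments of the
#' unfiltered reads, re-estimating the auxiliary distributions on the
#' usual schedule (first `aux_first` iterations and every `aux_every`
#' thereafter), until all abundances of at least `conv_theta_min` change
#' by less than `conv_rel_tol` relative, then converts `theta` to
#' transcript fractions tau, TPM, expected counts and within-gene
#' fractions.
#'
#' @param aset a filtered [alignment_set()] (see [filter_reads()]).
#' @param ts the [transcript_set()].
#' @param control a [quant_control()].
#' @param params optional initial [model_params()]; defaults are derived
#'   from the data and `control`.
#' @param m optional precomputed repeat-pass probabilities.
#' @return an object of class `ml_estimates`: `theta`, `expected_counts`
#'   (length M+1, noise first), `tau`, `tpm`, `gene_tau`, `isopct`,
#'   `eff_len`, `m`, `iterations`, `loglik`, `converged`, the final
#'   `params`, `n_unfiltered`, and the compiled alignment data (`data`)
#'   reused by the posterior sampler and writers.
#' @export
run_em <- function(aset, ts, control = quant_control(), params = NULL,
                   m = NULL) {
  stopifnot(inherits(aset, "alignment_set"))
  if (is.null(params)) params <- init_params(aset, control)
  N <- sum(aset$filtered == "none")
  if (N == 0) stop("no unfiltered reads")
  if (is.null(m)) m <- estimate_repeat_pass_prob(ts, params, control)
  comp <- compile_alignments(aset, ts, params)
  M <- comp$M
  theta <- rep(1 / (M + 1), M + 1)

  it <- 0
  converged <- FALSE
  loglik <- NA_real_
  while (it < control$max_iters && !converged) {
    aux_iter <- it < control$aux_first ||
      (it + 1) %% control$aux_every == 0
    if (aux_iter) {
      r <- cpp_responsibilities(comp$offsets, comp$cand_tid, comp$w,
                                comp$noise_w, theta)
      upd <- aux_update(r, comp, params, control)
      params <- upd$params
      comp <- comp_refresh(comp, params, upd$pos_changed)
      counts <- numeric(M + 1)
      counts[1] <- sum(r$noise_post)
      if (length(r$post) > 0) {
        s <- rowsum(r$post, comp$cand_tid)
        counts[as.integer(rownames(s)) + 1] <- s[, 1]
      }
      tnew <- m_step(counts, m)
      big <- theta >= control$conv_theta_min
      converged <- all(abs(tnew[big] - theta[big]) / theta[big] <
                         control$conv_rel_tol)
      theta <- tnew
      loglik <- r$loglik
      it <- it + 1
    } else {
      next_aux <- (floor(it / control$aux_every) + 1) * control$aux_every
      block <- min(next_aux - 1, control$max_iters) - it
      res <- cpp_em(comp$offsets, comp$cand_tid, comp$w, comp$noise_w,
                    theta, m, as.integer(block), control$conv_rel_tol,
                    control$conv_theta_min)
      theta <- res$theta
      it <- it + res$iters
      converged <- res$converged
      loglik <- res$loglik
    }
  }
  fin <- cpp_e_counts(comp$offsets, comp$cand_tid, comp$w, comp$noise_w,
                      theta, M)
  counts <- fin$counts
  loglik <- fin$loglik
  params$theta <- theta
  eff_len <- effective_lengths(ts, params$frag_dist)
  tau <- theta_to_tau(theta, eff_len)
  gi <- gene_and_isopct(tau, ts$gene_map)
  structure(list(theta = theta,
                 expected_counts = setNames(counts, c("noise", ts$id)),
                 tau = setNames(tau, ts$id), tpm = setNames(tau * 1e6, ts$id),
                 gene_tau = gi$gene_tau, isopct = gi$isopct,
                 eff_len = eff_len, m = m, iterations = it,
                 loglik = loglik, converged = converged, params = params,
                 n_unfiltered = N, ids = ts$id, gene_map = ts$gene_map,
                 data = comp),
            class = "ml_estimates")
}

#' @export
print.ml_estimates <- function(x, ...) {
  cat(sprintf(
    "<ml_estimates: %d transcripts, %d fragments (%.1f noise), %d EM iterations%s, logLik %.2f>\n",
    length(x$tau), x$n_unfiltered, x$expected_counts[1], x$iterations,
    if (x$converged) "" else " (not converged)", x$loglik))
  invisible(x)
}

#' Convert abundances theta to transcript fractions tau
#'
#' `tau_i = (theta_i / eff_len_i) / sum_j (theta_j / eff_len_j)` over the
#' transcripts (the noise component is excluded).  `tau_to_theta()` is the
#' inverse (up to the noise share), used when simulating from designed
#' transcript fractions.
#'
#' @param theta numeric vector of length M+1 (noise first) or M.
#' @param eff_lengths effective lengths (length M).
#' @return tau, a vector of length M summing to one (all zero, with a
#'   warning, when no transcript has positive abundance).
#' @export
theta_to_tau <- function(theta, eff_lengths) {
  th <- if (length(theta) == length(eff_lengths) + 1) theta[-1] else theta
  stopifnot(length(th) == length(eff_lengths))
  bad <- th > 0 & eff_lengths <= 0
  if (any(bad)) {
    stop("positive abundance on transcripts with zero effective length")
  }
  x <- ifelse(eff_lengths > 0, th / eff_lengths, 0)
  s <- sum(x)
  if (s <= 0) {
    warning("all transcript abundances are zero")
    return(rep(0, length(th)))
  }
  x / s
}

#' @rdname theta_to_tau
#' @param tau transcript fractions (length M).
#' @param noise share of fragments assigned to the noise component.
#' @export
tau_to_theta <- function(tau, eff_lengths, noise = 0) {
  stopifnot(length(tau) == length(eff_lengths), noise >= 0, noise < 1)
  x <- tau * eff_lengths
  s <- sum(x)
  if (s <= 0) stop("tau has no positive mass on transcripts")
  c(noise, (1 - noise) * x / s)
}

#' Gene-level fractions and within-gene isoform fractions
#'
#' Gene abundance is the sum of its member transcript fractions; the
#' within-gene fraction of an isoform is its share of the gene total (0
#' for genes with zero abundance).
#'
#' @param tau transcript fractions, named by transcript id or in
#'   transcript-set order.
#' @param gene_map named list mapping gene id to member transcript ids.
#' @return list with `gene_tau` (named by gene) and `isopct`
#'   (per-transcript within-gene fraction, in percent).
#' @export
gene_and_isopct <- function(tau, gene_map) {
  ids <- unlist(gene_map, use.names = FALSE)
  if (is.null(names(tau))) names(tau) <- ids
  stopifnot(all(ids %in% names(tau)))
  gene_of <- rep(names(gene_map), lengths(gene_map))
  gt <- rowsum(unname(tau[ids]), gene_of, reorder = FALSE)
  gene_tau <- setNames(gt[, 1], rownames(gt))
  denom <- gene_tau[gene_of]
  frac <- ifelse(denom > 0, tau[ids] / denom, 0)
  isopct <- setNames(100 * frac, ids)[names(tau)]
  list(gene_tau = gene_tau, isopct = isopct)
}
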