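# a perfect-match error model simplifies hand computation
perfect_params <- function(frag = 2, rlen = 2, ...) {
  em <- quality_error_model()
  em$eps[, , ] <- 0
  for (b in 1:4) em$eps[, b, b] <- 1
  model_params(frag_dist = point_length_dist(frag),
               read_dist = point_length_dist(rlen), error = em, ...)
}

test_that("E-step responsibilities follow theta and symmetry", {
  ts <- transcript_set(c("AACGT", "AACGT"), c("a", "b"))
  reads <- read_set("AACG", qual1 = qstr(30, 4))
  aset <- filter_reads(align_reads(reads, ts, seed_len = 4, max_mm = 0))
  par <- perfect_params(frag = 5, rlen = 4)
  par$theta <- c(0, .5, .5)
  r <- e_step(par, aset, ts)
  expect_equal(r$post, c(.5, .5))
  par$theta <- c(0, .8, .2)
  r2 <- e_step(par, aset, ts)
  expect_equal(r2$post, c(.8, .2))
  # per-read posteriors (incl. noise) sum to one
  expect_equal(sum(r2$post) + sum(r2$noise_post), 1)
  # read with no candidates: posterior fully on noise
  reads0 <- read_set("GGGG")
  aset0 <- filter_reads(align_reads(reads0, ts, seed_len = 4, max_mm = 0))
  par$theta <- c(1 / 3, 1 / 3, 1 / 3)
  r0 <- e_step(par, aset0, ts)
  expect_equal(r0$noise_post, 1)
})

test_that("M-step applies the repeat-pass correction", {
  expect_equal(m_step(c(0, 1, 3), c(1, 1)), c(0, .25, .75))
  # c = (0,1,3), m = (1, 1/2) -> proportional to (0, 1, 6)
  expect_equal(m_step(c(0, 1, 3), c(1, .5)), c(0, 1 / 7, 6 / 7))
  expect_equal(m_step(c(5, 0, 0), c(1, 1)), c(1, 0, 0))
})

test_that("theta-tau conversions are exact inverses", {
  expect_equal(theta_to_tau(c(0, .5, .5), c(100, 200)), c(2 / 3, 1 / 3))
  expect_equal(theta_to_tau(c(.2, .8), 50), 1)
  expect_equal(theta_to_tau(c(0, .3, .3, .4), c(10, 10, 10)),
               c(.3, .3, .4))
  set.seed(2)
  tau <- runif(5); tau <- tau / sum(tau)
  el <- runif(5, 100, 1000)
  expect_equal(theta_to_tau(tau_to_theta(tau, el, noise = 0.1), el), tau)
  expect_warning(theta_to_tau(c(1, 0, 0), c(10, 20)), "zero")
})

test_that("gene aggregation and within-gene fractions", {
  gm <- list(gA = c("t1", "t2"), gB = "t3", gC = "t4")
  tau <- c(t1 = .1, t2 = .3, t3 = .6, t4 = 0)
  r <- gene_and_isopct(tau, gm)
  expect_equal(unname(r$gene_tau), c(.4, .6, 0))
  expect_equal(unname(r$isopct[c("t1", "t2")]), c(25, 75))
  expect_equal(unname(r$isopct["t3"]), 100)
  expect_equal(unname(r$isopct["t4"]), 0)   # zero-abundance convention
})

test_that("repeat-pass probabilities reflect designed filtering", {
  # unique sequence, no tail: nothing is filtered
  ts <- transcript_set(rand_dna(300, seed = 31), "u")
  par <- model_params(frag_dist = point_length_dist(100),
                      read_dist = point_length_dist(35))
  m <- estimate_repeat_pass_prob(ts, par, quant_control())
  expect_equal(unname(m), 1)
  # pure-A transcript: every read is poly(A)-like -> floored at the bound
  tsA <- transcript_set(strrep("A", 300), "a")
  mA <- estimate_repeat_pass_prob(tsA, par, quant_control())
  expect_lte(unname(mA), 1e-6)
  # half the start positions yield poly(A)-like reads: exhaustive oracle
  half <- paste0(rand_dna(100, seed = 32), strrep("A", 135))
  tsH <- transcript_set(half, "h")
  parH <- model_params(frag_dist = point_length_dist(200),
                       read_dist = point_length_dist(35))
  ctl <- quant_control(polya_fraction = 0.9)
  mH <- estimate_repeat_pass_prob(tsH, parH, ctl)
  # oracle: enumerate all (s, o) for f = 200 over 36 starts
  starts <- 0:35
  surv <- function(w) {
    a <- strsplit(w, "")[[1]]
    max(mean(a == "A"), mean(a == "T")) < 0.9
  }
  wins_f <- substring(half, starts + 1, starts + 35)          # read at s
  wins_r <- substring(half, starts + 200 - 35 + 1, starts + 200)
  expected <- mean(c(vapply(wins_f, surv, TRUE), vapply(wins_r, surv, TRUE)))
  expect_equal(unname(mH), expected, tolerance = 1e-10)
})

test_that("EM recovers trivial and symmetric instances", {
  # ten uniquely-mapping reads on one transcript
  ts <- transcript_set(rand_dna(120, seed = 33), "t")
  reads <- exact_reads(ts, rep(1, 10), seq(0, 90, by = 10), len = 25)
  aset <- filter_reads(align_reads(reads, ts))
  ml <- run_em(aset, ts, quant_control(fragment_length_mean = 60,
                                       fragment_length_sd = 10,
                                       error_model = "profile"))
  expect_gt(ml$theta[2], 0.999)
  expect_equal(unname(ml$expected_counts[-1]), 10, tolerance = 1e-6)
  expect_equal(ml$tau, c(t = 1))
  # two identical transcripts sharing all reads: symmetric split
  ts2 <- transcript_set(rep(ts$seq, 2), c("a", "b"))
  aset2 <- filter_reads(align_reads(reads, ts2))
  ml2 <- run_em(aset2, ts2, quant_control(fragment_length_mean = 60,
                                          fragment_length_sd = 10,
                                          error_model = "profile"))
  expect_equal(unname(ml2$tau["a"]), 0.5, tolerance = 1e-9)
})

test_that("EM log-likelihood matches a dense grid search oracle", {
  # random small instances: <= 3 transcripts, <= 30 reads
  grid_ll <- function(comp_w, noise_w, m, step = 0.0025) {
    # dense search over the 2-simplex (theta0 fixed at 0 here)
    best <- -Inf
    M <- ncol(comp_w)
    gr <- seq(0, 1, by = step)
    if (M == 2) {
      for (a in gr) {
        th <- c(a, 1 - a)
        ll <- sum(log(comp_w %*% th + 1e-300))
        if (ll > best) best <- ll
      }
    } else {
      for (a in gr) for (b in seq(0, 1 - a, by = step)) {
        th <- c(a, b, 1 - a - b)
        ll <- sum(log(comp_w %*% th + 1e-300))
        if (ll > best) best <- ll
      }
    }
    best
  }
  set.seed(17)
  for (case in 1:3) {
    M <- sample(2:3, 1)
    n <- sample(10:30, 1)
    ts <- transcript_set(vapply(seq_len(M), function(i)
      paste0(rand_dna(60), substr(rand_dna(40), 1, 40)), ""),
      paste0("t", seq_len(M)))
    tid <- sample(M, n, replace = TRUE)
    start <- sample(0:70, n, replace = TRUE)
    reads <- exact_reads(ts, tid, start, len = 25)
    aset <- filter_reads(align_reads(reads, ts, seed_len = 20))
    ctl <- quant_control(fragment_length_mean = 50, fragment_length_sd = 5,
                         error_model = "profile", aux_first = 0,
                         aux_every = 1e9, conv_rel_tol = 1e-8,
                         max_iters = 20000)
    ml <- run_em(aset, ts, ctl)
    # oracle likelihood over the same candidate weights, no noise mass
    comp <- ml$data
    W <- matrix(0, comp$n, M)
    for (a in seq_along(comp$cand_read)) {
      W[comp$cand_read[a], comp$cand_tid[a]] <-
        W[comp$cand_read[a], comp$cand_tid[a]] + comp$w[a]
    }
    # EM solution includes a noise component; evaluate its transcripts-only
    # restriction on the grid (theta0 at the EM optimum is ~0 here)
    best <- grid_ll(W, comp$noise_w, ml$m)
    expect_lt(abs(ml$loglik - best), 1e-3 + abs(best) * 1e-6)
    expect_gte(ml$loglik, best - 1e-3)
  }
})

test_that("EM log-likelihood is monotone with fixed auxiliaries", {
  set.seed(23)
  ts <- transcript_set(c(rand_dna(150), rand_dna(150)), c("a", "b"))
  tid <- sample(2, 40, replace = TRUE)
  reads <- exact_reads(ts, tid, sample(0:120, 40, TRUE), len = 25)
  aset <- filter_reads(align_reads(reads, ts))
  par <- NULL
  ctl <- quant_control(fragment_length_mean = 60, fragment_length_sd = 10,
                       error_model = "profile", aux_first = 0,
                       aux_every = 1e9)
  ml <- run_em(aset, ts, ctl)
  comp <- ml$data
  # replay EM from uniform theta, tracking the likelihood by hand
  theta <- rep(1 / 3, 3)
  ll_prev <- -Inf
  for (it in 1:50) {
    r <- rnaquant:::cpp_e_counts(comp$offsets, comp$cand_tid, comp$w,
                                 comp$noise_w, theta, 2)
    expect_gte(r$loglik, ll_prev - 1e-12 * abs(ll_prev))
    ll_prev <- r$loglik
    theta <- m_step(r$counts, ml$m)
  }
})

test_that("auxiliary updates recover injected distributions", {
  # fragment lengths: paired-end fragments all of length 50
  set.seed(29)
  ts <- transcript_set(rand_dna(400), "t")
  n <- 60
  start <- sample(0:300, n, TRUE)
  s1 <- substring(ts$seq, start + 1, start + 20)
  s2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(ts$seq, start + 31, start + 50))))
  reads <- read_set(s1, seq2 = s2)
  aset <- filter_reads(align_reads(reads, ts, seed_len = 20))
  expect_true(all(aset$cand$flen == 50))
  par <- init_params_for_test(aset)
  par$theta <- c(0, 1)
  r <- e_step(par, aset, ts)
  upd <- update_auxiliary(r, aset, par, ts, quant_control())
  expect_equal(dist_mean(upd$frag_dist), 50, tolerance = 0.2)
  # error tables: with perfect data the confusion mass concentrates on match
  # add-one smoothing bounds the match mass at this depth (~15 counts/row)
  expect_gt(min(diag(upd$error$eps[10, , ])), 0.75)
})

test_that("noise background re-estimation matches a counting oracle", {
  ts <- transcript_set(rand_dna(200, seed = 35), "t")
  aligned <- exact_reads(ts, rep(1, 5), seq(0, 120, 30), len = 25)
  stray <- c(strrep("G", 25), paste0(strrep("GC", 12), "G"))
  reads <- read_set(c(aligned$seq1, stray))
  aset <- filter_reads(align_reads(reads, ts))
  par <- init_params_for_test(aset)
  par$theta <- c(0.5, 0.5)
  r <- e_step(par, aset, ts)
  upd <- update_auxiliary(r, aset, par, ts,
                          quant_control(update_noise = TRUE))
  # oracle: noise-posterior-weighted base counts with add-one smoothing
  w <- r$noise_post
  chars <- strsplit(reads$seq1, "")
  cnt <- numeric(4)
  names(cnt) <- c("A", "C", "G", "T")
  for (i in seq_along(chars)) {
    tb <- table(factor(chars[[i]], levels = names(cnt)))
    cnt <- cnt + w[i] * as.numeric(tb)
  }
  expect_equal(upd$noise_background, unname((cnt + 1) / sum(cnt + 1)),
               tolerance = 1e-9)
  # stray reads carry essentially all noise weight
  expect_gt(sum(w[6:7]), 1.9)
})
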