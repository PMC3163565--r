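perfect_em <- function() {
  em <- quality_error_model()
  em$eps[, , ] <- 0
  for (b in 1:4) em$eps[, b, b] <- 1
  em
}

# a small deterministic fit used by several sampler tests
unique_fit <- function(n = 12, seed = 51) {
  set.seed(seed)
  ts <- transcript_set(rand_dna(200), "t")
  reads <- exact_reads(ts, rep(1, n), sample(0:150, n, TRUE), len = 25)
  aset <- filter_reads(align_reads(reads, ts))
  run_em(aset, ts, quant_control(fragment_length_mean = 60,
                                 fragment_length_sd = 10,
                                 error_model = "profile"))
}

test_that("sampler bookkeeping: defaults give 1000 vectors, 50000 samples", {
  cfg <- sampler_config()
  expect_equal(cfg$n_count_vectors, 1000L)
  expect_equal(cfg$theta_per_vector, 50L)
  ml <- unique_fit()
  set.seed(1)
  cv <- gibbs_count_vectors(ml, cfg)
  expect_equal(nrow(cv), 1000)
  th <- theta_samples_from_counts(cv, cfg)
  expect_equal(nrow(th), 50000)
  # every count vector sums to the number of unfiltered reads
  expect_true(all(rowSums(cv) == ml$n_unfiltered))
})

test_that("uniquely-mapping reads give degenerate count vectors", {
  ml <- unique_fit()
  set.seed(2)
  cv <- gibbs_count_vectors(ml, sampler_config(n_count_vectors = 50,
                                               burn_in = 10))
  expect_true(all(cv[, "t"] == 12))
  expect_true(all(cv[, "noise"] == 0))
})

test_that("theta samples have the Dirichlet closed-form mean", {
  # M = 1 plus noise, counts (0, 4), alpha 1 -> E[theta_1] = 5/6
  cfg <- sampler_config(n_count_vectors = 2000, theta_per_vector = 10)
  cv <- matrix(rep(c(0L, 4L), each = 2000), ncol = 2)
  set.seed(3)
  th <- theta_samples_from_counts(cv, cfg)
  expect_equal(mean(th[, 2]), 5 / 6, tolerance = 0.005)
  # symmetric zero counts -> uniform mean
  cv0 <- matrix(0L, 2000, 3)
  th0 <- theta_samples_from_counts(cv0, cfg)
  expect_equal(colMeans(th0), rep(1 / 3, 3), tolerance = 0.01)
})

test_that("posterior summaries match Beta quantiles and nest by level", {
  # Dirichlet(1, 5) posterior: component 2 is Beta(5, 1) against noise
  cfg <- sampler_config(n_count_vectors = 5000, theta_per_vector = 4)
  cv <- matrix(rep(c(0L, 4L), each = 5000), ncol = 2)
  set.seed(4)
  th <- theta_samples_from_counts(cv, cfg)
  ml <- list(ids = "t", gene_map = list(t = "t"), m = 1,
             eff_len = c(t = 1))
  po <- summarize_posterior(th, ml, level = 0.95)
  # single transcript: tau is identically 1
  expect_equal(po$isoform$pme_tpm, 1e6)
  expect_equal(po$isoform$ci_lower, 1e6)
  # theta_1 itself should match Beta(5, 1) quantiles: check on raw samples
  qs <- quantile(th[, 2], c(0.025, 0.975), names = FALSE)
  expect_equal(qs, qbeta(c(0.025, 0.975), 5, 1), tolerance = 0.01)
  # narrower level nests inside wider
  po50 <- summarize_posterior(th, ml, level = 0.5)
  expect_gte(po50$isoform$ci_lower, po$isoform$ci_lower)
  expect_lte(po50$isoform$ci_upper, po$isoform$ci_upper)
})

test_that("collapsed Gibbs matches exact enumeration on 4 multireads", {
  # two identical transcripts, 4 reads mapping to both with equal weight:
  # P(c1 = k) from exact enumeration of the 2^4 assignment states with
  # Dirichlet(1) collapsed weights prod_i (c_i!)
  ts <- transcript_set(rep(rand_dna(60, seed = 52), 2), c("a", "b"))
  reads <- exact_reads(ts, rep(1, 4), c(0, 8, 16, 24), len = 25)
  aset <- filter_reads(align_reads(reads, ts))
  ml <- run_em(aset, ts, quant_control(fragment_length_mean = 40,
                                       fragment_length_sd = 5,
                                       error_model = "profile"))
  set.seed(5)
  cv <- gibbs_count_vectors(ml, sampler_config(n_count_vectors = 10000,
                                               burn_in = 100))
  emp <- tabulate(cv[, "a"] + 1L, 5) / 10000
  # exact: assignments z in {a,b}^4, P(z) propto c_a! c_b! (equal weights)
  states <- expand.grid(rep(list(0:1), 4))
  ca <- rowSums(states == 0)
  pz <- factorial(ca) * factorial(4 - ca)
  pz <- pz / sum(pz)
  exact <- vapply(0:4, function(k) sum(pz[ca == k]), 1)
  expect_equal(emp, exact, tolerance = 0.035)
})

test_that("seeded sampler runs are bit-reproducible", {
  ml <- unique_fit()
  cfg <- sampler_config(n_count_vectors = 20, burn_in = 5)
  set.seed(77); cv1 <- gibbs_count_vectors(ml, cfg)
  set.seed(77); cv2 <- gibbs_count_vectors(ml, cfg)
  expect_identical(cv1, cv2)
})

test_that("PME lies within its own credibility interval", {
  set.seed(53)
  ts <- transcript_set(c(rand_dna(300), rand_dna(300)), c("a", "b"))
  reads <- exact_reads(ts, sample(1:2, 40, TRUE), sample(0:250, 40, TRUE),
                       len = 25)
  aset <- filter_reads(align_reads(reads, ts))
  ml <- run_em(aset, ts, quant_control(fragment_length_mean = 60,
                                       fragment_length_sd = 10,
                                       error_model = "profile"))
  cv <- gibbs_count_vectors(ml, sampler_config(n_count_vectors = 200,
                                               burn_in = 20))
  po <- summarize_posterior(theta_samples_from_counts(
    cv, sampler_config(theta_per_vector = 20)), ml)
  expect_true(all(po$isoform$pme_tpm >= po$isoform$ci_lower &
                    po$isoform$pme_tpm <= po$isoform$ci_upper))
  expect_equal(sum(po$isoform$pme_tau), 1, tolerance = 1e-9)
})
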