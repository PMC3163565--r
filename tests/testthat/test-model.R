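test_that("length pmf truncation renormalizes and is idempotent", {
  d <- length_dist(1, c(.25, .25, .25, .25))
  t2 <- truncate_length_pmf(d, 2)
  expect_equal(t2$pmf, c(.5, .5))
  d2 <- length_dist(1, c(.2, .3, .5))
  expect_equal(truncate_length_pmf(d2, 2)$pmf, c(.4, .6))
  expect_equal(truncate_length_pmf(point_length_dist(7), 9)$pmf, 1)
  expect_length(truncate_length_pmf(point_length_dist(7), 5)$pmf, 0)
  # idempotent at or above max_len
  expect_equal(truncate_length_pmf(d2, 10), d2)
})

test_that("RSPD start probabilities split bin mass and normalize", {
  expect_equal(rspd_position_probs(1, 4), rep(0.25, 4))
  expect_equal(rspd_position_probs(c(.8, .2), 2), c(.8, .2))
  expect_equal(rspd_position_probs(c(.8, .2), 4), c(.4, .4, .1, .1))
  expect_equal(rspd_start_prob(c(.8, .2), 2, 4), 0.1)
  # sums to one for awkward n, including n < bins
  for (n in c(1, 3, 7, 19, 23)) {
    p <- rspd_position_probs(runif(20), n)
    expect_equal(sum(p), 1)
    expect_length(p, n)
  }
})

test_that("emission probabilities follow the error model", {
  # perfect match under a perfect model
  em <- quality_error_model()
  em$eps[, , ] <- 0
  for (b in 1:4) em$eps[, b, b] <- 1
  p <- model_params(error = em, read_dist = point_length_dist(2))
  expect_equal(read_emission_prob(p, "AC", qstr(30, 2), "AC"), 1)
  # constant match probability multiplies
  em2 <- profile_error_model(10, error_rate = 0.1)
  p2 <- model_params(error = em2, read_dist = point_length_dist(2))
  expect_equal(read_emission_prob(p2, "AC", NULL, "AC"), 0.81)
  # theoretical quality model: q=10 twice, both mismatched
  p3 <- model_params(error = quality_error_model(),
                     read_dist = point_length_dist(2))
  expect_equal(read_emission_prob(p3, "AC", qstr(10, 2), "GG"), (0.1 / 3)^2,
               tolerance = 1e-12)
  expect_error(read_emission_prob(p3, "ACG", qstr(10, 3), "AC"), "length")
})

test_that("quality and profile models coincide when flat", {
  emq <- quality_error_model()
  for (q in seq_len(dim(emq$eps)[1])) emq$eps[q, , ] <- emq$eps[11, , ]
  emp <- profile_error_model(50, error_rate = 1 - emq$eps[11, 1, 1])
  pq <- model_params(error = emq, read_dist = point_length_dist(4))
  pp <- model_params(error = emp, read_dist = point_length_dist(4))
  expect_equal(read_emission_prob(pq, "ACGT", qstr(10, 4), "ACCT"),
               read_emission_prob(pp, "ACGT", NULL, "ACCT"),
               tolerance = 1e-12)
})

test_that("single-end alignment weight marginalizes fragment length", {
  # 1 transcript of length 3, read length 2, point-mass fragment length 2:
  # two start positions, uniform RSPD -> P(o) * 1 * 1/2 = 0.25
  ts <- transcript_set("ACG", "t")
  em <- quality_error_model()
  em$eps[, , ] <- 0
  for (b in 1:4) em$eps[, b, b] <- 1
  par <- model_params(frag_dist = point_length_dist(2),
                      read_dist = point_length_dist(2), error = em)
  rd <- read_set("AC", qual1 = qstr(30, 2))
  a <- list(tid = 1L, pos = 0L, orient = 0L)
  expect_equal(alignment_weight(par, rd, a, ts), 0.25)
  par_ss <- model_params(frag_dist = point_length_dist(2),
                         read_dist = point_length_dist(2), error = em,
                         strand_specific = TRUE)
  expect_equal(alignment_weight(par_ss, rd, a, ts), 0.5)
  # start beyond l - f is infeasible
  a2 <- list(tid = 1L, pos = 2L, orient = 0L)
  expect_equal(alignment_weight(par, rd, a2, ts), 0)
})

test_that("alignment weights are a distribution over reads given (i, f)", {
  # exhaustive: sum over (s, o, emitted read) of weight = 1 for a fixed
  # fragment length on a tiny transcript, perfect emissions
  ts <- transcript_set("ACGTTGAC", "t")
  em <- quality_error_model()
  em$eps[, , ] <- 0
  for (b in 1:4) em$eps[, b, b] <- 1
  par <- model_params(frag_dist = point_length_dist(3),
                      read_dist = point_length_dist(2), error = em)
  tot <- 0
  for (pos in 0:6) {
    for (orient in 0:1) {
      for (r1 in c("A", "C", "G", "T")) for (r2 in c("A", "C", "G", "T")) {
        rd <- read_set(paste0(r1, r2), qual1 = qstr(30, 2))
        tot <- tot + alignment_weight(par, rd,
                                      list(tid = 1, pos = pos,
                                           orient = orient), ts)
      }
    }
  }
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("noise weight is background times read-length mass", {
  par <- model_params(read_dist = point_length_dist(2))
  rd <- read_set("AC")
  expect_equal(noise_weight(par, rd), 0.25^2)
  par2 <- model_params(read_dist = length_dist(1, c(.5, .5)),
                       noise_background = c(.4, .3, .2, .1))
  expect_equal(noise_weight(par2, rd), .4 * .3 * .5)
})

test_that("model parameters round-trip through the text serialization", {
  set.seed(11)
  em <- quality_error_model(40)
  par <- model_params(theta = c(.1, .5, .4),
                      frag_dist = gaussian_length_dist(100, 10),
                      read_dist = point_length_dist(35),
                      rspd = runif(20), error = em,
                      strand_specific = TRUE,
                      noise_background = c(.3, .2, .3, .2))
  f <- tempfile()
  write_model(par, f)
  par2 <- read_model(f)
  expect_equal(par2$theta, par$theta)
  expect_equal(par2$frag_dist, par$frag_dist)
  expect_equal(par2$rspd, par$rspd, tolerance = 1e-12)
  expect_equal(par2$error$eps, par$error$eps, tolerance = 1e-12)
  expect_true(par2$strand_specific)
})
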