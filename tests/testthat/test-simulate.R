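test_that("quality Markov chain fits and regenerates structure", {
  # constant-quality strings refit to a (smoothed) identity chain
  rs <- read_set(rep("ACGT", 5), qual1 = rep(qstr(30, 4), 5))
  qm <- fit_quality_markov(rs)
  expect_equal(qm$scores, 30)
  expect_equal(unname(qm$init), 1)
  set.seed(1)
  q <- rnaquant:::simulate_markov_quals(qm, 3, 6)
  expect_true(all(q == 30))
  # deterministic alternation dominates the transition rows
  alt <- paste0(rawToChar(as.raw(33 + 20)), rawToChar(as.raw(33 + 25)))
  rs2 <- read_set(rep("ACACAC", 50), qual1 = rep(strrep(alt, 3), 50))
  qm2 <- fit_quality_markov(rs2)
  expect_gt(qm2$trans["20", "25"], 0.9)
  expect_gt(qm2$trans["25", "20"], 0.9)
  # refit from a known chain recovers the transition matrix
  set.seed(2)
  qm0 <- default_quality_markov()
  qmat <- rnaquant:::simulate_markov_quals(qm0, 4000, 35)
  quals <- rnaquant:::qual_strings(qmat)
  fit <- fit_quality_markov(read_set(strrep("A", 35), qual1 = quals))
  common <- intersect(as.character(qm0$scores), as.character(fit$scores))
  heavy <- common[colSums(qm0$trans[common, common]) > 0]
  for (s in c("35", "38")) {
    expect_equal(fit$trans[s, common], qm0$trans[s, common],
                 tolerance = 0.05, ignore_attr = TRUE)
  }
  expect_error(fit_quality_markov(read_set("ACGT")), "quality")
})

test_that("error-free simulation emits exact (reverse-complemented) windows", {
  set.seed(3)
  ts <- transcript_set(c(rand_dna(500), rand_dna(700)), c("a", "b"))
  fd <- gaussian_length_dist(200, 20)
  par <- model_params(theta = c(0, .4, .6), frag_dist = fd,
                      read_dist = point_length_dist(30))
  sim <- simulate_dataset(par, ts, 300, read_len = 30, qmodel = NULL)
  expect_equal(nrow(sim$truth), 300)
  expect_true(all(table(sim$truth$transcript_id) > 0))
  for (i in sample(300, 25)) {
    tr <- sim$truth[i, ]
    tl <- ts$length[tr$tid]
    expect_true(tr$start >= 0 && tr$start + tr$flen <= tl)
    win_start <- if (tr$orient == 0) tr$start else tr$start + tr$flen - 30
    win <- substr(ts$seq[tr$tid], win_start + 1, win_start + 30)
    if (tr$orient == 1) {
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(win)))
    }
    expect_equal(sim$reads$seq1[i], win)
  }
})

test_that("simulated fragment fractions track theta", {
  set.seed(4)
  ts <- transcript_set(vapply(1:5, function(i) rand_dna(600), ""),
                       paste0("t", 1:5))
  theta <- c(0, .05, .1, .15, .3, .4)
  par <- model_params(theta = theta, frag_dist = gaussian_length_dist(200, 20),
                      read_dist = point_length_dist(30))
  sim <- simulate_dataset(par, ts, 20000, read_len = 30, qmodel = NULL)
  frac <- tabulate(sim$truth$tid, 5) / 20000
  se <- sqrt(theta[-1] * (1 - theta[-1]) / 20000)
  expect_true(all(abs(frac - theta[-1]) < 3.5 * se))
})

test_that("paired simulation reproduces the truncated fragment pmf", {
  set.seed(5)
  ts <- transcript_set(rand_dna(1000), "t")
  fd <- gaussian_length_dist(250, 15)
  par <- model_params(theta = c(0, 1), frag_dist = fd,
                      read_dist = point_length_dist(30))
  sim <- simulate_dataset(par, ts, 8000, paired = TRUE, read_len = 30,
                          qmodel = NULL)
  expect_true(all(nchar(sim$reads$seq2) == 30))
  # mate-implied fragment lengths equal the recorded truth by construction;
  # their distribution matches the truncated pmf
  d <- truncate_length_pmf(fd, 1000)
  f <- sim$truth$flen
  expect_equal(mean(f), dist_mean(d), tolerance = 1)
  hist_emp <- tabulate(f - d$min + 1L, length(d$pmf)) / length(f)
  expect_lt(max(abs(cumsum(hist_emp) - cumsum(d$pmf))), 0.02)  # KS-style
})

test_that("theoretical error injection follows the Phred rate", {
  set.seed(6)
  ts <- transcript_set(rand_dna(2000), "t")
  par <- model_params(theta = c(0, 1),
                      frag_dist = gaussian_length_dist(300, 10),
                      read_dist = point_length_dist(35))
  q20 <- quality_markov(setNames(1, "20"), matrix(1, 1, 1,
                                                  dimnames = list("20", "20")))
  sim <- simulate_dataset(par, ts, 4000, read_len = 35, qmodel = q20,
                          error_mode = "theoretical")
  # compare emitted reads to their source windows: error rate ~ 1%
  tr <- sim$truth
  win_start <- ifelse(tr$orient == 0, tr$start, tr$start + tr$flen - 35)
  win <- substring(ts$seq[tr$tid], win_start + 1, win_start + 35)
  rc <- tr$orient == 1
  win[rc] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(win[rc])))
  mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               sim$reads$seq1, win)
  rate <- sum(mm) / (4000 * 35)
  expect_equal(rate, 0.01, tolerance = 0.15)
})

test_that("simulation is seed-reproducible and writes files", {
  ts <- transcript_set(rand_dna(400, seed = 7), "t")
  par <- model_params(theta = c(0, 1),
                      frag_dist = gaussian_length_dist(200, 20),
                      read_dist = point_length_dist(30))
  set.seed(9); s1 <- simulate_dataset(par, ts, 50, read_len = 30)
  set.seed(9); s2 <- simulate_dataset(par, ts, 50, read_len = 30)
  expect_identical(s1$reads$seq1, s2$reads$seq1)
  expect_identical(s1$reads$qual1, s2$reads$qual1)
  pre <- file.path(tempdir(), "simtest")
  set.seed(9); simulate_dataset(par, ts, 50, read_len = 30, out_prefix = pre)
  rs <- read_sequences(paste0(pre, ".fq"))
  expect_identical(rs$seq1, s1$reads$seq1)
  truth <- read.table(paste0(pre, "_truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 50)
  expect_equal(sum(table(truth$transcript_id)), 50)
})
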