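test_that("read-gate matrices validate their inputs", {
  rgm <- read_gate_matrix(c("ACGT", "AAAA", "ACGA"), c(1, 2, 2), m = 3)
  expect_identical(rgm$n, 3L)
  expect_identical(rgm$P, 4L)
  expect_error(read_gate_matrix(c("ACGT"), c(1, 2)), "one gate")
  expect_error(read_gate_matrix(c("ACGT"), 5, m = 3), "out of range")
  expect_error(read_gate_matrix(c("ACNT"), 1), "outside")
})

test_that("read-count tables expand to one row per read", {
  g <- make_log_gates(3, 1, 8)
  tab <- read_count_table(g, h = c(3, 2, 1),
                          counts = rbind(c(2, 0, 1), c(0, 1, 0)),
                          seqs = c("AAA", "CCC"))
  rgm <- expand_read_counts(tab)
  expect_identical(rgm$n, 4L)
  expect_identical(rgm$gate, c(1L, 1L, 3L, 2L))
  expect_identical(sortseqtools:::decode_seqs(rgm$enc),
                   c("AAA", "AAA", "AAA", "CCC"))
})

test_that("information footprint matches closed-form tables", {
  # position 1 constant, position 2 perfectly correlated with the gate
  seqs <- c(rep("AC", 500), rep("AG", 500))
  gate <- c(rep(1L, 500), rep(2L, 500))
  fp <- information_footprint(read_gate_matrix(seqs, gate, m = 2))
  expect_equal(fp[1], 0)
  expect_equal(fp[2], 1)  # diagonal balanced 2x2 table carries 1 bit
  # base independent of gate: product table has zero MI
  seqs2 <- rep(c("AC", "AG"), times = 250)
  gate2 <- rep(c(1L, 1L, 2L, 2L), 125)
  fp2 <- information_footprint(read_gate_matrix(seqs2, gate2, m = 2))
  expect_lt(fp2[2], 1e-12)
})

test_that("least-squares fit recovers a known model from noiseless data", {
  set.seed(81)
  P <- 8
  ref <- strrep("A", P)
  model <- sample_additive_model(P, 3, 4)
  # targeted library: every free parameter directly observed
  lib <- make_targeted_library(ref)
  nu <- activity_to_mean(activity(model, lib), "repression", nu_null = 5)
  fit <- lsq_fit_additive(nu, lib, ref, mode = "repression", nu_null = 5)
  expect_true(fit$converged)
  expect_equal(fit$G0, model$G0, tolerance = 1e-6)
  expect_equal(fit$H, model$H, tolerance = 1e-6)
  # random library, expression map
  lib2 <- make_random_library(ref, 600, 2)
  nu2 <- activity_to_mean(activity(model, lib2), "expression")
  fit2 <- lsq_fit_additive(nu2, lib2, ref, mode = "expression")
  expect_equal(fit2$H, model$H, tolerance = 1e-4)
})

test_that("least-squares fit residuals respect the bounded map range", {
  set.seed(82)
  P <- 6
  ref <- strrep("A", P)
  model <- sample_additive_model(P, 3, 4)
  lib <- make_targeted_library(ref)
  nu <- activity_to_mean(activity(model, lib), "repression", nu_null = 5)
  # shifting all observations above nu_null cannot be fit exactly
  fit <- lsq_fit_additive(nu + 5, lib, ref, mode = "repression", nu_null = 5)
  expect_gt(fit$rss, 1e-2)
})

test_that("rank MI is invariant to monotone transforms and scaling of G", {
  set.seed(83)
  sim <- simulate_model_reads(P = 8, n_variants = 400,
                              reads_per_variant = 10)
  G <- activity(sim$model, sim$reads$enc)
  set.seed(1); a <- mi_of_model(sim$reads, G, block = 200)
  set.seed(1); b <- mi_of_model(sim$reads, 2 * G, block = 200)
  set.seed(1); d <- mi_of_model(sim$reads, exp(G), block = 200)
  expect_identical(a, b)
  expect_identical(a, d)
})

test_that("constant activity carries no mutual information about gates", {
  set.seed(84)
  sim <- simulate_model_reads(P = 8, n_variants = 1000,
                              reads_per_variant = 100)
  flat <- rep(0, sim$reads$n)
  expect_lt(mi_of_model(sim$reads, flat, block = 1000), 0.01)
})

test_that("the generating model beats shuffled models on mutual information", {
  set.seed(85)
  sim <- simulate_model_reads(P = 10, n_variants = 800,
                              reads_per_variant = 12)
  mi_true <- mi_of_model(sim$reads, sim$model, block = 500)
  wins <- 0L
  for (i in 1:20) {
    shuf <- sim$model
    mask <- shuf$H != 0
    shuf$H[mask] <- sample(shuf$H[mask])
    if (mi_true > mi_of_model(sim$reads, shuf, block = 500)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("the smoothed rank/gate table is a proper joint distribution", {
  set.seed(86)
  n <- 5000
  scores <- rnorm(n)
  gate <- sample.int(6, n, replace = TRUE)
  # reach inside: compressed, smoothed table must sum to 1
  kern <- sortseqtools:::rank_smoothing_kernel(10, 0.5)
  D <- matrix(tabulate((gate - 1) * 10 + ceiling(seq_len(n) / 500),
                       nbins = 60), 10, 6) / n
  sm <- kern %*% D
  expect_equal(sum(sm / sum(sm)), 1, tolerance = 1e-9)
  expect_true(all(sm >= 0))
})

test_that("Monte Carlo MI fit recovers a planted model on a small instance", {
  set.seed(87)
  sim <- simulate_model_reads(P = 6, n_variants = 600,
                              reads_per_variant = 20)
  fit <- mi_fit_montecarlo(sim$reads, strrep("A", 6), n_steps = 3000,
                           burn_in = 2000, block = 500)
  r <- h_correlation(sim$model$H, fit$H, sim$model$ref_enc)
  expect_gt(r, 0.8)
  expect_gt(fit$mi, 0.1)
  expect_identical(nrow(fit$trace) > 0, TRUE)
  # the trace climbs: final MI above the early values
  expect_gt(tail(fit$trace$mi, 1), fit$trace$mi[1] - 1e-9)
})
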