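test_that("gate centers use the bias-minimizing placement constant", {
  g <- six_gate_config(w = 0.8)
  b <- 0.8 / (exp(0.4) - exp(-0.4))
  expect_equal(b, 0.973822, tolerance = 1e-6)  # direct evaluation
  expect_equal(gate_centers(g), b * sqrt(g$lower * g$upper))
  expect_error(gate_centers(six_gate_config(semibounded = TRUE)),
               "semibounded")
})

test_that("simple estimators reduce to hand-computable cases", {
  g <- six_gate_config(w = 0.8)
  phi <- gate_centers(g)
  r <- c(0, 0, 120, 0, 0, 0)
  expect_equal(simple_mean(r, g), phi[3])  # single occupied gate
  expect_equal(simple_cv(r, g), 0)
  r2 <- c(0, 1, 0, 0, 1, 0)
  expect_equal(simple_mean(r2, g), (phi[2] + phi[5]) / 2)
  expect_equal(simple_cv(r2, g),
               abs(phi[2] - phi[5]) / (phi[2] + phi[5]))
  expect_error(simple_mean(c(0, 0, 0, 0, 0, 0), g), "no sorted cells")
  # the simple mean is a weighted average of occupied gate centers
  set.seed(41)
  for (i in 1:20) {
    r <- rpois(6, 3)
    if (sum(r) == 0) next
    m <- simple_mean(r, g)
    occ <- which(r > 0)
    expect_gte(m, min(phi[occ]))
    expect_lte(m, max(phi[occ]))
  }
})

test_that("MLE recovers parameters from near-asymptotic counts", {
  g <- make_log_gates(8, exp(-2), exp(2), semibounded = TRUE)
  p <- gate_probabilities(g, 0, 0.5)
  counts <- round(p * 1e6)
  fit <- mle_fit(counts, g)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_hat - 0), 0.5 / 100 * 0.5)
  expect_lt(abs(fit$sigma_hat - 0.5) / 0.5, 0.005)
  mom <- params_to_moments(fit$mu_hat, fit$sigma_hat)
  expect_equal(fit$nu_hat, unname(mom["nu"]))
  expect_equal(fit$c_hat, unname(mom["cv"]))
})

test_that("MLE agrees with a brute-force grid search of the likelihood", {
  set.seed(42)
  g <- six_gate_config(w = 0.8, semibounded = TRUE)
  r <- sample_output(0.4, 0.7, g, 200)$counts
  # independent oracle: evaluate the binned log-likelihood on a grid
  mu_grid <- seq(-1.5, 1.5, length.out = 200)
  sigma_grid <- seq(0.1, 1.6, length.out = 200)
  ll <- outer(mu_grid, sigma_grid, Vectorize(function(mu, s) {
    p <- gate_probabilities(g, mu, s)
    sum(r[r > 0] * log(p[r > 0]))
  }))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  fit <- mle_fit(r, g)
  expect_lt(abs(fit$mu_hat - mu_grid[best[1]]), diff(mu_grid[1:2]))
  expect_lt(abs(fit$sigma_hat - sigma_grid[best[2]]), diff(sigma_grid[1:2]))
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("MLE is invariant to uniform count scaling and flags degeneracy", {
  set.seed(43)
  g <- six_gate_config(semibounded = TRUE)
  r <- sample_output(0, 0.6, g, 150)$counts
  f1 <- mle_fit(r, g)
  f2 <- mle_fit(r * 37, g)
  expect_equal(f1$mu_hat, f2$mu_hat, tolerance = 1e-5)
  expect_equal(f1$sigma_hat, f2$sigma_hat, tolerance = 1e-5)
  # all mass in one bounded gate: scale unidentifiable
  gb <- six_gate_config(semibounded = FALSE)
  fit <- mle_fit(c(0, 0, 50, 0, 0, 0), gb)
  expect_false(fit$converged)
})

test_that("predicted fractions interpolate between model and outliers", {
  g <- make_log_gates(4, 1, exp(4))
  T <- rep(0.25, 4)
  # point mass inside gate 2
  mu <- log(sqrt(g$lower[2] * g$upper[2]))
  lam <- predicted_fractions(mu, 1e-6, g, T, gamma = 0.05)
  expect_equal(lam, c(0.0125, 0.9625, 0.0125, 0.0125), tolerance = 1e-9)
  p <- gate_probabilities(sortseqtools:::censored_gates(g), 0.5, 0.7)
  expect_equal(predicted_fractions(0.5, 0.7, g, T, gamma = 0), p)
  expect_error(predicted_fractions(0, 1, g, T, gamma = 1), "gamma")
})

test_that("robust MLE recovers the generating parameters exactly at the fixed point", {
  g <- make_log_gates(16, exp(-2), exp(2))
  T <- rep(1 / 16, 16)
  t <- predicted_fractions(0.35, 0.45, g, T, gamma = 0.05)
  fit <- robust_mle_fit(t, g, T, gamma = 0.05)
  expect_lt(abs(fit$mu_hat - 0.35), 1e-4)
  expect_lt(abs(fit$sigma_hat - 0.45), 1e-4)
})

test_that("gamma = 0 robust fit coincides with the censored plain MLE", {
  set.seed(44)
  g <- make_log_gates(12, exp(-1.5), exp(1.5))
  t <- sample_fractions(0.2, 0.5, g, 5000)
  T <- rep(1 / 12, 12)
  a <- robust_mle_fit(t, g, T, gamma = 0)
  b <- mle_fit(t, sortseqtools:::censored_gates(g))
  # same objective; residual difference is simplex termination noise
  expect_equal(a$mu_hat, b$mu_hat, tolerance = 1e-3)
  expect_equal(a$sigma_hat, b$sigma_hat, tolerance = 1e-3)
})

test_that("the outlier term protects the fit against contamination", {
  set.seed(45)
  g <- make_log_gates(16, exp(-2.2), exp(2.2))
  T <- rep(1 / 16, 16)
  mu_true <- -0.4
  sigma_true <- 0.35
  err <- function(fit) {
    abs(fit$mu_hat - mu_true) + abs(fit$sigma_hat - sigma_true)
  }
  plain_err <- robust_err <- numeric(10)
  for (i in 1:10) {
    clean <- sample_fractions(mu_true, sigma_true, g, 4000)
    t <- 0.95 * clean + 0.05 * rep(1 / 16, 16)  # 5 % uniform contamination
    plain_err[i] <- err(mle_fit(t, sortseqtools:::censored_gates(g)))
    robust_err[i] <- err(robust_mle_fit(t, g, rep(1 / 16, 16), gamma = 0.05))
  }
  expect_lt(mean(robust_err), mean(plain_err) / 3)
})

test_that("KL divergence matches hand computation and the Gibbs bound", {
  expect_equal(kl_divergence_bits(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * 1 + 0.5 * log2(2 / 3), tolerance = 1e-12)
  expect_equal(kl_divergence_bits(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence_bits(c(0, 1), c(0.4, 0.6)), log2(1 / 0.6))
  set.seed(46)
  for (i in 1:25) {
    t <- as.vector(rmultinom(1, 100, runif(6))) / 100
    lam <- runif(6)
    lam <- lam / sum(lam)
    expect_gte(kl_divergence_bits(t, lam), 0)
  }
  expect_error(kl_divergence_bits(c(0.5, 0.5), c(1, 0)), "incompat|fraction")
})

test_that("QC rules fire in order with the documented reasons", {
  t_ok <- c(0.05, 0.15, 0.3, 0.3, 0.15, 0.05)
  expect_identical(qc_filter(t_ok, 299)$reason, "reads")
  expect_identical(qc_filter(c(0.61, 0.1, 0.1, 0.1, 0.05, 0.04), 1000)$reason,
                   "concentration")  # one gate above 60 %
  expect_identical(qc_filter(c(0.05, 0.46, 0.45, 0.02, 0.01, 0.01),
                             1000)$reason, "concentration")  # top two > 90 %
  expect_identical(qc_filter(c(0.41, 0.2, 0.15, 0.1, 0.1, 0.04),
                             1000)$reason, "concentration")  # censoring gate
  lam_bad <- c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02)
  expect_identical(qc_filter(t_ok, 1000, lam_bad)$reason, "fit")
  expect_true(qc_filter(t_ok, 1000, t_ok)$keep)
})

test_that("clean high-depth variants pass QC with the fitted model", {
  set.seed(47)
  g <- make_log_gates(16, exp(-2), exp(2))
  T <- rep(1 / 16, 16)
  for (i in 1:5) {
    t <- sample_fractions(-0.2, 0.5, g, 1e4)
    fit <- robust_mle_fit(t, g, T)
    lam <- predicted_fractions(fit$mu_hat, fit$sigma_hat, g, T, 0.05)
    expect_true(qc_filter(t, 1e4, lam)$keep)
  }
})

test_that("reference estimator reproduces closed-form and consistency cases", {
  expect_equal(reference_estimate(rep(7, 12))$mu_hat, log(7))
  expect_equal(reference_estimate(rep(7, 12))$c_hat, 0)
  two <- reference_estimate(c(1, exp(2)))
  expect_equal(two$mu_hat, 1)
  expect_equal(two$sigma_hat, 1)
  set.seed(48)
  big <- reference_estimate(exp(1 + 0.3 * rnorm(1e5)))
  expect_lt(abs(big$mu_hat - 1), 0.01)
  expect_lt(abs(big$sigma_hat - 0.3) / 0.3, 0.01)
  expect_error(reference_estimate(numeric(0)), "empty")
})
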