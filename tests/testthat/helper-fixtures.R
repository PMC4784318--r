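# Shared fixture builders for the test suite. Everything is generated in
# code under set.seed() so the suite is deterministic and text-only.

# Six log-spaced gates of width w centered so that the middle boundary
# sits at nu = 1 (log fluorescence 0).
six_gate_config <- function(w = 0.8, semibounded = FALSE) {
  make_log_gates(6, exp(-3 * w), exp(3 * w), semibounded = semibounded)
}

# Multinomial gate fractions for a variant with given (mu, sigma); the
# extreme gates censor, as in a real sorter.
sample_fractions <- function(mu, sigma, gates, reads) {
  p <- gate_probabilities(sortseqtools:::censored_gates(gates), mu, sigma)
  as.vector(stats::rmultinom(1, reads, p)) / reads
}

# Simulated read-gate data from a known additive model: a random library
# at rate r_mut, expression-mapped means with input CV `cv`, reads
# sampled one cell each. Returns the model, per-variant truth and a
# read_gate_matrix plus per-variant mean estimates.
simulate_model_reads <- function(P = 20, R = 5, n_variants = 2000,
                                 r_mut = 2, reads_per_variant = 25,
                                 cv = 0.5, m_gates = 24, w = 0.3) {
  model <- sample_additive_model(P, 3, R)
  lib <- make_random_library(strrep("A", P), n_variants, r_mut)
  G <- activity(model, lib)
  nu <- activity_to_mean(G, "expression")
  sigma <- sqrt(log(1 + cv^2))
  lo <- log(min(nu)) - 2 * sigma
  gates <- make_log_gates(m_gates, exp(lo), exp(lo + m_gates * w))
  n <- n_variants * reads_per_variant
  variant_of_read <- rep(seq_len(n_variants), each = reads_per_variant)
  mu_read <- log(nu[variant_of_read]) - sigma^2 / 2
  x <- exp(mu_read + sigma * stats::rnorm(n))
  gi <- findInterval(x, c(gates$lower, Inf))
  keep <- gi >= 1 & gi <= m_gates
  nu_hat <- vapply(split(x, variant_of_read), mean, numeric(1))
  list(
    model = model, lib = lib, nu = nu, gates = gates, sigma = sigma,
    reads = read_gate_matrix(lib[variant_of_read[keep]], gi[keep],
                             m = m_gates),
    nu_hat = nu_hat
  )
}

# correlation between the free entries of two H matrices of one model
# family (mask taken from the first)
h_correlation <- function(H_true, H_fit, ref_enc) {
  mask <- matrix(TRUE, 4, ncol(H_true))
  mask[cbind(ref_enc, seq_len(ncol(H_true)))] <- FALSE
  stats::cor(H_true[mask], H_fit[mask])
}
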