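make_fraction_fixture <- function(n = 6, m = 32, seed = 61) {
  set.seed(seed)
  g <- make_log_gates(m, exp(-2), exp(2))
  frac <- t(vapply(seq_len(n), function(i) {
    sample_fractions(runif(1, -1, 1), runif(1, 0.2, 0.6), g, 5000)
  }, numeric(m)))
  T <- colMeans(frac)
  gate_fraction_table(g, T / sum(T), frac)
}

test_that("fraction tables enforce their normalization invariants", {
  tab <- make_fraction_fixture()
  expect_equal(unname(rowSums(tab$fractions)), rep(1, 6), tolerance = 1e-9)
  bad <- tab$fractions
  bad[2, ] <- bad[2, ] * 0.8
  expect_error(gate_fraction_table(tab$gates, tab$T, bad), "summing to 1")
})

test_that("regrouping to the identity partition is a no-op", {
  tab <- make_fraction_fixture()
  same <- regroup_gates(tab, as.list(seq_len(32)))
  expect_equal(same$fractions, tab$fractions)
  expect_equal(same$T, tab$T)
  expect_equal(same$gates$lower, tab$gates$lower)
})

test_that("pairing 32 gates yields 16 gates of doubled width", {
  tab <- make_fraction_fixture()
  pairs <- lapply(seq_len(16), function(k) c(2 * k - 1, 2 * k))
  t16 <- regroup_gates(tab, pairs)
  expect_identical(t16$gates$m, 16L)
  expect_equal(t16$gates$w, 2 * tab$gates$w, tolerance = 1e-9)
  expect_equal(unname(rowSums(t16$fractions)), rep(1, 6), tolerance = 1e-9)
  expect_equal(t16$fractions[, 1],
               tab$fractions[, 1] + tab$fractions[, 2])
  expect_equal(sum(t16$T), 1, tolerance = 1e-9)
  # group-label vector interface gives the same result
  t16b <- regroup_gates(tab, rep(seq_len(16), each = 2))
  expect_equal(t16b$fractions, t16$fractions)
  expect_error(regroup_gates(tab, list(c(1, 3), 2, 4:32)), "consecutive")
})

test_that("depth factors convert reads back to sorted cells", {
  g <- make_log_gates(3, 1, 8)
  counts <- rbind(a = c(100, 200, 50), b = c(400, 300, 50))
  h <- c(1000, 500, 100)
  tab <- read_count_table(g, h, counts)
  d <- depth_factors(tab)
  expect_equal(d, c(2, 1, 1))
  # conservation: estimated cells per gate reproduce h exactly
  cells <- sweep(counts, 2, d, `*`)
  expect_equal(colSums(cells), h)
  # a gate with cells but no reads is flagged
  tab2 <- read_count_table(g, h, rbind(c(1, 0, 3), c(2, 0, 4)))
  expect_warning(d2 <- depth_factors(tab2), "no reads")
  expect_true(is.na(d2[2]))
})

test_that("enrichment fractions are partial sums with CDF behavior", {
  g <- make_log_gates(3, 1, 8)
  tab <- gate_fraction_table(g, c(0.3, 0.3, 0.4),
                             rbind(v1 = c(0.2, 0.3, 0.5)))
  expect_equal(unname(enrichment_below(tab, "v1", m_prime = 2)), 0.5)
  expect_equal(unname(enrichment_below(tab, "v1", m_prime = 3)), 1)
  phis <- vapply(1:3, function(mp) {
    unname(enrichment_below(tab, "v1", mp))
  }, numeric(1))
  expect_true(all(diff(phis) >= 0))
  # read-count route weights by depth factors
  rct <- read_count_table(g, h = c(200, 100, 100),
                          counts = rbind(v1 = c(100, 100, 100)))
  # d = (2, 1, 1): cells = (200, 100, 100)
  expect_equal(unname(enrichment_below(rct, "v1", 1)), 0.5)
})

test_that("depth-weighted simple mean matches hand computation", {
  g <- make_log_gates(2, 1, exp(2))
  phi <- sqrt(g$lower * g$upper)
  counts <- rbind(v1 = c(10, 5))
  tab <- read_count_table(g, h = c(10, 10), counts = counts)
  # d = (1, 2): cells = (10, 10)
  expect_equal(unname(weighted_simple_mean(tab, "v1")),
               (10 * phi[1] + 10 * phi[2]) / 20)
  # uniform depth reduces to the plain simple mean with b = 1
  tabu <- read_count_table(g, h = c(10, 5), counts = counts)
  expect_equal(unname(weighted_simple_mean(tabu, "v1")),
               (10 * phi[1] + 5 * phi[2]) / 15)
  expect_error(weighted_simple_mean(
    read_count_table(make_log_gates(2, 1, 4, semibounded = TRUE),
                     c(1, 1), counts)), "bounded")
})

test_that("fold change is the ratio to the non-functional reference", {
  expect_equal(fold_change(4, 4), 1)
  expect_equal(fold_change(0, 3), 0)
  expect_equal(fold_change(2, 4), 0.5)
  expect_error(fold_change(1, 0), "positive")
})

test_that("estimates are invariant under identity regrouping of count tables", {
  set.seed(62)
  g <- make_log_gates(8, exp(-1.6), exp(1.6))
  counts <- matrix(rpois(3 * 8, 40), 3, 8)
  h <- colSums(counts) * c(1, 2, 1, 1, 3, 1, 1, 2)
  tab <- read_count_table(g, h, counts)
  same <- regroup_gates(tab, as.list(1:8))
  expect_equal(weighted_simple_mean(same), weighted_simple_mean(tab))
  expect_equal(enrichment_below(same, m_prime = 4),
               enrichment_below(tab, m_prime = 4))
})
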