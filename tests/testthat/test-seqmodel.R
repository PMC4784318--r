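# independent oracle: evaluate the activity by explicit indicator sums
activity_oracle <- function(model, seq_str) {
  q <- strsplit(seq_str, "")[[1]]
  G <- model$G0
  for (p in seq_along(q)) {
    G <- G + model$H[q[p], p]
  }
  if (!is.null(model$J)) {
    for (p1 in seq_along(q)) {
      for (p2 in seq_along(q)) {
        if (p1 < p2) {
          q1 <- match(q[p1], c("A", "C", "G", "T"))
          q2 <- match(q[p2], c("A", "C", "G", "T"))
          G <- G + model$J[q1, p1, q2, p2]
        }
      }
    }
  }
  G
}

test_that("additive activity follows the indicator-sum definition", {
  set.seed(71)
  model <- sample_additive_model(P = 12, G0 = 3, R = 4)
  ref <- model$reference
  expect_equal(activity(model, ref), 3)  # all indicators off
  # single mutant: baseline plus one term
  mut <- sub("^A", "G", ref)
  expect_equal(activity(model, mut), unname(3 + model$H["G", 1]))
  # random sequences against the oracle
  lib <- make_random_library(ref, 30, 3)
  expect_equal(activity(model, lib),
               vapply(lib, activity_oracle, numeric(1), model = model),
               ignore_attr = TRUE)
})

test_that("pairwise terms add on top of the additive model", {
  set.seed(72)
  model <- sample_additive_model(P = 10, G0 = 3, R = 4)
  with_j <- sample_interaction_terms(model, S = 0.8)
  lib <- make_random_library(model$reference, 25, 3)
  expect_equal(activity(with_j, lib),
               vapply(lib, activity_oracle, numeric(1), model = with_j),
               ignore_attr = TRUE)
  # S = 0 leaves the additive activities untouched
  no_j <- sample_interaction_terms(model, S = 0)
  expect_equal(activity(no_j, lib), activity(model, lib))
  # symmetric storage
  Jm <- matrix(with_j$J, 40, 40)
  expect_equal(Jm, t(Jm))
})

test_that("random models have the prescribed robustness statistics", {
  set.seed(73)
  R <- 10
  model <- sample_additive_model(P = 50, G0 = 3, R = R)
  free <- model$H[model$H != 0]
  expect_equal(mean(free), -3 / R, tolerance = 0.15)
  expect_equal(sd(free), 4 * 3 / (3 * R), tolerance = 0.1)
  # after exactly R random mutations, half of variants drop below G = 0
  n_draw <- 1e4
  frac_below <- mean(replicate(n_draw, {
    pos <- sample.int(50, R)
    bases <- vapply(pos, function(p) sample(setdiff(1:4, model$ref_enc[p]), 1),
                    integer(1))
    3 + sum(model$H[cbind(bases, pos)]) < 0
  }))
  expect_lt(abs(frac_below - 0.5), 0.05)
})

test_that("interaction terms have scale S G0 / R", {
  set.seed(74)
  model <- sample_additive_model(P = 50, G0 = 3, R = 6)
  wj <- sample_interaction_terms(model, S = 1.2)
  vals <- wj$J[wj$J != 0]
  expect_gt(length(vals), 1e4)
  expect_equal(sd(vals), 1.2 * 3 / 6, tolerance = 0.05)
  expect_equal(mean(vals), 0, tolerance = 0.05)
})

test_that("activity-to-mean maps are monotone with the stated anchors", {
  expect_equal(activity_to_mean(0, "expression"), 2)
  expect_equal(activity_to_mean(0, "repression", nu_null = 6), 3)
  expect_equal(activity_to_mean(-50, "repression", nu_null = 6), 6,
               tolerance = 1e-9)
  g <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(activity_to_mean(g, "expression")) > 0))
  expect_true(all(diff(activity_to_mean(g, "repression", 2)) < 0))
  expect_error(activity_to_mean(0, "repression", nu_null = -1))
})

test_that("random libraries carry the requested mutation load", {
  set.seed(75)
  ref <- strrep("A", 50)
  lib <- make_random_library(ref, 1e4, r_mut = 3)
  n_mut <- vapply(strsplit(lib, ""), function(q) sum(q != "A"), integer(1))
  se <- sqrt(3 * (1 - 3 / 50) / 1e4)
  expect_lt(abs(mean(n_mut) - 3), 3 * se)
  # no position ever carries a double substitution: bases stay in ACGT
  expect_true(all(grepl("^[ACGT]+$", lib)))
  expect_error(make_random_library(ref, 10, r_mut = 50))
})

test_that("targeted libraries enumerate all single mutants once", {
  lib <- make_targeted_library(strrep("A", 50))
  expect_length(lib, 151)
  expect_identical(anyDuplicated(lib), 0L)
  expect_identical(lib[1], strrep("A", 50))
  n_mut <- vapply(strsplit(lib[-1], ""), function(q) sum(q != "A"),
                  integer(1))
  expect_true(all(n_mut == 1))
  expect_length(make_targeted_library("A"), 4)
})

test_that("models and libraries round-trip through their file formats", {
  set.seed(76)
  model <- sample_interaction_terms(
    sample_additive_model(P = 6, G0 = 3, R = 3), S = 0.5)
  path <- withr::local_tempfile()
  write_activity_model(model, path)
  back <- read_activity_model(path)
  expect_equal(back$G0, model$G0)
  expect_equal(back$H, model$H)
  expect_equal(back$J, model$J)
  lib <- make_random_library(strrep("A", 8), 20, 2)
  fpath <- withr::local_tempfile(fileext = ".fasta")
  write_library_fasta(lib, fpath)
  expect_identical(unname(read_library_fasta(fpath)), lib)
  file.remove(paste0(path, ".interactions"))
})

test_that("gauge fixing rejects nonzero reference entries", {
  H <- matrix(0.1, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(activity_model(1, H, strrep("A", 5)), "gauge")
})
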