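#' Per-read sequence/gate table for model inference
#'
#' Organizes sort-seq data as one row per sequencing read: the read's
#' sequence and the index of the sorting gate it came from (the binary
#' table \eqn{D_{ij}} with \eqn{D_{ij} = 1} iff read \eqn{i} was found in
#' gate \eqn{j}). This is the input to the information footprint and the
#' mutual-information model fit.
#'
#' @param seqs character vector of per-read sequences (one common length).
#' @param gate integer vector of per-read gate indices in \code{1..m}.
#' @param m number of gates (default \code{max(gate)}).
#' @return Object of class \code{read_gate_matrix} with fields
#'   \code{enc} (integer matrix, reads x positions), \code{gate},
#'   \code{n}, \code{m}, \code{P}.
#' @export
read_gate_matrix <- function(seqs, gate, m = max(gate)) {
  enc <- encode_seqs(seqs)
  gate <- as.integer(gate)
  if (length(gate) != nrow(enc)) stop("one gate index per read required")
  if (any(gate < 1 | gate > m)) stop("gate indices out of range")
  structure(list(enc = enc, gate = gate, n = nrow(enc), m = as.integer(m),
                 P = ncol(enc)),
            class = "read_gate_matrix")
}

#' @export
print.read_gate_matrix <- function(x, ...) {
  cat(sprintf("<read_gate_matrix> %d reads x %d positions, %d gates\n",
              x$n, x$P, x$m))
  invisible(x)
}

#' Expand a read-count table into per-read rows
#'
#' Replicates each variant's sequence once per (depth-unadjusted) read in
#' each gate, producing the [read_gate_matrix()] needed for MI-based
#' inference.
#'
#' @param table a \code{read_count_table} carrying sequences.
#' @return A \code{read_gate_matrix}.
#' @export
expand_read_counts <- function(table) {
  stopifnot(inherits(table, "read_count_table"))
  if (is.null(table$seqs)) stop("read-count table carries no sequences")
  counts <- round(table$counts)
  idx <- rep(seq_len(nrow(counts)), rowSums(counts))
  gate <- unlist(lapply(seq_len(nrow(counts)), function(i) {
    rep(seq_len(ncol(counts)), counts[i, ])
  }), use.names = FALSE)
  read_gate_matrix(table$seqs[idx], gate, m = table$gates$m)
}

# one-hot design over free (non-reference) H entries; column k maps to
# free_pos[k]/free_base[k]
one_hot_free <- function(enc, ref_enc) {
  n <- nrow(enc)
  P <- ncol(enc)
  free_pos <- rep(seq_len(P), each = 3)
  free_base <- unlist(lapply(seq_len(P), function(p) setdiff(1:4, ref_enc[p])))
  X <- matrix(0, n, 3 * P)
  for (k in seq_len(3 * P)) {
    X[, k] <- as.numeric(enc[, free_pos[k]] == free_base[k])
  }
  list(X = X, free_pos = free_pos, free_base = free_base)
}

free_to_H <- function(theta_h, free_pos, free_base, P) {
  H <- matrix(0, 4, P, dimnames = list(DNA_BASES, NULL))
  H[cbind(free_base, free_pos)] <- theta_h
  H
}

#' Least-squares fit of an additive activity model
#'
#' Fits \eqn{(G_0, H)} by nonlinear least squares on per-variant estimated
#' means: the activity \eqn{G(Q) = G_0 + \sum_p H_{p,Q_p}} is pushed
#' through a monotone activity-to-fluorescence map and the squared
#' difference to \eqn{\hat\nu_i} is minimized (Levenberg-Marquardt with an
#' analytic Jacobian). Two maps are supported (see [activity_to_mean()]):
#' the two-state repression model \eqn{\nu = \nu_{null}(1 + e^G)^{-1}}
#' and the expression map \eqn{\nu = 1 + e^G}.
#'
#' The reference base at each position is gauge-fixed to \eqn{H = 0};
#' entries never observed mutated in the data are unidentifiable and
#' returned as 0.
#'
#' @param nu_hat per-variant estimated mean fluorescence.
#' @param seqs per-variant sequences (same order).
#' @param reference reference sequence defining the gauge.
#' @param mode activity-to-mean map, \code{"repression"} or
#'   \code{"expression"}.
#' @param nu_null non-functional mean (repression mode).
#' @param init optional [activity_model()] used as a starting point.
#' @param loss \code{"absolute"} minimizes plain squared differences
#'   \eqn{\sum_i (\hat\nu_i - \nu_i(\theta))^2}; \code{"relative"}
#'   divides each residual by the model prediction,
#'   \eqn{\sum_i (\hat\nu_i/\nu_i(\theta) - 1)^2}; \code{"log"} works on
#'   the log-fluorescence scale,
#'   \eqn{\sum_i (\log\hat\nu_i - \log\nu_i(\theta))^2}. When
#'   measurement noise is multiplicative (constant CV, log-normal cells)
#'   the log loss is the maximum-likelihood choice and the relative loss
#'   its first-order approximation; the absolute loss matches the
#'   classical recipe but overweights bright variants.
#' @return An [activity_model()] with extra fields \code{converged},
#'   \code{rss} (residual sum of squares) and \code{fitted}.
#' @export
lsq_fit_additive <- function(nu_hat, seqs, reference,
                             mode = c("repression", "expression"),
                             nu_null = 1, init = NULL,
                             loss = c("absolute", "relative", "log")) {
  mode <- match.arg(mode)
  loss <- match.arg(loss)
  enc <- encode_seqs(seqs)
  ref_enc <- as.vector(encode_seqs(reference))
  P <- length(ref_enc)
  if (ncol(enc) != P) stop("sequence length does not match reference")
  n <- nrow(enc)
  if (n < 3 * P + 1) {
    warning("fewer observations than free parameters; fit may be degenerate")
  }
  oh <- one_hot_free(enc, ref_enc)
  X <- oh$X

  predict_fun <- function(G) activity_to_mean(G, mode, nu_null)
  dpred_dG <- function(G) {
    if (mode == "repression") -nu_null * exp(G) / (1 + exp(G))^2
    else exp(G)
  }

  if (is.null(init)) {
    # invert the map on clamped observations, then linear least squares
    g0 <- if (mode == "repression") {
      ratio <- pmax(nu_null / pmax(nu_hat, 1e-9 * nu_null) - 1, 1e-3)
      log(ratio)
    } else {
      log(pmax(nu_hat - 1, 1e-3))
    }
    theta0 <- stats::lm.fit(cbind(1, X), g0)$coefficients
    theta0[is.na(theta0)] <- 0
  } else {
    theta0 <- c(init$G0,
                init$H[cbind(oh$free_base, oh$free_pos)])
  }

  if (loss == "absolute") {
    resid_fun <- function(theta) {
      G <- theta[1] + as.vector(X %*% theta[-1])
      nu_hat - predict_fun(G)
    }
    jac_fun <- function(theta) {
      G <- theta[1] + as.vector(X %*% theta[-1])
      -dpred_dG(G) * cbind(1, X)
    }
  } else if (loss == "relative") {
    resid_fun <- function(theta) {
      G <- theta[1] + as.vector(X %*% theta[-1])
      nu_hat / predict_fun(G) - 1
    }
    jac_fun <- function(theta) {
      G <- theta[1] + as.vector(X %*% theta[-1])
      pred <- predict_fun(G)
      (-nu_hat * dpred_dG(G) / pred^2) * cbind(1, X)
    }
  } else {
    if (any(nu_hat <= 0)) stop("log loss requires positive `nu_hat`")
    log_nu <- log(nu_hat)
    resid_fun <- function(theta) {
      G <- theta[1] + as.vector(X %*% theta[-1])
      log_nu - log(predict_fun(G))
    }
    jac_fun <- function(theta) {
      G <- theta[1] + as.vector(X %*% theta[-1])
      pred <- predict_fun(G)
      (-dpred_dG(G) / pred) * cbind(1, X)
    }
  }
  fit <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fun, jac = jac_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  theta <- unname(fit$par)
  model <- activity_model(theta[1],
                          free_to_H(theta[-1], oh$free_pos, oh$free_base, P),
                          reference)
  model$converged <- fit$info %in% 1:4
  model$rss <- sum(fit$fvec^2)
  model$fitted <- predict_fun(theta[1] + as.vector(X %*% theta[-1]))
  model
}

#' Per-position information footprint
#'
#' For each sequence position \eqn{p}, tabulates reads by (base, gate)
#' into \eqn{a_p(q, j)}, normalizes by the total read count
#' (\eqn{A_p = a_p / n}), and returns the mutual information in bits
#' between base identity and sorting gate:
#' \deqn{I(p) = \sum_{q,j} A_p(q,j) \log_2
#'   \frac{A_p(q,j)}{A_p(q) A_p(j)}.}
#' Positions whose base identity carries no information about sorting
#' outcome score 0; functionally sensitive positions stand out.
#'
#' @param reads a [read_gate_matrix()].
#' @return Numeric vector of length \code{P}, MI in bits per position.
#' @export
information_footprint <- function(reads) {
  stopifnot(inherits(reads, "read_gate_matrix"))
  n <- reads$n
  m <- reads$m
  vapply(seq_len(reads$P), function(p) {
    a <- matrix(tabulate((reads$gate - 1L) * 4L + reads$enc[, p],
                         nbins = 4L * m), 4L, m) / n
    aq <- rowSums(a)
    aj <- colSums(a)
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / outer(aq, aj)[nz]))
  }, numeric(1))
}

# Rank-smoothing kernel: discrete gaussian CDF differences along the
# compressed rank axis, sd = kernel_frac * (number of compressed rows).
rank_smoothing_kernel <- function(n_rows, sd_rows) {
  i <- matrix(seq_len(n_rows), n_rows, n_rows)
  diff_ij <- i - t(i)
  stats::pnorm(diff_ij / sd_rows) - stats::pnorm((diff_ij - 1) / sd_rows)
}

# Shared MI-from-rank computation: given per-read scores and the per-read
# gate indices, sort, compress into blocks, smooth, and return MI (bits).
mi_from_scores <- function(scores, gate, m, block, kernel_frac, tiebreak) {
  n <- length(scores)
  ord <- order(scores, tiebreak)
  bid <- ceiling(seq_len(n) / block)
  B <- bid[n]
  counts <- tabulate((gate[ord] - 1L) * B + bid, nbins = B * m)
  D <- matrix(counts, B, m) / n
  if (kernel_frac > 0 && B > 1) {
    D <- rank_smoothing_kernel(B, kernel_frac * B) %*% D
    D <- D / sum(D)  # edge truncation of the kernel loses a little mass
  }
  ri <- rowSums(D)
  cj <- colSums(D)
  nz <- D > 0
  sum(D[nz] * log2(D[nz] / outer(ri, cj)[nz]))
}

#' Mutual information between a model's activity ranking and sorting gates
#'
#' Ranks reads by model activity \eqn{G} (ascending, with a seeded random
#' tie-break so constant models carry no spurious structure), compresses
#' the read-by-gate indicator table by summing consecutive blocks of
#' \code{block} reads, smooths along the rank axis with a discrete
#' gaussian kernel of standard deviation \code{kernel_frac} times the
#' number of compressed rows, and returns the mutual information (bits)
#' of the resulting joint rank/gate distribution. Because only the
#' ranking of \eqn{G} enters, the statistic is invariant to any strictly
#' increasing transform of the activities — in particular to overall
#' scaling of \eqn{H} — which is the degree of freedom the Monte Carlo
#' fit renormalizes away.
#'
#' @param reads a [read_gate_matrix()].
#' @param model an [activity_model()], or a precomputed numeric vector of
#'   per-read activities.
#' @param block number of reads summed per compressed row (default 1000).
#' @param kernel_frac smoothing bandwidth as a fraction of the compressed
#'   row count (default 0.01).
#' @return Mutual information in bits.
#' @export
mi_of_model <- function(reads, model, block = 1000, kernel_frac = 0.01) {
  stopifnot(inherits(reads, "read_gate_matrix"))
  if (reads$n < block) stop("need at least `block` reads")
  G <- if (is.numeric(model)) {
    stopifnot(length(model) == reads$n)
    model
  } else {
    activity(model, reads$enc)
  }
  tiebreak <- stats::runif(reads$n)
  mi_from_scores(G, reads$gate, reads$m, block, kernel_frac, tiebreak)
}

#' Monte Carlo maximization of model/data mutual information
#'
#' Fits the additive parameters \eqn{H} by a Metropolis-like search on the
#' mutual information between the activity ranking and the sorting gates:
#' at each step one randomly chosen free \eqn{H_{p,q}} is perturbed by
#' Normal(0, 1); if the MI did not decrease the change is kept, and if it
#' decreased by \eqn{\delta} it is kept with probability
#' \eqn{2^{-n\delta}} (\eqn{n} = total reads). After each kept step the
#' parameters are renormalized — divided by the standard deviation of the
#' free entries — because a proportional rescaling of all \eqn{H} does
#' not change the activity ranking and would otherwise drift freely.
#' The reported model is the ensemble average of the normalized \eqn{H}
#' over the post-burn-in steps.
#'
#' Since the ranking (hence the MI) is also invariant to a global sign
#' flip of \eqn{H}, the averaged model is oriented so that activity
#' correlates positively with gate index; flip the sign for assays where
#' activity suppresses fluorescence.
#'
#' @param reads a [read_gate_matrix()].
#' @param reference reference sequence fixing the gauge (\eqn{H = 0} for
#'   the reference base at each position).
#' @param init starting point: \code{"counts"} (default) seeds each free
#'   \eqn{H_{p,q}} with the mean gate index of the reads carrying base
#'   \eqn{q} at position \eqn{p}, relative to the reference base — a
#'   crude moment estimate that keeps the zero-temperature search out of
#'   local optima; \code{"random"} draws standard-normal entries; or an
#'   [activity_model()] to refine.
#' @param n_steps total Monte Carlo steps (default 300000).
#' @param burn_in steps before ensemble averaging starts (default half of
#'   \code{n_steps}).
#' @param block,kernel_frac passed to the MI computation.
#' @param trace_every record the MI trace every this many steps.
#' @return An [activity_model()] (ensemble-averaged, orientation-fixed)
#'   with fields \code{mi} (final MI of the averaged model),
#'   \code{trace} (data frame step/mi), and \code{acceptance_rate}.
#' @export
mi_fit_montecarlo <- function(reads, reference, init = "counts",
                              n_steps = 300000, burn_in = n_steps %/% 2,
                              block = 1000, kernel_frac = 0.01,
                              trace_every = max(1, n_steps %/% 200)) {
  stopifnot(inherits(reads, "read_gate_matrix"))
  ref_enc <- as.vector(encode_seqs(reference))
  P <- reads$P
  if (length(ref_enc) != P) stop("reference length does not match reads")
  n <- reads$n
  m <- reads$m

  free_pos <- rep(seq_len(P), each = 3)
  free_base <- unlist(lapply(seq_len(P), function(p) setdiff(1:4, ref_enc[p])))
  n_free <- 3 * P
  # reads carrying free entry k (base free_base[k] at position free_pos[k])
  carriers <- lapply(seq_len(n_free), function(k) {
    which(reads$enc[, free_pos[k]] == free_base[k])
  })

  h <- if (inherits(init, "activity_model")) {
    init$H[cbind(free_base, free_pos)]
  } else if (identical(init, "random") || is.null(init)) {
    stats::rnorm(n_free)
  } else if (identical(init, "counts")) {
    vapply(seq_len(n_free), function(k) {
      p <- free_pos[k]
      ref_reads <- reads$enc[, p] == ref_enc[p]
      if (length(carriers[[k]]) == 0 || !any(ref_reads)) return(0)
      mean(reads$gate[carriers[[k]]]) - mean(reads$gate[ref_reads])
    }, numeric(1))
  } else {
    stop("`init` must be \"counts\", \"random\", or an activity_model")
  }
  s <- stats::sd(h)
  if (s > 0) h <- h / s

  G <- numeric(n)
  for (k in seq_len(n_free)) G[carriers[[k]]] <- G[carriers[[k]]] + h[k]
  tiebreak <- stats::runif(n)

  mi <- mi_from_scores(G, reads$gate, m, block, kernel_frac, tiebreak)
  h_sum <- numeric(n_free)
  n_avg <- 0L
  accepted <- 0L
  trace_steps <- integer(0)
  trace_mi <- numeric(0)

  for (step in seq_len(n_steps)) {
    k <- sample.int(n_free, 1)
    delta_h <- stats::rnorm(1)
    G_new <- G
    G_new[carriers[[k]]] <- G_new[carriers[[k]]] + delta_h
    mi_new <- mi_from_scores(G_new, reads$gate, m, block, kernel_frac,
                             tiebreak)
    keep <- if (mi_new >= mi) TRUE else stats::runif(1) < 2^(-n * (mi - mi_new))
    if (keep) {
      accepted <- accepted + 1L
      h[k] <- h[k] + delta_h
      s <- stats::sd(h)
      if (s > 0) {
        h <- h / s
        G <- G_new / s
      } else {
        G <- G_new
      }
      mi <- mi_new
    }
    if (step > burn_in) {
      h_sum <- h_sum + h
      n_avg <- n_avg + 1L
    }
    if (step %% trace_every == 0) {
      trace_steps <- c(trace_steps, step)
      trace_mi <- c(trace_mi, mi)
    }
  }

  h_avg <- if (n_avg > 0) h_sum / n_avg else h
  G_avg <- numeric(n)
  for (k in seq_len(n_free)) {
    G_avg[carriers[[k]]] <- G_avg[carriers[[k]]] + h_avg[k]
  }
  # orientation convention: activity increases with gate index
  if (stats::sd(G_avg) > 0 && stats::cor(G_avg, reads$gate) < 0) {
    h_avg <- -h_avg
    G_avg <- -G_avg
  }
  model <- activity_model(0, free_to_H(h_avg, free_pos, free_base, P),
                          paste(DNA_BASES[ref_enc], collapse = ""))
  model$mi <- mi_from_scores(G_avg, reads$gate, m, block, kernel_frac,
                             tiebreak)
  model$trace <- data.frame(step = trace_steps, mi = trace_mi)
  model$acceptance_rate <- accepted / n_steps
  model
}
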