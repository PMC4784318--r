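#' Read and write gate-fraction tables
#'
#' The on-disk format mirrors published sort-seq exports: a main TSV with
#' column \code{variant_id} followed by one fraction column per gate
#' (\code{f_1 .. f_m}), and a gate sidecar file (see
#' [write_gate_config()]) carrying \code{lower}, \code{upper} and the
#' per-gate sorted fraction column \code{T}. Rows whose fractions do not
#' sum to 1 within \code{tol} are rejected with their line numbers.
#'
#' @param path main table path.
#' @param gate_path sidecar path (default \code{paste0(path, ".gates")}).
#' @param tol per-row sum tolerance (default 1e-6).
#' @return \code{read_gate_fraction_table}: a [gate_fraction_table()];
#'   the writer returns \code{path} invisibly.
#' @export
read_gate_fraction_table <- function(path, gate_path = paste0(path, ".gates"),
                                     tol = 1e-6) {
  gc <- read_gate_config(gate_path)
  if (!"T" %in% names(gc$extra)) {
    stop("gate sidecar must carry per-gate sorted fractions in column `T`")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- gc$gates$m
  if (ncol(df) != m + 1) {
    stop(sprintf("expected %d fraction columns after variant_id, found %d",
                 m, ncol(df) - 1))
  }
  frac <- as.matrix(df[, -1])
  bad <- abs(rowSums(frac) - 1) > tol
  if (any(bad)) {
    stop(sprintf("fraction rows not summing to 1 (data line%s %s)",
                 if (sum(bad) > 1) "s" else "",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  gate_fraction_table(gc$gates, gc$extra$T, frac, ids = df[[1]])
}

#' @rdname read_gate_fraction_table
#' @param table a [gate_fraction_table()].
#' @export
write_gate_fraction_table <- function(table, path,
                                      gate_path = paste0(path, ".gates")) {
  write_gate_config(table$gates, gate_path,
                    extra = data.frame(T = table$T))
  df <- data.frame(variant_id = table$ids, table$fractions,
                   check.names = FALSE)
  colnames(df) <- c("variant_id", paste0("f_", seq_len(table$gates$m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write read-count tables
#'
#' Main TSV columns: \code{variant_id}, optional \code{seq}, then
#' \code{r_1 .. r_m}; the gate sidecar carries \code{lower},
#' \code{upper} and the per-gate sorted-cell totals \code{h}.
#'
#' @param path main table path.
#' @param gate_path sidecar path (default \code{paste0(path, ".gates")}).
#' @return \code{read_read_count_table}: a [read_count_table()]; the
#'   writer returns \code{path} invisibly.
#' @export
read_read_count_table <- function(path, gate_path = paste0(path, ".gates")) {
  gc <- read_gate_config(gate_path)
  if (!"h" %in% names(gc$extra)) {
    stop("gate sidecar must carry per-gate sorted-cell totals in column `h`")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  seqs <- if ("seq" %in% names(df)) df$seq else NULL
  cnt <- as.matrix(df[, grep("^r_", names(df)), drop = FALSE])
  if (ncol(cnt) != gc$gates$m) {
    stop("count columns do not match the number of gates")
  }
  read_count_table(gc$gates, gc$extra$h, cnt, ids = df$variant_id,
                   seqs = seqs)
}

#' @rdname read_read_count_table
#' @param table a [read_count_table()].
#' @export
write_read_count_table <- function(table, path,
                                   gate_path = paste0(path, ".gates")) {
  write_gate_config(table$gates, gate_path,
                    extra = data.frame(h = table$h))
  df <- data.frame(variant_id = table$ids, stringsAsFactors = FALSE)
  if (!is.null(table$seqs)) df$seq <- table$seqs
  cnt <- table$counts
  colnames(cnt) <- paste0("r_", seq_len(table$gates$m))
  df <- cbind(df, cnt)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic gate-fraction library with known ground truth
#'
#' Emulates a published-style gate-fraction dataset: per-variant true
#' means are drawn log-uniformly over \code{nu_range} and log-widths
#' uniformly over \code{sigma_range}; each variant's reads are a
#' multinomial sample of size \code{reads_per_variant} from its gate
#' probabilities (with the extreme gates censoring, matching how a real
#' sorter collects the tails). The observable table and the hidden truth
#' are returned together so estimator recovery can be tested end to end.
#'
#' @param n_variants number of variants.
#' @param nu_range length-2 range of true means.
#' @param sigma_range length-2 range of true log-widths.
#' @param gates a \code{gate_config}.
#' @param reads_per_variant reads (cells) sampled per variant.
#' @return List with \code{table} (a [gate_fraction_table()]) and
#'   \code{truth} (data frame \code{variant_id, nu, sigma, mu, cv}).
#' @export
generate_fixture_library <- function(n_variants, nu_range, sigma_range,
                                     gates, reads_per_variant = 1000) {
  nu <- exp(stats::runif(n_variants, log(nu_range[1]), log(nu_range[2])))
  sigma <- stats::runif(n_variants, sigma_range[1], sigma_range[2])
  mu <- log(nu) - sigma^2 / 2
  cg <- censored_gates(gates)
  frac <- t(vapply(seq_len(n_variants), function(i) {
    p <- gate_probabilities(cg, mu[i], sigma[i])
    as.vector(stats::rmultinom(1, reads_per_variant, p)) / reads_per_variant
  }, numeric(gates$m)))
  T <- colMeans(frac)
  T <- T / sum(T)
  ids <- sprintf("v%04d", seq_len(n_variants))
  list(
    table = gate_fraction_table(gates, T, frac, ids = ids),
    truth = data.frame(variant_id = ids, nu = nu, sigma = sigma, mu = mu,
                       cv = sqrt(exp(sigma^2) - 1),
                       reads = reads_per_variant,
                       stringsAsFactors = FALSE)
  )
}

#' Estimate every variant of a gate-fraction table
#'
#' Runs the outlier-robust censored MLE ([robust_mle_fit()]) on each row
#' of a gate-fraction table, applies the QC filter, and returns a tidy
#' results table.
#'
#' @param table a [gate_fraction_table()].
#' @param reads per-variant total read counts (single value recycled);
#'   used by the QC read-depth rule.
#' @param gamma assumed outlier fraction.
#' @param thresholds a [qc_thresholds()] list.
#' @return Data frame with one row per variant: \code{variant_id},
#'   \code{nu_hat, c_hat, mu_hat, sigma_hat, converged, dkl_bits,
#'   qc_keep, qc_reason}.
#' @export
estimate_table <- function(table, reads = 1000, gamma = 0.05,
                           thresholds = qc_thresholds()) {
  stopifnot(inherits(table, "gate_fraction_table"))
  nv <- nrow(table$fractions)
  reads <- rep_len(reads, nv)
  out <- vector("list", nv)
  for (i in seq_len(nv)) {
    t_i <- table$fractions[i, ]
    fit <- robust_mle_fit(t_i, table$gates, table$T, gamma = gamma)
    lam <- predicted_fractions(fit$mu_hat, fit$sigma_hat, table$gates,
                               table$T, gamma)
    qc <- qc_filter(t_i, reads[i], lam, thresholds)
    out[[i]] <- data.frame(
      variant_id = table$ids[i], nu_hat = fit$nu_hat, c_hat = fit$c_hat,
      mu_hat = fit$mu_hat, sigma_hat = fit$sigma_hat,
      converged = fit$converged,
      dkl_bits = kl_divergence_bits(t_i, lam),
      qc_keep = qc$keep, qc_reason = qc$reason,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
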