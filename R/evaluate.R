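#' Bias, mean squared error, and efficiency of an estimator
#'
#' Over repeated simulated experiments, the bias of an estimator
#' \eqn{\hat\theta} of \eqn{\theta} is
#' \eqn{\beta = \langle \hat\theta - \theta \rangle} and its precision is
#' the MSE \eqn{\langle (\hat\theta - \theta)^2 \rangle}. Efficiency
#' compares a binned (sort-seq) estimator to the full-resolution reference
#' estimator computed from the same number of exact measurements:
#' \eqn{\eta = \mathrm{MSE}(\mathrm{reference}) /
#' \mathrm{MSE}(\mathrm{sort\text{-}seq})}, so \eqn{\eta \approx 1} means
#' binning loses essentially no information.
#'
#' @param estimates numeric vector of repeated estimates.
#' @param truth true parameter value.
#' @return \code{estimator_bias}: list with \code{bias} and
#'   \code{relative_bias} (\code{NA} if \code{truth == 0});
#'   \code{estimator_mse}: the MSE; \code{estimator_efficiency}: the
#'   ratio \eqn{\eta}.
#' @export
estimator_bias <- function(estimates, truth) {
  if (length(estimates) == 0) stop("no estimates")
  b <- mean(estimates - truth)
  list(bias = b,
       relative_bias = if (truth != 0) b / truth else NA_real_)
}

#' @rdname estimator_bias
#' @export
estimator_mse <- function(estimates, truth) {
  if (length(estimates) == 0) stop("no estimates")
  mean((estimates - truth)^2)
}

#' @rdname estimator_bias
#' @param sortseq_estimates,reference_estimates matched vectors of binned
#'   and full-resolution estimates (same truth, same sample size).
#' @export
estimator_efficiency <- function(sortseq_estimates, reference_estimates,
                                 truth) {
  denom <- estimator_mse(sortseq_estimates, truth)
  if (denom == 0) stop("sort-seq MSE is zero: efficiency undefined")
  estimator_mse(reference_estimates, truth) / denom
}

#' Benchmark estimator bias and efficiency over a parameter grid
#'
#' For every \eqn{(\nu, \sigma)} cell of the grid, simulates
#' \code{n_repeats} sort-seq experiments of \code{n_cells} cells each,
#' applies the chosen estimator, and records bias, relative bias, MSE and
#' efficiency for the mean and the CV. The reference estimator consumes
#' the \emph{same} raw fluorescence draws that were binned, so efficiency
#' is a paired comparison (this substantially reduces Monte Carlo noise in
#' \eqn{\eta}).
#'
#' For bounded configurations, simple estimators only see the sorted
#' cells; repeats in which no cell lands in any gate are recorded as
#' \code{NA} and dropped from the summaries.
#'
#' @param estimator \code{"simple"} or \code{"mle"}.
#' @param gates a \code{gate_config} (simple estimators require bounded
#'   gates).
#' @param nu_grid,sigma_grid vectors of true linear means and log-widths.
#' @param n_cells cells drawn per repeat (default 100).
#' @param n_repeats simulation repeats per grid cell (default 1000).
#' @return A data frame with one row per (nu, sigma) cell and columns
#'   \code{estimator, nu, sigma, cv}, then for the mean and the CV:
#'   bias, relative bias, MSE, and efficiency
#'   (\code{*_mean}, \code{*_cv}), plus \code{n_repeats} and
#'   \code{n_failed}.
#' @export
run_benchmark <- function(estimator = c("simple", "mle"), gates, nu_grid,
                          sigma_grid, n_cells = 100, n_repeats = 1000) {
  estimator <- match.arg(estimator)
  if (estimator == "simple" &&
      (gates$semibounded_low || gates$semibounded_high)) {
    stop("simple estimators require bounded gates")
  }
  grid <- expand.grid(nu = nu_grid, sigma = sigma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    nu <- grid$nu[k]
    sigma <- grid$sigma[k]
    mu <- log(nu) - sigma^2 / 2
    cv_true <- sqrt(exp(sigma^2) - 1)
    est_nu <- est_cv <- ref_nu <- ref_cv <- rep(NA_real_, n_repeats)
    for (rep_i in seq_len(n_repeats)) {
      out <- sample_output(mu, sigma, gates, n_cells, keep_values = TRUE)
      x <- attr(out, "values")
      ref <- reference_estimate(x)
      ref_nu[rep_i] <- ref$nu_hat
      ref_cv[rep_i] <- ref$c_hat
      if (out$n_sorted == 0) next
      if (estimator == "simple") {
        est_nu[rep_i] <- simple_mean(out, gates)
        est_cv[rep_i] <- simple_cv(out, gates)
      } else {
        fit <- mle_fit(out, gates)
        est_nu[rep_i] <- fit$nu_hat
        est_cv[rep_i] <- fit$c_hat
      }
    }
    ok <- !is.na(est_nu)
    bm <- estimator_bias(est_nu[ok], nu)
    bc <- estimator_bias(est_cv[ok], cv_true)
    rows[[k]] <- data.frame(
      estimator = estimator, nu = nu, sigma = sigma, cv = cv_true,
      bias_mean = bm$bias, relative_bias_mean = bm$relative_bias,
      mse_mean = estimator_mse(est_nu[ok], nu),
      efficiency_mean = estimator_efficiency(est_nu[ok], ref_nu[ok], nu),
      bias_cv = bc$bias, relative_bias_cv = bc$relative_bias,
      mse_cv = estimator_mse(est_cv[ok], cv_true),
      efficiency_cv = estimator_efficiency(est_cv[ok], ref_cv[ok], cv_true),
      n_repeats = n_repeats, n_failed = sum(!ok),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
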