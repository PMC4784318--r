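#' Representative fluorescence of each gate
#'
#' The simple estimators place every cell sorted into gate \eqn{j} at the
#' fixed fluorescence \eqn{\varphi_j = b\sqrt{L_j U_j}}, the geometric
#' gate center scaled by \eqn{b = w / (e^{w/2} - e^{-w/2})}, a constant
#' that minimizes the estimator's bias over inputs well inside the
#' measurement range (\eqn{b \to 1} as \eqn{w \to 0}).
#'
#' @param gates a bounded \code{gate_config}.
#' @return Numeric vector \eqn{\varphi_j} of length \code{gates$m}.
#' @export
gate_centers <- function(gates) {
  stopifnot(inherits(gates, "gate_config"))
  if (gates$semibounded_low || gates$semibounded_high) {
    stop("gate centers are undefined for semibounded (censoring) gates")
  }
  w <- gates$w
  b <- w / (exp(w / 2) - exp(-w / 2))
  b * sqrt(gates$lower * gates$upper)
}

#' Simple (moment) estimators of mean and CV from binned counts
#'
#' \code{simple_mean} is the population average over sorted cells with each
#' cell placed at its gate center \eqn{\varphi_j} (see [gate_centers()]):
#' \eqn{\hat\nu_1 = \sum_j r_j \varphi_j / \sum_j r_j}. \code{simple_cv}
#' is the matching weighted standard deviation divided by
#' \eqn{\hat\nu_1}. Both silently ignore cells outside the measurement
#' range — those cells are never observed in a real sorter — which is the
#' source of the boundary bias these estimators exhibit.
#'
#' @param counts an \code{output_counts} object, or a bare numeric vector
#'   of per-gate counts/fractions.
#' @param gates a bounded \code{gate_config}.
#' @return \code{simple_mean}: the estimated mean \eqn{\hat\nu_1};
#'   \code{simple_cv}: the estimated CV \eqn{\hat c_1}.
#' @export
simple_mean <- function(counts, gates) {
  r <- gate_count_vector(counts, gates)
  if (sum(r) <= 0) stop("no sorted cells: simple mean undefined")
  phi <- gate_centers(gates)
  sum(r * phi) / sum(r)
}

#' @rdname simple_mean
#' @export
simple_cv <- function(counts, gates) {
  r <- gate_count_vector(counts, gates)
  if (sum(r) <= 0) stop("no sorted cells: simple CV undefined")
  phi <- gate_centers(gates)
  nu1 <- sum(r * phi) / sum(r)
  sqrt(sum(r * (phi - nu1)^2) / sum(r)) / nu1
}

gate_count_vector <- function(counts, gates) {
  r <- if (inherits(counts, "output_counts")) counts$counts else counts
  if (length(r) != gates$m) stop("counts length does not match gate count")
  if (any(r < 0)) stop("negative counts")
  r
}

#' Container for a mean/CV estimate
#'
#' @param method estimator tag (\code{"simple"}, \code{"mle"},
#'   \code{"robust_mle"}, \code{"reference"}).
#' @param mu_hat,sigma_hat log-scale parameters (NA for simple estimators).
#' @param nu_hat,c_hat linear-scale mean and CV.
#' @param converged logical convergence flag (optimizer methods).
#' @param loglik final log-likelihood (optimizer methods).
#' @return Object of class \code{estimate_record} (a one-row-style list).
#' @export
estimate_record <- function(method, nu_hat, c_hat, mu_hat = NA_real_,
                            sigma_hat = NA_real_, converged = NA,
                            loglik = NA_real_) {
  structure(
    list(method = method, nu_hat = nu_hat, c_hat = c_hat, mu_hat = mu_hat,
         sigma_hat = sigma_hat, converged = converged, loglik = loglik),
    class = "estimate_record"
  )
}

#' @export
print.estimate_record <- function(x, ...) {
  cat(sprintf("<estimate_record:%s> nu_hat = %.5g, c_hat = %.5g", x$method,
              x$nu_hat, x$c_hat))
  if (!is.na(x$mu_hat)) {
    cat(sprintf(" (mu = %.5g, sigma = %.5g, converged = %s)",
                x$mu_hat, x$sigma_hat, x$converged))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.estimate_record <- function(x, ...) {
  data.frame(method = x$method, nu_hat = x$nu_hat, c_hat = x$c_hat,
             mu_hat = x$mu_hat, sigma_hat = x$sigma_hat,
             converged = x$converged, loglik = x$loglik,
             stringsAsFactors = FALSE)
}

# Shared Nelder-Mead driver on (mu, log sigma). `negll` takes (mu, sigma).
# Log-parameterizing sigma keeps it positive without box constraints.
run_mle_optim <- function(negll, init, reltol = 1e-8, maxit = 1e4) {
  obj <- function(par) negll(par[1], exp(par[2]))
  fit <- stats::optim(c(init[1], log(init[2])), obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  # one restart from the optimum tightens the simplex considerably
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(reltol = reltol, maxit = maxit))
  if (fit2$value <= fit$value) fit <- fit2
  list(mu = fit$par[1], sigma = exp(fit$par[2]), value = fit$value,
       converged = fit$convergence == 0)
}

mle_default_init <- function(r, gates) {
  # simple-estimator initialization where defined; fall back to
  # geometric gate midpoints for censoring configurations
  w <- if (is.finite(gates$w)) gates$w else
    stats::median(diff(log(gates$lower[gates$lower > 0])))
  ctr <- sqrt(pmax(gates$lower, gates$range[1] * exp(-w)) *
                pmin(gates$upper, gates$range[2] * exp(w)))
  l <- log(ctr)
  mu0 <- sum(r * l) / sum(r)
  s0 <- sqrt(sum(r * (l - mu0)^2) / sum(r))
  c(mu0, max(s0, w / 4, 1e-3))
}

#' Maximum-likelihood estimate of mean and CV from binned counts
#'
#' Maximizes the multinomial log-likelihood of the observed gate counts,
#' \deqn{\log L(\mu, \sigma \mid r) = \sum_j r_j \log\left(
#'   F_{\mu,\sigma}(U_j) - F_{\mu,\sigma}(L_j)\right),}
#' over \eqn{(\mu, \sigma)} by Nelder-Mead simplex search, then converts to
#' the linear scale: \eqn{\hat\nu_2 = \exp(\hat\mu + \hat\sigma^2/2)},
#' \eqn{\hat c_2 = \sqrt{\exp(\hat\sigma^2) - 1}}. Semibounded gates enter
#' as censored terms \eqn{F(U_1) - 0} and \eqn{1 - F(L_m)}, which is what
#' removes the boundary bias of the simple estimators. Zero-count gates
#' contribute 0 (the \eqn{0 \log p := 0} convention).
#'
#' The likelihood depends on \code{r} only through its proportions (up to
#' an additive constant), so counts and read fractions give identical
#' fits.
#'
#' @param counts \code{output_counts} or a numeric vector of counts or
#'   fractions.
#' @param gates a \code{gate_config}.
#' @param init optional \code{c(mu0, sigma0)} starting point; defaults to
#'   a moment-based heuristic from the occupied gates.
#' @return An [estimate_record()] with \code{method = "mle"}. Degenerate
#'   inputs (all mass in a single bounded gate) return
#'   \code{converged = FALSE}.
#' @export
mle_fit <- function(counts, gates, init = NULL) {
  r <- gate_count_vector(counts, gates)
  if (sum(r) <= 0) stop("no sorted cells: MLE undefined")
  occupied <- sum(r > 0)
  negll <- function(mu, sigma) {
    p <- gate_probabilities(gates, mu, sigma)
    nz <- r > 0
    if (any(p[nz] <= 0)) return(1e12)
    -sum(r[nz] * log(p[nz]))
  }
  if (is.null(init)) init <- mle_default_init(r, gates)
  fit <- run_mle_optim(negll, init)
  degenerate <- occupied < 2 &&
    !(gates$semibounded_low || gates$semibounded_high)
  mom <- params_to_moments(fit$mu, fit$sigma)
  estimate_record("mle", nu_hat = unname(mom["nu"]), c_hat = unname(mom["cv"]),
                  mu_hat = fit$mu, sigma_hat = fit$sigma,
                  converged = fit$converged && !degenerate,
                  loglik = -fit$value)
}

#' Gate fractions predicted by an outlier-robust fit
#'
#' Under the contamination model used by [robust_mle_fit()], a fraction
#' \eqn{\gamma} of each variant's cells are mis-sorted or mis-identified
#' and land in gates in proportion to the overall per-gate sorted
#' fractions \eqn{T_j}. The predicted fraction of the variant's reads in
#' gate \eqn{j} is then
#' \deqn{\lambda_j = (1 - \gamma)\left(F_{\mu,\sigma}(U_j) -
#'   F_{\mu,\sigma}(L_j)\right) + \gamma T_j.}
#'
#' @param mu,sigma log-normal input parameters.
#' @param gates a \code{gate_config}; evaluated with the first and last
#'   gates treated as censoring gates (lower sentinel 0, upper
#'   \code{Inf}), matching the robust-likelihood convention.
#' @param T per-gate sorted fractions (sums to 1).
#' @param gamma outlier fraction in [0, 1).
#' @return Numeric vector \eqn{\lambda} of length \code{gates$m}.
#' @export
predicted_fractions <- function(mu, sigma, gates, T, gamma = 0.05) {
  if (gamma < 0 || gamma >= 1) stop("`gamma` must be in [0, 1)")
  stopifnot(length(T) == gates$m)
  p <- gate_probabilities(censored_gates(gates), mu, sigma)
  (1 - gamma) * p + gamma * T
}

# Treat the extreme gates as censoring gates regardless of their recorded
# boundaries (the sorter collects everything beyond them).
censored_gates <- function(gates) {
  g <- gates
  g$lower[1] <- 0
  g$upper[g$m] <- Inf
  g$semibounded_low <- TRUE
  g$semibounded_high <- TRUE
  g
}

#' Outlier-robust censored MLE from per-variant gate fractions
#'
#' Fits \eqn{(\mu, \sigma)} by maximizing
#' \eqn{\sum_j t_j \log \lambda_j(\mu, \sigma)} with
#' \eqn{\lambda} from [predicted_fractions()]: a fraction \code{gamma}
#' (default 5\%) of cells is attributed to sorting/sequencing errors
#' distributed like the global gate occupancy \eqn{T_j}, and the extreme
#' gates are treated as censoring gates. With \code{gamma = 0} this
#' reduces exactly to [mle_fit()] on the censored configuration.
#'
#' @param t per-variant gate fractions (sums to 1).
#' @param gates a \code{gate_config}.
#' @param T per-gate sorted fractions.
#' @param gamma assumed outlier fraction.
#' @param init optional starting point \code{c(mu0, sigma0)}.
#' @return An [estimate_record()] with \code{method = "robust_mle"}.
#' @export
robust_mle_fit <- function(t, gates, T, gamma = 0.05, init = NULL) {
  stopifnot(length(t) == gates$m, length(T) == gates$m)
  if (sum(t) <= 0) stop("empty fraction vector")
  negll <- function(mu, sigma) {
    lam <- predicted_fractions(mu, sigma, gates, T, gamma)
    nz <- t > 0
    if (any(lam[nz] <= 0)) return(1e12)
    -sum(t[nz] * log(lam[nz]))
  }
  if (is.null(init)) init <- mle_default_init(t, gates)
  fit <- run_mle_optim(negll, init)
  mom <- params_to_moments(fit$mu, fit$sigma)
  estimate_record("robust_mle", nu_hat = unname(mom["nu"]),
                  c_hat = unname(mom["cv"]), mu_hat = fit$mu,
                  sigma_hat = fit$sigma, converged = fit$converged,
                  loglik = -fit$value)
}

#' Kullback-Leibler divergence between observed and fitted gate fractions
#'
#' \eqn{D_{KL}(t \| \lambda) = \sum_j t_j \log_2(t_j / \lambda_j)} in
#' bits; gates with \eqn{t_j = 0} contribute 0. Used as the
#' goodness-of-fit statistic of the QC filter.
#'
#' @param t observed fractions (sum to 1).
#' @param lam model-predicted fractions (sum to 1).
#' @return Divergence in bits (nonnegative).
#' @export
kl_divergence_bits <- function(t, lam) {
  stopifnot(length(t) == length(lam))
  nz <- t > 0
  if (any(lam[nz] <= 0)) {
    stop("predicted fraction is 0 where observed fraction is positive")
  }
  sum(t[nz] * log2(t[nz] / lam[nz]))
}

#' Default quality-control thresholds for sort-seq variants
#'
#' @param reads_min minimum sort-seq reads per variant.
#' @param single_gate_max maximum fraction of cells in any single gate.
#' @param two_gate_max maximum fraction in the top two gates (by count;
#'   adjacency not required).
#' @param censor_max maximum fraction in either censoring (extreme) gate.
#' @param dkl_max_bits maximum KL divergence between observed and fitted
#'   fractions.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(reads_min = 300, single_gate_max = 0.60,
                          two_gate_max = 0.90, censor_max = 0.40,
                          dkl_max_bits = 0.4) {
  list(reads_min = reads_min, single_gate_max = single_gate_max,
       two_gate_max = two_gate_max, censor_max = censor_max,
       dkl_max_bits = dkl_max_bits)
}

#' Quality-control filter for fitted sort-seq variants
#'
#' Applies, in order: (i) a read-depth floor; (ii) concentration rules —
#' more than \code{single_gate_max} of cells in one gate, more than
#' \code{two_gate_max} in the top two gates, or more than
#' \code{censor_max} in either censoring gate; (iii) a goodness-of-fit
#' ceiling on \eqn{D_{KL}(t \| \lambda)}. The first failing rule is
#' reported.
#'
#' @param t per-variant gate fractions.
#' @param reads total sort-seq reads for the variant.
#' @param lam fitted fractions from [predicted_fractions()] (needed for
#'   rule iii; may be \code{NULL} to skip it).
#' @param thresholds a [qc_thresholds()] list.
#' @return List with logical \code{keep} and character \code{reason}
#'   (\code{"pass"}, \code{"reads"}, \code{"concentration"}, or
#'   \code{"fit"}).
#' @export
qc_filter <- function(t, reads, lam = NULL, thresholds = qc_thresholds()) {
  th <- thresholds
  if (reads < th$reads_min) {
    return(list(keep = FALSE, reason = "reads"))
  }
  top2 <- sum(sort(t, decreasing = TRUE)[1:2])
  if (max(t) > th$single_gate_max || top2 > th$two_gate_max ||
      t[1] > th$censor_max || t[length(t)] > th$censor_max) {
    return(list(keep = FALSE, reason = "concentration"))
  }
  if (!is.null(lam) && kl_divergence_bits(t, lam) > th$dkl_max_bits) {
    return(list(keep = FALSE, reason = "fit"))
  }
  list(keep = TRUE, reason = "pass")
}

#' Full-resolution reference estimator
#'
#' The MLE of \eqn{(\mu, \sigma)} from \eqn{N} exact fluorescence
#' measurements: \eqn{\hat\mu_0} is the mean of the log values and
#' \eqn{\hat\sigma_0^2} their population (divide-by-N) variance. This is
#' the yardstick against which binned sort-seq estimators are measured —
#' an estimator with efficiency 1 extracts as much information from the
#' gate counts as this estimator does from the raw values.
#'
#' @param samples positive raw fluorescence values.
#' @return An [estimate_record()] with \code{method = "reference"}.
#' @export
reference_estimate <- function(samples) {
  if (length(samples) == 0) stop("empty sample")
  if (any(samples <= 0)) stop("fluorescence samples must be positive")
  l <- log(samples)
  mu0 <- mean(l)
  s0 <- sqrt(mean((l - mu0)^2))
  estimate_record("reference",
                  nu_hat = exp(mu0 + s0^2 / 2),
                  c_hat = sqrt(exp(s0^2) - 1),
                  mu_hat = mu0, sigma_hat = s0, converged = TRUE)
}
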