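#' Log-normal cumulative distribution function for fluorescence
#'
#' Single-cell fluorescence of a clonal variant is modeled as log-normal:
#' \deqn{F_{\mu,\sigma}(x) = \frac{1}{2}\left(1 +
#'   \mathrm{erf}\left(\frac{\log x - \mu}{\sigma\sqrt{2}}\right)\right),}
#' where \eqn{\mu} is the log-scale location and \eqn{\sigma} the log-scale
#' width of the distribution. The support is \eqn{x \ge 0}; \code{x = 0}
#' maps to probability 0 and \code{x = Inf} to 1, so semibounded sorting
#' gates can be evaluated exactly.
#'
#' @param x fluorescence value(s), nonnegative (0 and \code{Inf} allowed).
#' @param mu log-scale location parameter.
#' @param sigma log-scale width parameter, must be > 0.
#' @return Probability \eqn{P(X < x)}, vectorized over all three
#'   arguments with the usual recycling.
#' @examples
#' lognormal_cdf(exp(0.5), mu = 0.5, sigma = 1) # median -> 0.5
#' @export
lognormal_cdf <- function(x, mu, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) {
    stop("`sigma` must be positive: a log-normal with sigma <= 0 is invalid")
  }
  if (any(x < 0, na.rm = TRUE)) stop("fluorescence `x` must be nonnegative")
  n <- max(length(x), length(mu), length(sigma))
  x <- rep_len(x, n)
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  p <- numeric(n)
  pos <- is.finite(x) & x > 0
  p[pos] <- stats::pnorm((log(x[pos]) - mu[pos]) / sigma[pos])
  p[is.infinite(x)] <- 1
  p
}

#' Convert linear-scale moments to log-normal parameters
#'
#' The linear-scale mean \eqn{\nu} and coefficient of variation \eqn{c} of a
#' log-normal distribution determine its log-scale parameters through
#' \eqn{\sigma = \sqrt{\log(1 + c^2)}} and \eqn{\mu = \log\nu - \sigma^2/2}.
#' For small widths \eqn{c \approx \sigma}.
#'
#' @param nu linear-scale mean fluorescence, > 0.
#' @param c coefficient of variation (sd / mean), > 0.
#' @return Named numeric vector with elements \code{mu} and \code{sigma}.
#' @seealso [params_to_moments()] for the inverse map.
#' @export
moments_to_params <- function(nu, c) {
  if (any(nu <= 0) || any(c <= 0)) stop("`nu` and `c` must be positive")
  nu <- unname(nu)
  sigma <- sqrt(log(1 + unname(c)^2))
  c(mu = log(nu) - sigma^2 / 2, sigma = sigma)
}

#' Convert log-normal parameters to linear-scale moments
#'
#' Inverse of [moments_to_params()]: \eqn{\nu = \exp(\mu + \sigma^2/2)} and
#' \eqn{c = \sqrt{\exp(\sigma^2) - 1}}.
#'
#' @param mu log-scale location.
#' @param sigma log-scale width, > 0.
#' @return Named numeric vector with elements \code{nu} and \code{cv}.
#' @export
params_to_moments <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  mu <- unname(mu)
  sigma <- unname(sigma)
  c(nu = exp(mu + sigma^2 / 2), cv = sqrt(exp(sigma^2) - 1))
}

#' Construct log-spaced sorting gates
#'
#' Builds \code{m} contiguous sorting gates evenly spaced on a logarithmic
#' scale across the measurement range \eqn{[\ell, u]}, each of log-width
#' \eqn{w = \log(u/\ell)/m}, so that \eqn{\log U_j = \log L_j + w}.
#' If \code{semibounded = TRUE} the outermost gates are censoring gates: the
#' first gate's lower boundary is 0 and the last gate's upper boundary is
#' \code{Inf}, while the interior boundaries remain log-spaced over
#' \eqn{[\ell, u]}. Gate intervals are half-open \eqn{[L_j, U_j)} so every
#' fluorescence value belongs to at most one gate.
#'
#' @param m number of gates (integer >= 1).
#' @param lower_bound lower end \eqn{\ell} of the finite measurement range.
#' @param upper_bound upper end \eqn{u}; must satisfy \eqn{u > \ell > 0}.
#' @param semibounded if \code{TRUE}, extend the outermost gates to 0 and
#'   \code{Inf} so the gates partition the whole log-normal support.
#' @return An object of class \code{gate_config}: a list with integer
#'   \code{m}, numeric vectors \code{lower} and \code{upper} of length
#'   \code{m}, the per-gate log-width \code{w}, the finite range
#'   \code{range = c(lower_bound, upper_bound)}, and logicals
#'   \code{semibounded_low} / \code{semibounded_high}.
#' @examples
#' g <- make_log_gates(6, 1, exp(4.8))   # six gates, w = 0.8
#' g$w
#' @export
make_log_gates <- function(m, lower_bound, upper_bound, semibounded = FALSE) {
  if (m < 1 || m != round(m)) stop("`m` must be a positive integer")
  if (!(lower_bound > 0 && upper_bound > lower_bound)) {
    stop("need 0 < lower_bound < upper_bound")
  }
  edges <- exp(seq(log(lower_bound), log(upper_bound), length.out = m + 1))
  w <- log(upper_bound / lower_bound) / m
  lower <- edges[-(m + 1)]
  upper <- edges[-1]
  if (semibounded) {
    lower[1] <- 0
    upper[m] <- Inf
  }
  structure(
    list(
      m = as.integer(m), lower = lower, upper = upper, w = w,
      range = c(lower_bound, upper_bound),
      semibounded_low = isTRUE(semibounded),
      semibounded_high = isTRUE(semibounded)
    ),
    class = "gate_config"
  )
}

#' Construct a gate configuration from explicit boundaries
#'
#' Lower-level constructor used by the table readers and by
#' [regroup_gates()]: takes ordered, contiguous boundary vectors as they
#' appear in published gate tables (possibly with 0 / \code{Inf} sentinels
#' for censoring gates).
#'
#' @param lower,upper boundary vectors of equal length; must satisfy
#'   \code{lower[j + 1] == upper[j]} and be strictly increasing.
#' @return A \code{gate_config} object. \code{w} is the common log-width of
#'   the interior (finite) gates, or \code{NA} if they are not log-uniform.
#' @export
gate_config <- function(lower, upper) {
  m <- length(lower)
  if (length(upper) != m || m < 1) stop("`lower` and `upper` lengths differ")
  if (any(upper <= lower)) stop("gate boundaries must be strictly increasing")
  if (m > 1 && any(abs(lower[-1] - upper[-m]) >
                   1e-9 * pmax(1, abs(upper[-m])))) {
    stop("gates must be contiguous: lower[j + 1] must equal upper[j]")
  }
  finite <- is.finite(log(lower)) & is.finite(log(upper))
  widths <- log(upper[finite]) - log(lower[finite])
  w <- if (length(widths) && diff(range(widths)) < 1e-6 * max(widths)) {
    mean(widths)
  } else {
    NA_real_
  }
  lo <- if (lower[1] > 0) lower[1] else upper[1]
  hi <- if (is.finite(upper[m])) upper[m] else lower[m]
  structure(
    list(
      m = as.integer(m), lower = lower, upper = upper, w = w,
      range = c(lo, hi),
      semibounded_low = lower[1] == 0,
      semibounded_high = is.infinite(upper[m])
    ),
    class = "gate_config"
  )
}

#' @export
print.gate_config <- function(x, ...) {
  kind <- if (x$semibounded_low || x$semibounded_high) "semibounded" else "bounded"
  cat(sprintf("<gate_config> %d %s gates, w = %.4g, range [%.4g, %.4g]\n",
              x$m, kind, x$w, x$range[1], x$range[2]))
  invisible(x)
}

#' Per-gate occupancy probabilities of a log-normal input
#'
#' The probability that a cell with input distribution \eqn{(\mu, \sigma)}
#' falls into gate \eqn{j} is \eqn{p_j = F_{\mu,\sigma}(U_j) -
#' F_{\mu,\sigma}(L_j)}. Censoring gates use the exact limits
#' \eqn{F(0) = 0} and \eqn{F(\infty) = 1}, so for semibounded
#' configurations the probabilities sum to exactly 1; for bounded
#' configurations the deficit is the probability of falling outside the
#' measurement range.
#'
#' @param gates a \code{gate_config}.
#' @param mu,sigma log-normal input parameters.
#' @return Numeric vector of length \code{gates$m}.
#' @export
gate_probabilities <- function(gates, mu, sigma) {
  stopifnot(inherits(gates, "gate_config"))
  lognormal_cdf(gates$upper, mu, sigma) - lognormal_cdf(gates$lower, mu, sigma)
}

#' Expected enrichment above a fluorescence threshold
#'
#' For a single-gate (threshold) sorting design, the expected fraction of a
#' variant's cells collected above the threshold \eqn{\tau} is
#' \eqn{\varepsilon = 1 - F_{\mu,\sigma}(\tau)}. As a function of \eqn{\mu}
#' this is a sigmoid whose dynamic range widens with \eqn{\sigma}: noisier
#' variants respond to the selection over a wider range of mean expression.
#'
#' @param mu,sigma log-normal input parameters.
#' @param threshold gate threshold \eqn{\tau > 0}.
#' @return Probability that a cell exceeds the threshold.
#' @export
expected_enrichment <- function(mu, sigma, threshold) {
  if (any(threshold <= 0)) stop("`threshold` must be positive")
  1 - lognormal_cdf(threshold, mu, sigma)
}

#' Write / read a gate configuration as a TSV table
#'
#' One row per gate with columns \code{gate}, \code{lower}, \code{upper},
#' and optionally extra per-gate columns (e.g. the sorted fraction
#' \code{T} or sorted-cell totals \code{h}). Infinite/zero sentinels are
#' preserved. These files are the sidecar format used by the gate-fraction
#' and read-count table readers.
#'
#' @param gates a \code{gate_config}.
#' @param path file path.
#' @param extra optional data frame of per-gate columns to append.
#' @return \code{write_gate_config} returns \code{path} invisibly;
#'   \code{read_gate_config} returns a list with elements \code{gates} (a
#'   \code{gate_config}) and \code{extra} (data frame of any additional
#'   columns, possibly empty).
#' @export
write_gate_config <- function(gates, path, extra = NULL) {
  df <- data.frame(gate = seq_len(gates$m), lower = gates$lower,
                   upper = gates$upper)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gate_config
#' @export
read_gate_config <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("lower", "upper") %in% names(df))) {
    stop("gate file must have `lower` and `upper` columns")
  }
  extra <- df[, setdiff(names(df), c("gate", "lower", "upper")), drop = FALSE]
  list(gates = gate_config(df$lower, df$upper), extra = extra)
}
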