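#' Simulate the output distribution of one variant
#'
#' Draws \code{n_cells} single-cell fluorescence values from the variant's
#' log-normal input distribution by inverse-CDF sampling
#' (\eqn{X = F^{-1}_{\mu,\sigma}(y)} for uniform \eqn{y}) and assigns each
#' cell to the sorting gate with \eqn{L_j \le X < U_j}. In bounded
#' configurations, cells falling outside the measurement range are drawn
#' but never sorted; they are counted in \code{n_drawn} only. This is what
#' produces the boundary bias of estimators that ignore censoring.
#'
#' Randomness comes from the session RNG; call \code{set.seed()} for
#' reproducible counts.
#'
#' @param mu,sigma log-normal input parameters (see [moments_to_params()]
#'   to convert from mean/CV).
#' @param gates a \code{gate_config}.
#' @param n_cells number of cells drawn for this variant.
#' @param keep_values if \code{TRUE}, attach the raw fluorescence draws as
#'   attribute \code{"values"} (used for paired comparisons against the
#'   full-resolution reference estimator).
#' @return An object of class \code{output_counts}: list with integer
#'   vector \code{counts} (length \code{gates$m}), \code{n_drawn}, and
#'   \code{n_sorted = sum(counts)}.
#' @export
sample_output <- function(mu, sigma, gates, n_cells, keep_values = FALSE) {
  stopifnot(inherits(gates, "gate_config"), n_cells >= 0)
  x <- exp(mu + sigma * stats::qnorm(stats::runif(n_cells)))
  out <- bin_cells(x, gates)
  if (keep_values) attr(out, "values") <- x
  out
}

#' Bin raw fluorescence values into sorting gates
#'
#' @param x positive fluorescence values.
#' @param gates a \code{gate_config}.
#' @return An \code{output_counts} object (see [sample_output()]).
#' @export
bin_cells <- function(x, gates) {
  # half-open gates [L_j, U_j): findInterval on the full boundary grid
  edges <- c(gates$lower, gates$upper[gates$m])
  idx <- findInterval(x, edges, left.open = FALSE)
  idx[idx < 1 | idx > gates$m] <- NA_integer_
  counts <- tabulate(idx, nbins = gates$m)
  structure(
    list(counts = counts, n_drawn = length(x), n_sorted = sum(counts)),
    class = "output_counts"
  )
}

#' @export
print.output_counts <- function(x, ...) {
  cat(sprintf("<output_counts> %d/%d cells sorted over %d gates\n",
              x$n_sorted, x$n_drawn, length(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Dual-reporter noise model
#'
#' Per-cell fluorescence of reporter FP is modeled as the product of two
#' independent log-normal factors, \eqn{X^{(FP)} = W \cdot Z^{(FP)}}: a
#' shared (extrinsic) factor \eqn{W} with parameters
#' \eqn{(\mu_W, \sigma_W)} common to all reporters, and a reporter-specific
#' (intrinsic) factor \eqn{Z^{(FP)}} with parameters
#' \eqn{(\mu'_{FP}, \sigma'_{FP})}. The observable channels are then also
#' log-normal:
#' \itemize{
#'   \item single channel: \eqn{\mu_{FP} = \mu'_{FP} + \mu_W},
#'     \eqn{\sigma_{FP} = \sqrt{\sigma'^2_{FP} + \sigma_W^2}};
#'   \item ratio channel FP1/FP2: \eqn{\mu = \mu'_{FP1} - \mu'_{FP2}},
#'     \eqn{\sigma = \sqrt{\sigma'^2_{FP1} + \sigma'^2_{FP2}}} — the shared
#'     factor cancels exactly.
#' }
#' Normalizing by a reference reporter therefore pays off whenever the
#' shared noise exceeds the reference reporter's intrinsic noise
#' (\eqn{\sigma_W > \sigma'_{ref}}).
#'
#' The location parameters \eqn{\mu_W} and the reference reporter's
#' \eqn{\mu'} only rescale all measurements and default to 0.
#'
#' @param sigma_W shared log-width (default 0.40).
#' @param mu_W shared log-location (default 0).
#' @param reporters named list; each element is a numeric vector
#'   \code{c(mu_prime, sigma_prime)} for one reporter.
#' @return Object of class \code{dual_reporter_model}.
#' @examples
#' m <- dual_reporter_model(reporters = list(
#'   GFP = c(0, 0.2), RFP = c(0, 0.15)))
#' derive_reporter_channels(m, c("GFP", "RFP"))  # ratio channel
#' @export
dual_reporter_model <- function(sigma_W = 0.40, mu_W = 0, reporters = list()) {
  stopifnot(sigma_W >= 0, is.list(reporters))
  structure(list(sigma_W = sigma_W, mu_W = mu_W, reporters = reporters),
            class = "dual_reporter_model")
}

#' Composite channel parameters of a dual-reporter model
#'
#' @param model a [dual_reporter_model()].
#' @param reporter a single reporter name for a direct channel, or a
#'   character vector of two names \code{c(num, den)} for the ratio
#'   channel num/den.
#' @return Named numeric vector \code{c(mu, sigma)} of the (log-normal)
#'   channel.
#' @export
derive_reporter_channels <- function(model, reporter) {
  stopifnot(inherits(model, "dual_reporter_model"))
  get_rep <- function(nm) {
    r <- model$reporters[[nm]]
    if (is.null(r)) stop(sprintf("unknown reporter '%s'", nm))
    r
  }
  if (length(reporter) == 1) {
    r <- get_rep(reporter)
    c(mu = r[[1]] + model$mu_W, sigma = sqrt(r[[2]]^2 + model$sigma_W^2))
  } else if (length(reporter) == 2) {
    a <- get_rep(reporter[1]); b <- get_rep(reporter[2])
    c(mu = a[[1]] - b[[1]], sigma = sqrt(a[[2]]^2 + b[[2]]^2))
  } else {
    stop("`reporter` must be one name or a pair of names")
  }
}

#' Intrinsic reporter parameters for a target mean
#'
#' Parameterizes the reporter-specific factor \eqn{Z} so that it has mean
#' \eqn{\nu} and CV \eqn{\nu^{-1/2}} (Poisson-like scaling of intrinsic
#' noise with expression): \eqn{\sigma' = \sqrt{\log(1 + \nu^{-1})}} and
#' \eqn{\mu' = \log(\nu / \sqrt{1 + \nu^{-1}})}.
#'
#' @param nu target mean of the intrinsic factor, > 0.
#' @return Named numeric vector \code{c(mu_prime, sigma_prime)}.
#' @export
gfp_intrinsic_params <- function(nu) {
  if (any(nu <= 0)) stop("`nu` must be positive")
  c(mu_prime = log(nu / sqrt(1 + 1 / nu)),
    sigma_prime = sqrt(log(1 + 1 / nu)))
}

#' Simulate a dual-reporter sort-seq experiment
#'
#' For each variant mean \eqn{\nu}, builds the GFP intrinsic factor with
#' [gfp_intrinsic_params()], composes the single-channel (GFP) and
#' ratio-channel (GFP/RFP) log-normal parameters from \code{model}, and
#' samples both channels with the same per-variant cell budget. Defaults
#' follow a cautious design: shared noise \eqn{\sigma_W = 0.40}, reference
#' reporter intrinsic noise \eqn{\sigma'_{RFP} = 0.15}.
#'
#' @param variant_means vector of per-variant means \eqn{\nu}.
#' @param cells_per_variant integer vector (recycled) of cells drawn per
#'   variant.
#' @param gates a \code{gate_config}; the same gates serve both channels
#'   (with \eqn{\mu_W = \mu'_{RFP} = 0} the two channels share the same
#'   location scale).
#' @param model a [dual_reporter_model()]; GFP entries are overwritten per
#'   variant from \code{variant_means}.
#' @return List with elements \code{gfp} and \code{ratio}, each a list of
#'   \code{output_counts} (one per variant), plus the per-variant channel
#'   parameter matrices \code{params_gfp}, \code{params_ratio}.
#' @export
simulate_dual_reporter_experiment <- function(variant_means, cells_per_variant,
                                              gates,
                                              model = dual_reporter_model(
                                                sigma_W = 0.40,
                                                reporters = list(RFP = c(0, 0.15)))) {
  nv <- length(variant_means)
  cells <- rep_len(cells_per_variant, nv)
  pg <- matrix(NA_real_, nv, 2, dimnames = list(NULL, c("mu", "sigma")))
  pr <- pg
  gfp <- vector("list", nv)
  ratio <- vector("list", nv)
  for (i in seq_len(nv)) {
    zi <- gfp_intrinsic_params(variant_means[i])
    m_i <- model
    m_i$reporters$GFP <- unname(zi)
    pg[i, ] <- derive_reporter_channels(m_i, "GFP")
    pr[i, ] <- derive_reporter_channels(m_i, c("GFP", "RFP"))
    gfp[[i]] <- sample_output(pg[i, 1], pg[i, 2], gates, cells[i])
    ratio[[i]] <- sample_output(pr[i, 1], pr[i, 2], gates, cells[i])
  }
  list(gfp = gfp, ratio = ratio, params_gfp = pg, params_ratio = pr)
}
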