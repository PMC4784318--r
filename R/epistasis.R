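#' Predicted double-mutant fold-change under the additive null
#'
#' From fold-change measurements of the wild type and of two single
#' mutants \eqn{\alpha} and \eqn{\beta}, the additive (two-state) model
#' predicts the double-mutant fold-change
#' \deqn{f_{pred} = \frac{C}{C + A B}, \quad
#'   C = f_{WT}^{-1} - 1,\; A = f_\alpha^{-1} - 1,\; B = f_\beta^{-1} - 1.}
#' A mutation with \eqn{f = f_{WT}} is neutral and cancels out; a fully
#' disabling pair (\eqn{f_\alpha = f_\beta = 1}) predicts
#' \eqn{f_{pred} = 1}. If the wild type shows no repression
#' (\eqn{f_{WT} = 1}) the prediction degenerates to 0 and a warning is
#' issued.
#'
#' @param f_WT,f_alpha,f_beta fold-changes in (0, 1].
#' @return Predicted double-mutant fold-change.
#' @export
predicted_double_fold <- function(f_WT, f_alpha, f_beta) {
  vals <- c(f_WT, f_alpha, f_beta)
  if (any(vals <= 0 | vals > 1)) stop("fold-changes must lie in (0, 1]")
  C <- 1 / f_WT - 1
  A <- 1 / f_alpha - 1
  B <- 1 / f_beta - 1
  if (C == 0) {
    warning("f_WT = 1 (no repression): predicted fold-change degenerates to 0")
    return(0)
  }
  C / (C + A * B)
}

#' Interaction strength of a mutation pair
#'
#' \eqn{IS = f_{pred} / f_{\alpha\beta}}: the additive-model prediction
#' for the double mutant divided by its measured fold-change.
#' \eqn{IS = 1} means the pair is consistent with the additive model;
#' deviations in either direction indicate epistasis.
#'
#' @param f_pred predicted double-mutant fold-change (see
#'   [predicted_double_fold()]).
#' @param f_alphabeta measured double-mutant fold-change, > 0.
#' @return The interaction strength.
#' @export
interaction_strength <- function(f_pred, f_alphabeta) {
  if (any(f_alphabeta <= 0)) stop("measured double-mutant fold-change must be positive")
  f_pred / f_alphabeta
}

#' Model-free enrichment ratio for a mutation pair
#'
#' With \eqn{\varepsilon} the fraction of a variant's sort-seq reads in
#' the selection gates (by default the bottom two gates),
#' \deqn{K_{\alpha\beta} = \log\frac{\varepsilon_{\alpha\beta}\,
#'   \varepsilon_{WT}}{\varepsilon_\alpha\,\varepsilon_\beta}}
#' (natural log by default). Under a multiplicative null
#' (\eqn{\varepsilon_{\alpha\beta}\varepsilon_{WT} =
#' \varepsilon_\alpha\varepsilon_\beta}) \eqn{K = 0}; it requires no
#' fitted model, only single-gate enrichments (see
#' [enrichment_below()]).
#'
#' @param eps_WT,eps_alpha,eps_beta,eps_alphabeta enrichment fractions,
#'   all > 0.
#' @param base logarithm base (default \code{exp(1)}).
#' @return The enrichment ratio \eqn{K}.
#' @export
enrichment_ratio_K <- function(eps_WT, eps_alpha, eps_beta, eps_alphabeta,
                               base = exp(1)) {
  vals <- c(eps_WT, eps_alpha, eps_beta, eps_alphabeta)
  if (any(vals <= 0)) stop("enrichment fractions must be positive")
  log(eps_alphabeta * eps_WT / (eps_alpha * eps_beta), base = base)
}

#' Epistasis record for a mutation pair
#'
#' Convenience constructor bundling the fold-change-based and
#' enrichment-based interaction statistics for one pair of mutations.
#'
#' @param pair character vector of length 2 naming the mutations.
#' @param f_WT,f_alpha,f_beta,f_alphabeta fold-changes.
#' @param eps_WT,eps_alpha,eps_beta,eps_alphabeta enrichment fractions
#'   (optional; \code{NA} to skip \eqn{K}).
#' @return A one-row data frame with the inputs, \code{f_pred},
#'   \code{IS}, and \code{K}.
#' @export
epistasis_record <- function(pair, f_WT, f_alpha, f_beta, f_alphabeta,
                             eps_WT = NA, eps_alpha = NA, eps_beta = NA,
                             eps_alphabeta = NA) {
  f_pred <- predicted_double_fold(f_WT, f_alpha, f_beta)
  IS <- interaction_strength(f_pred, f_alphabeta)
  K <- if (anyNA(c(eps_WT, eps_alpha, eps_beta, eps_alphabeta))) {
    NA_real_
  } else {
    enrichment_ratio_K(eps_WT, eps_alpha, eps_beta, eps_alphabeta)
  }
  data.frame(alpha = pair[1], beta = pair[2], f_WT = f_WT,
             f_alpha = f_alpha, f_beta = f_beta, f_alphabeta = f_alphabeta,
             f_pred = f_pred, IS = IS, eps_WT = eps_WT,
             eps_alpha = eps_alpha, eps_beta = eps_beta,
             eps_alphabeta = eps_alphabeta, K = K,
             stringsAsFactors = FALSE)
}
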