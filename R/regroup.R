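#' Gate-fraction table (published-dataset style)
#'
#' Container for datasets that report, for each variant \eqn{i}, the
#' fraction \eqn{t_{ij}} of its reads in each of \eqn{m} gates, together
#' with the gate boundaries and the overall per-gate sorted fractions
#' \eqn{T_j}. Per-variant fractions must sum to 1 (tolerance 1e-6 per
#' row); rows violating this are rejected.
#'
#' @param gates a \code{gate_config}.
#' @param T per-gate sorted fractions, summing to 1.
#' @param fractions numeric matrix, variants x gates, rows summing to 1.
#' @param ids variant identifiers (default: rownames or sequence numbers).
#' @return Object of class \code{gate_fraction_table}.
#' @export
gate_fraction_table <- function(gates, T, fractions, ids = NULL) {
  fractions <- as.matrix(fractions)
  stopifnot(inherits(gates, "gate_config"), ncol(fractions) == gates$m,
            length(T) == gates$m)
  if (any(fractions < 0) || any(T < 0)) stop("fractions must be nonnegative")
  if (abs(sum(T) - 1) > 1e-6) stop("per-gate fractions T must sum to 1")
  bad <- abs(rowSums(fractions) - 1) > 1e-6
  if (any(bad)) {
    stop(sprintf("%d variant row(s) have fractions not summing to 1 (first: row %d)",
                 sum(bad), which(bad)[1]))
  }
  if (is.null(ids)) ids <- rownames(fractions)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(fractions)))
  dimnames(fractions) <- list(ids, NULL)
  structure(list(gates = gates, T = T, fractions = fractions, ids = ids),
            class = "gate_fraction_table")
}

#' @export
print.gate_fraction_table <- function(x, ...) {
  cat(sprintf("<gate_fraction_table> %d variants x %d gates\n",
              nrow(x$fractions), x$gates$m))
  invisible(x)
}

#' Read-count table with per-gate sorted-cell totals
#'
#' Container for raw sequencing output: read counts \eqn{r_{ij}} per
#' variant and gate, plus the number of sorted cells \eqn{h_j} per gate,
#' from which depth factors \eqn{d_j = h_j / \sum_i r_{ij}} convert reads
#' back to cells. Optionally carries variant sequences.
#'
#' @param gates a \code{gate_config}.
#' @param h per-gate sorted-cell totals.
#' @param counts nonnegative matrix of reads, variants x gates.
#' @param ids variant identifiers.
#' @param seqs optional character vector of variant sequences.
#' @return Object of class \code{read_count_table}.
#' @export
read_count_table <- function(gates, h, counts, ids = NULL, seqs = NULL) {
  counts <- as.matrix(counts)
  stopifnot(inherits(gates, "gate_config"), ncol(counts) == gates$m,
            length(h) == gates$m)
  if (any(counts < 0) || any(h < 0)) stop("counts must be nonnegative")
  if (is.null(ids)) ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("v", seq_len(nrow(counts)))
  dimnames(counts) <- list(ids, NULL)
  structure(list(gates = gates, h = h, counts = counts, ids = ids,
                 seqs = seqs),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(sprintf("<read_count_table> %d variants x %d gates, %s reads\n",
              nrow(x$counts), x$gates$m,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Per-gate sequencing depth factors
#'
#' \eqn{d_j = h_j / \sum_i r_{ij}} converts reads in gate \eqn{j} back to
#' estimated sorted cells: variant \eqn{i} contributed about
#' \eqn{d_j r_{ij}} cells to gate \eqn{j}. Gates with recorded cells but
#' zero reads get \code{NA} with a warning (such gates carry no usable
#' information and are dropped by downstream summaries).
#'
#' @param table a \code{read_count_table}.
#' @return Numeric vector \eqn{d_j} of length \code{m}.
#' @export
depth_factors <- function(table) {
  stopifnot(inherits(table, "read_count_table"))
  tot <- colSums(table$counts)
  d <- table$h / tot
  empty <- tot == 0 & table$h > 0
  if (any(empty)) {
    warning(sprintf("%d gate(s) have sorted cells but no reads; depth factor set to NA",
                    sum(empty)))
    d[empty] <- NA_real_
  }
  d[tot == 0 & table$h == 0] <- 0
  d
}

normalize_grouping <- function(grouping, m) {
  # accept either a list of consecutive index runs or a length-m group-id
  # vector; always return the list form and validate consecutiveness
  if (!is.list(grouping)) {
    if (length(grouping) != m) stop("group-label vector must have length m")
    runs <- cumsum(c(TRUE, grouping[-1] != grouping[-m]))
    grouping <- unname(split(seq_len(m), runs))
  }
  idx <- unlist(grouping)
  if (!identical(as.integer(idx), seq_len(m))) {
    stop("grouping must partition gates 1..m into consecutive runs, in order")
  }
  grouping
}

#' Combine adjacent sorting gates
#'
#' Emulates a coarser gate configuration from finer data: a combined gate
#' spans \eqn{[L_{first}, U_{last}]}; read counts, per-variant fractions
#' and the sorted fractions \eqn{T_j} (or cell totals \eqn{h_j}) are
#' summed within each group. For read-count tables the depth factors are
#' applied \emph{before} regrouping — \eqn{d_j} is a per-original-gate
#' sequencing artifact — and the combined table holds estimated cells
#' \eqn{\sum d_j r_{ij}} with unit depth.
#'
#' @param table a \code{gate_fraction_table} or \code{read_count_table}.
#' @param grouping an ordered partition of \code{1..m} into consecutive
#'   runs: either a list of index vectors (e.g.
#'   \code{list(1:2, 3:4, ...)}) or a length-\code{m} vector of group
#'   labels.
#' @return A table of the same class over the combined gates.
#' @examples
#' # pair up 32 gates into 16
#' pairs <- lapply(seq_len(16), function(k) c(2 * k - 1, 2 * k))
#' @export
regroup_gates <- function(table, grouping) {
  UseMethod("regroup_gates")
}

#' @export
regroup_gates.gate_fraction_table <- function(table, grouping) {
  g <- normalize_grouping(grouping, table$gates$m)
  gates2 <- combine_gate_runs(table$gates, g)
  T2 <- vapply(g, function(ix) sum(table$T[ix]), numeric(1))
  f2 <- sapply(g, function(ix) {
    rowSums(table$fractions[, ix, drop = FALSE])
  })
  if (is.null(dim(f2))) f2 <- matrix(f2, nrow = 1)
  gate_fraction_table(gates2, T2, f2, ids = table$ids)
}

#' @export
regroup_gates.read_count_table <- function(table, grouping) {
  g <- normalize_grouping(grouping, table$gates$m)
  gates2 <- combine_gate_runs(table$gates, g)
  d <- depth_factors(table)
  d[is.na(d)] <- 0
  cells <- sweep(table$counts, 2, d, `*`)
  c2 <- sapply(g, function(ix) rowSums(cells[, ix, drop = FALSE]))
  if (is.null(dim(c2))) c2 <- matrix(c2, nrow = 1)
  h2 <- vapply(g, function(ix) sum(table$h[ix]), numeric(1))
  read_count_table(gates2, h2, c2, ids = table$ids, seqs = table$seqs)
}

combine_gate_runs <- function(gates, grouping) {
  lower <- vapply(grouping, function(ix) gates$lower[ix[1]], numeric(1))
  upper <- vapply(grouping, function(ix) gates$upper[ix[length(ix)]],
                  numeric(1))
  gate_config(lower, upper)
}

#' Fraction of a variant's cells in gate m' or below
#'
#' The single-gate enrichment statistic: for read-count tables,
#' \eqn{\Phi_i = \sum_{j \le m'} d_j r_{ij} / \sum_j d_j r_{ij}} (reads
#' converted to cells via the depth factors); for gate-fraction tables,
#' \eqn{\Phi_i = \sum_{j \le m'} t_{ij}}.
#'
#' @param table a \code{read_count_table} or \code{gate_fraction_table}.
#' @param variant variant id or row index; \code{NULL} returns all
#'   variants.
#' @param m_prime index of the top gate included in the selection.
#' @return Named numeric vector of enrichment fractions.
#' @export
enrichment_below <- function(table, variant = NULL, m_prime) {
  m <- table$gates$m
  if (m_prime < 1 || m_prime > m) stop("`m_prime` out of range")
  mat <- if (inherits(table, "read_count_table")) {
    d <- depth_factors(table)
    d[is.na(d)] <- 0
    sweep(table$counts, 2, d, `*`)
  } else {
    table$fractions
  }
  if (!is.null(variant)) mat <- mat[variant, , drop = FALSE]
  tot <- rowSums(mat)
  if (any(tot == 0)) stop("variant with zero total reads")
  phi <- rowSums(mat[, seq_len(m_prime), drop = FALSE]) / tot
  stats::setNames(phi, rownames(mat))
}

#' Depth-weighted simple mean from a read-count table
#'
#' \eqn{\nu_i = \sum_j d_j r_{ij} \sqrt{L_j U_j} / \sum_j d_j r_{ij}}:
#' the simple mean with cells placed at the geometric gate centers (no
#' bias-correction factor \eqn{b}) and reads converted to cells with the
#' depth factors.
#'
#' @param table a \code{read_count_table} with bounded gates.
#' @param variant variant id/index or \code{NULL} for all.
#' @return Named numeric vector of estimated means.
#' @export
weighted_simple_mean <- function(table, variant = NULL) {
  gates <- table$gates
  if (gates$semibounded_low || gates$semibounded_high) {
    stop("weighted simple mean requires bounded gates")
  }
  d <- depth_factors(table)
  d[is.na(d)] <- 0
  cells <- sweep(table$counts, 2, d, `*`)
  if (!is.null(variant)) cells <- cells[variant, , drop = FALSE]
  tot <- rowSums(cells)
  if (any(tot == 0)) stop("variant with zero total reads")
  phi <- sqrt(gates$lower * gates$upper)
  stats::setNames(as.vector(cells %*% phi) / tot, rownames(cells))
}

#' Fold-change relative to non-functional variants
#'
#' \eqn{f = \nu / \nu_{null}}: measured fluorescence divided by the
#' fluorescence of strains whose variant is non-functional (no
#' regulation). In a repression assay, \eqn{f = 1} means no measurable
#' activity and small \eqn{f} means strong repression.
#'
#' @param nu variant mean fluorescence(s).
#' @param nu_null mean fluorescence of the non-functional reference.
#' @return Fold-change value(s).
#' @export
fold_change <- function(nu, nu_null) {
  if (any(nu_null <= 0)) stop("`nu_null` must be positive")
  nu / nu_null
}
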