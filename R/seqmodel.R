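DNA_BASES <- c("A", "C", "G", "T")

# sequences are handled internally as integer matrices (variants x
# positions, values 1..4 indexing DNA_BASES)
encode_seqs <- function(seqs) {
  if (is.matrix(seqs) && is.numeric(seqs)) return(seqs)
  if (is.matrix(seqs)) {
    enc <- matrix(match(seqs, DNA_BASES), nrow(seqs), ncol(seqs))
  } else {
    n <- length(seqs)
    P <- unique(nchar(seqs))
    if (length(P) != 1) stop("sequences must have a common length")
    chars <- strsplit(toupper(seqs), "", fixed = TRUE)
    enc <- matrix(match(unlist(chars), DNA_BASES), n, P, byrow = TRUE)
  }
  if (anyNA(enc)) stop("sequences contain bases outside A/C/G/T")
  enc
}

decode_seqs <- function(enc) {
  apply(enc, 1, function(row) paste(DNA_BASES[row], collapse = ""))
}

#' Additive (and pairwise-interaction) sequence-activity model
#'
#' The activity of a sequence \eqn{Q} of length \eqn{P} is
#' \deqn{G(Q) = G_0 + \sum_{p} H_{p, Q_p},}
#' where \eqn{H_{p,q}} is the contribution of base \eqn{q} at position
#' \eqn{p} and the reference base at each position is gauge-fixed to
#' \eqn{H = 0}, so the reference sequence has activity exactly
#' \eqn{G_0}. An optional pairwise-interaction tensor \eqn{J} adds
#' \eqn{\sum_{p_1 < p_2} J_{p_1, q_1, p_2, q_2}} for the base pair
#' carried by the sequence; \eqn{J} is stored symmetrically and entries
#' involving a reference base are 0.
#'
#' @param G0 baseline activity of the reference sequence.
#' @param H numeric matrix, 4 x P (rows A, C, G, T), with the reference
#'   base's row zero at each position.
#' @param reference reference sequence (character string of length P).
#' @param J optional interaction array, dim \code{c(4, P, 4, P)},
#'   symmetric under swapping the two (base, position) slots.
#' @return Object of class \code{activity_model}.
#' @export
activity_model <- function(G0, H, reference, J = NULL) {
  ref <- encode_seqs(reference)
  P <- ncol(ref)
  H <- as.matrix(H)
  stopifnot(nrow(H) == 4, ncol(H) == P)
  rownames(H) <- DNA_BASES
  off <- abs(H[cbind(as.vector(ref), seq_len(P))])
  if (any(off > 1e-12)) {
    stop("H must be 0 for the reference base at every position (gauge)")
  }
  if (!is.null(J)) {
    stopifnot(length(dim(J)) == 4, all(dim(J) == c(4, P, 4, P)))
    Jm <- matrix(J, 4 * P, 4 * P)
    if (max(abs(Jm - t(Jm))) > 1e-9) stop("J must be symmetric under pair swap")
  }
  structure(list(G0 = G0, H = H, J = J, reference = reference,
                 P = P, ref_enc = as.vector(ref)),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> P = %d, G0 = %.4g, %s\n", x$P, x$G0,
              if (is.null(x$J)) "additive" else "with pairwise interactions"))
  invisible(x)
}

#' Evaluate model activity for sequences
#'
#' @param model an [activity_model()].
#' @param seqs character vector of sequences (or a pre-encoded integer
#'   matrix).
#' @return Numeric vector of activities \eqn{G} (or \eqn{G_I} when the
#'   model carries interaction terms).
#' @export
activity <- function(model, seqs) {
  enc <- encode_seqs(seqs)
  if (ncol(enc) != model$P) stop("sequence length does not match model")
  P <- model$P
  g <- model$G0 + vapply(seq_len(nrow(enc)), function(i) {
    sum(model$H[cbind(enc[i, ], seq_len(P))])
  }, numeric(1))
  if (!is.null(model$J)) {
    Jm <- matrix(model$J, 4 * P, 4 * P)
    # one-hot index of (base, position) pairs carried by each sequence
    for (i in seq_len(nrow(enc))) {
      idx <- enc[i, ] + 4 * (seq_len(P) - 1)
      g[i] <- g[i] + sum(Jm[idx, idx]) / 2  # symmetric storage, p1 < p2 once
    }
  }
  g
}

#' Draw a random additive model with prescribed mutational robustness
#'
#' Each of the 3 non-reference entries \eqn{H_{p,q}} per position is
#' drawn i.i.d. Normal with mean \eqn{-G_0/R} and standard deviation
#' \eqn{4 G_0 / (3R)}. \eqn{R} is the robustness: the expected activity
#' after \eqn{R} random mutations is \eqn{G_0 + R(-G_0/R) = 0}, so
#' \eqn{R} is roughly the number of mutations at which half the variants
#' drop below the functional threshold \eqn{G < 0}.
#'
#' @param P sequence length (default 50).
#' @param G0 baseline activity (default 3.0).
#' @param R robustness, > 0.
#' @param reference reference sequence; default \code{P} repeats of "A".
#' @return An additive [activity_model()] with attribute-like fields
#'   \code{R} recorded for downstream interaction sampling.
#' @export
sample_additive_model <- function(P = 50, G0 = 3.0, R, reference = NULL) {
  stopifnot(R > 0)
  if (is.null(reference)) reference <- strrep("A", P)
  ref <- as.vector(encode_seqs(reference))
  H <- matrix(stats::rnorm(4 * P, mean = -G0 / R, sd = 4 * G0 / (3 * R)),
              4, P, dimnames = list(DNA_BASES, NULL))
  H[cbind(ref, seq_len(P))] <- 0
  m <- activity_model(G0, H, reference)
  m$R <- R
  m
}

#' Add random pairwise-interaction terms to an additive model
#'
#' Interaction entries \eqn{J_{p_1,q_1,p_2,q_2}} for non-reference base
#' pairs at distinct positions are drawn i.i.d. Normal(0,
#' \eqn{(S G_0 / R)^2}), where \eqn{S} (the interaction power) sets the
#' scale of epistatic terms relative to the additive ones. \eqn{S = 0}
#' returns the purely additive model.
#'
#' @param model an additive [activity_model()] carrying field \code{R}.
#' @param S interaction power, >= 0.
#' @return The model with a symmetric \code{J} array attached.
#' @export
sample_interaction_terms <- function(model, S) {
  stopifnot(S >= 0)
  if (is.null(model$R)) stop("model must record robustness R")
  P <- model$P
  sd_J <- S * model$G0 / model$R
  J <- array(0, dim = c(4, P, 4, P))
  ref <- model$ref_enc
  for (p1 in seq_len(P - 1)) {
    q1s <- setdiff(1:4, ref[p1])
    for (p2 in (p1 + 1):P) {
      q2s <- setdiff(1:4, ref[p2])
      vals <- if (sd_J > 0) stats::rnorm(9, 0, sd_J) else numeric(9)
      k <- 0
      for (q1 in q1s) for (q2 in q2s) {
        k <- k + 1
        J[q1, p1, q2, p2] <- vals[k]
        J[q2, p2, q1, p1] <- vals[k]
      }
    }
  }
  model$J <- J
  model$S <- S
  model
}

#' Map activity to mean fluorescence
#'
#' Two monotone maps are supported. \code{"repression"} is the two-state
#' thermodynamic model common for repressed targets:
#' \eqn{\nu = \nu_{null} (1 + e^G)^{-1}} (activity decreases
#' fluorescence from the non-functional level \eqn{\nu_{null}}).
#' \code{"expression"} is the increasing map \eqn{\nu = 1 + e^G} used for
#' simulated expression libraries.
#'
#' @param G activity value(s).
#' @param mode \code{"repression"} or \code{"expression"}.
#' @param nu_null non-functional mean fluorescence (repression mode).
#' @return Mean fluorescence value(s).
#' @export
activity_to_mean <- function(G, mode = c("repression", "expression"),
                             nu_null = 1) {
  mode <- match.arg(mode)
  if (mode == "repression") {
    if (nu_null <= 0) stop("`nu_null` must be positive")
    nu_null / (1 + exp(G))
  } else {
    1 + exp(G)
  }
}

#' Random mutant library at a given mutation rate
#'
#' Each position of each variant independently keeps the reference base
#' with probability \eqn{1 - r_{mut}/P} or substitutes one of the three
#' alternatives uniformly, so the mean number of mutations per variant is
#' \eqn{r_{mut}}. (A mutated position carries exactly one substitution.)
#'
#' @param reference reference sequence.
#' @param n_variants library size (default 3000).
#' @param r_mut mean mutations per variant, in (0, P).
#' @return Character vector of variant sequences.
#' @export
make_random_library <- function(reference, n_variants = 3000, r_mut) {
  ref <- as.vector(encode_seqs(reference))
  P <- length(ref)
  if (r_mut <= 0 || r_mut >= P) stop("`r_mut` must be in (0, P)")
  enc <- matrix(ref, n_variants, P, byrow = TRUE)
  hit <- matrix(stats::runif(n_variants * P) < r_mut / P, n_variants, P)
  n_hit <- sum(hit)
  if (n_hit > 0) {
    # pick one of the 3 non-reference bases uniformly
    shift <- sample.int(3, n_hit, replace = TRUE)
    enc[hit] <- ((enc[hit] - 1 + shift) %% 4) + 1
  }
  decode_seqs(enc)
}

#' Targeted single-mutant library
#'
#' The reference sequence plus every single-position mutant: \eqn{3P + 1}
#' sequences for length \eqn{P} (151 for \eqn{P = 50}).
#'
#' @param reference reference sequence.
#' @return Character vector of sequences; the reference comes first, then
#'   mutants ordered by position and base.
#' @export
make_targeted_library <- function(reference) {
  ref <- as.vector(encode_seqs(reference))
  P <- length(ref)
  out <- character(1 + 3 * P)
  out[1] <- paste(DNA_BASES[ref], collapse = "")
  k <- 1
  for (p in seq_len(P)) {
    for (q in setdiff(1:4, ref[p])) {
      k <- k + 1
      mut <- ref
      mut[p] <- q
      out[k] <- paste(DNA_BASES[mut], collapse = "")
    }
  }
  out
}

#' Write / read model parameters as TSV tables
#'
#' The additive part is one row per (position, base) with column \code{H}
#' (reference-base rows included with H = 0); interactions, if present,
#' are a second table with columns \code{p1, q1, p2, q2, J} listing each
#' unordered pair once.
#'
#' @param model an [activity_model()].
#' @param path path of the additive table; the interaction table (if any)
#'   goes to \code{paste0(path, ".interactions")}.
#' @return \code{write_activity_model}: \code{path}, invisibly;
#'   \code{read_activity_model}: an [activity_model()].
#' @export
write_activity_model <- function(model, path) {
  df <- data.frame(
    position = rep(seq_len(model$P), each = 4),
    base = rep(DNA_BASES, model$P),
    H = as.vector(model$H)
  )
  hdr <- sprintf("# G0=%.17g reference=%s", model$G0, model$reference)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  if (!is.null(model$J)) {
    P <- model$P
    rows <- which(model$J != 0, arr.ind = TRUE)
    rows <- rows[rows[, 2] < rows[, 4] |
                   (rows[, 2] == rows[, 4] & rows[, 1] < rows[, 3]), ,
                 drop = FALSE]
    jdf <- data.frame(p1 = rows[, 2], q1 = DNA_BASES[rows[, 1]],
                      p2 = rows[, 4], q2 = DNA_BASES[rows[, 3]],
                      J = model$J[rows])
    utils::write.table(jdf, paste0(path, ".interactions"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_activity_model
#' @export
read_activity_model <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("# G0=([^ ]+) reference=([ACGT]+)", hdr))[[1]]
  if (length(m) != 3) stop("malformed model header")
  G0 <- as.numeric(m[2])
  reference <- m[3]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE)
  P <- max(df$position)
  H <- matrix(0, 4, P, dimnames = list(DNA_BASES, NULL))
  H[cbind(match(df$base, DNA_BASES), df$position)] <- df$H
  J <- NULL
  jpath <- paste0(path, ".interactions")
  if (file.exists(jpath)) {
    jdf <- utils::read.table(jpath, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    J <- array(0, dim = c(4, P, 4, P))
    for (k in seq_len(nrow(jdf))) {
      q1 <- match(jdf$q1[k], DNA_BASES); q2 <- match(jdf$q2[k], DNA_BASES)
      J[q1, jdf$p1[k], q2, jdf$p2[k]] <- jdf$J[k]
      J[q2, jdf$p2[k], q1, jdf$p1[k]] <- jdf$J[k]
    }
  }
  activity_model(G0, H, reference, J)
}

#' Write / read a variant library as FASTA
#'
#' Thin wrappers over plain-text FASTA for sequence libraries. Uses
#' Biostrings when available, else a minimal built-in writer/reader.
#'
#' @param seqs named or unnamed character vector of sequences.
#' @param path file path.
#' @return \code{write_library_fasta}: \code{path} invisibly;
#'   \code{read_library_fasta}: named character vector.
#' @export
write_library_fasta <- function(seqs, path) {
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("v", seq_along(seqs))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(stats::setNames(seqs, nm))
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(paste0(">", nm, "\n", seqs), path)
  }
  invisible(path)
}

#' @rdname write_library_fasta
#' @export
read_library_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                   collapse = "")
    stats::setNames(seqs, sub("^>", "", lines[hdr]))
  }
}
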