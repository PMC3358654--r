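#' Inside probabilities over the constrained grammar
#'
#' Fills the chart alpha(S, i, j) = Prob(S =>* x_i ... x_j) for the three
#' nonterminals by dynamic programming over increasing span length, in log
#' space (so nonzero values never underflow for sequences into the hundreds
#' of bases). alpha(X, 1, n) is the total probability of the sequence under
#' the model; it is always positive because the all-unpaired chain derivation
#' exists for every sequence.
#'
#' @param x an [rna_seq()] (or a plain string, coerced).
#' @param model a [triple_model()].
#' @return An object of class `inside_chart`: log-probability matrices
#'   `alpha$X`, `alpha$H`, `alpha$Y` (entry `[i, j]` is the 1-based span
#'   i..j), `logZ`, `n`, `id`, and the model.
#' @export
scfg_inside <- function(x, model = triple_model()) {
  x <- as_rna_seq(x)
  ch <- scfg_inside_cpp(seq_codes(x), model$lp, model$lu, model$lpi)
  structure(list(alpha = list(X = ch$alphaX, H = ch$alphaH, Y = ch$alphaY),
                 logZ = ch$logZ, n = x$n, id = x$id, model = model),
            class = "inside_chart")
}

#' Outside probabilities over the constrained grammar
#'
#' Fills beta(S, i, j) = Prob(X_start =>* x_1..x_{i-1} S x_{j+1}..x_n),
#' top-down from beta(X, 1, n) = 1, distributing each rule's outside mass to
#' its children. For every nonterminal and span, alpha * beta is the total
#' probability of derivations in which that nonterminal spans (i, j).
#'
#' @param x the same sequence the inside chart was built from.
#' @param inside an [scfg_inside()] chart.
#' @return An object of class `outside_chart` with log matrices `beta$X`,
#'   `beta$H`, `beta$Y`.
#' @export
scfg_outside <- function(x, inside) {
  x <- as_rna_seq(x)
  stopifnot(inherits(inside, "inside_chart"))
  if (inside$n != x$n)
    stop("inside chart was built for a sequence of length ", inside$n,
         ", not ", x$n)
  m <- inside$model
  ch <- scfg_outside_cpp(seq_codes(x), m$lp, m$lu, m$lpi,
                         inside$alpha$X, inside$alpha$H, inside$alpha$Y)
  structure(list(beta = list(X = ch$betaX, H = ch$betaH, Y = ch$betaY),
                 n = x$n, id = x$id),
            class = "outside_chart")
}

#' Base-pair probability matrix
#'
#' The marginal probability that positions i and j pair, over all
#' derivations: each pair-emitting rule S -> aRbT contributes
#' ruleprob * pi(x_i, x_j) * gamma(R, S, T, i, j) with
#' gamma = sum_(j < k <= n) alpha(R, i+1, j-1) beta(S, i, k) alpha(T, j+1, k)
#' (for rules with no trailing T the sum collapses to k = j), all normalized
#' by the total inside probability. Entries at non-canonical (x_i, x_j) are
#' exactly zero, and each row sums to at most 1 since a base pairs with at
#' most one partner in any derivation.
#'
#' @param x the sequence.
#' @param inside,outside matching charts from [scfg_inside()] /
#'   [scfg_outside()].
#' @return An upper-triangular n x n matrix of class `pair_prob_matrix` with
#'   attributes `id` and `n`.
#' @export
pair_probabilities <- function(x, inside, outside) {
  x <- as_rna_seq(x)
  stopifnot(inherits(inside, "inside_chart"), inherits(outside, "outside_chart"))
  if (inside$n != x$n || outside$n != x$n)
    stop("chart/sequence length mismatch")
  m <- inside$model
  P <- scfg_pairprob_cpp(seq_codes(x), m$lp, m$lpi,
                         inside$alpha$X, inside$alpha$H, inside$alpha$Y,
                         outside$beta$X, outside$beta$H, outside$beta$Y,
                         inside$logZ)
  structure(P, class = c("pair_prob_matrix", "matrix"), id = x$id, n = x$n)
}

#' Pair probabilities in one call
#'
#' @param x sequence; @param model a [triple_model()].
#' @return a `pair_prob_matrix`.
#' @export
pair_prob_matrix <- function(x, model = triple_model()) {
  x <- as_rna_seq(x)
  ins <- scfg_inside(x, model)
  pair_probabilities(x, ins, scfg_outside(x, ins))
}

#' Shannon base-pairing entropy
#'
#' Q(x) = -(1/n) * sum_(i<j) P_ij log P_ij, with the convention
#' 0 log 0 = 0. The logarithm is natural by default; because downstream
#' Z-scores standardize Q, changing the base rescales all entropies by a
#' constant and leaves every Z-score unchanged.
#'
#' @param P a `pair_prob_matrix`.
#' @param base logarithm base (default `exp(1)`).
#' @return An object of class `entropy_result`: list with `Q`, `n`, and
#'   `expected_pairs` (= sum of all P_ij).
#' @export
shannon_entropy <- function(P, base = exp(1)) {
  stopifnot(inherits(P, "pair_prob_matrix"))
  n <- attr(P, "n")
  p <- P[upper.tri(P)]
  p <- p[p > 0]
  Q <- if (length(p) == 0) 0 else -sum(p * log(p, base = base)) / n
  structure(list(Q = Q, n = n, expected_pairs = sum(P[upper.tri(P)]),
                 id = attr(P, "id")),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> %s  n=%d  Q=%.6f  E[pairs]=%.3f\n",
              x$id, x$n, x$Q, x$expected_pairs))
  invisible(x)
}

#' Entropy of a sequence in one call
#'
#' @inheritParams pair_prob_matrix
#' @param base logarithm base for the entropy.
#' @return an `entropy_result`.
#' @export
base_pairing_entropy <- function(x, model = triple_model(), base = exp(1)) {
  shannon_entropy(pair_prob_matrix(x, model), base = base)
}

#' Export a pair-probability matrix as a sparse TSV
#'
#' Writes one row (i, j, prob) per entry with P_ij > 0, 1-based positions.
#'
#' @param P a `pair_prob_matrix`; @param path output file.
#' @export
write_pair_probs <- function(P, path) {
  stopifnot(inherits(P, "pair_prob_matrix"))
  idx <- which(P > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   prob = sprintf("%.6f", P[idx]))
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
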