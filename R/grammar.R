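#' The stem-constrained grammar
#'
#' Returns a description of the seven production rules
#' \preformatted{
#'   (1) X -> a     (2) X -> aX     (3) X -> aHb   (4) X -> aHbX
#'   (5) H -> aHb   (6) H -> aYb    (7) Y -> aXb
#' }
#' with start symbol X. A stem can only be opened through X -> aHb (or aHbX),
#' continued through H, and closed through H -> aYb then Y -> aXb, so every
#' complete derivation places at least three directly nested base pairs in
#' each stem. Minimum spans follow: Y derives >= 3 positions, H >= 5, and a
#' pair-carrying expansion of X >= 7; a hairpin loop always contains at least
#' one position.
#'
#' @return An object of class `triple_grammar` listing the rules with their
#'   left-hand sides and right-hand-side shapes.
#' @export
triple_grammar <- function() {
  rules <- data.frame(
    rule = 1:7,
    lhs = c("X", "X", "X", "X", "H", "H", "Y"),
    rhs = c("a", "aX", "aHb", "aHbX", "aHb", "aYb", "aXb"),
    emits_pair = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    child = c("", "X", "H", "H+X", "H", "Y", "X"),
    stringsAsFactors = FALSE
  )
  structure(list(nonterminals = c("X", "H", "Y"), start = "X", rules = rules,
                 min_span = c(X = 1L, H = 5L, Y = 3L)),
            class = "triple_grammar")
}

#' @export
print.triple_grammar <- function(x, ...) {
  cat("<triple_grammar> start = X; every stem has >= 3 nested pairs\n")
  with(x$rules, cat(paste0("  (", rule, ") ", lhs, " -> ", rhs), sep = "\n"))
  invisible(x)
}

#' Maximum-entropy rule probabilities
#'
#' Solves for the seven rule probabilities without any training data, from
#' the requirement that the probability contribution of a base pair stay
#' close to that of unpaired bases. With `u` the unpaired-base probability
#' (its geometric mean for non-uniform emissions; 0.25 at the defaults) and
#' `qbp` the geometric mean of the six canonical pair probabilities, the
#' constraints are
#' \preformatted{
#'   p1 = p2,  p3 = p4,  p1 + p2 + p3 + p4 = 1,  p5 + p6 = 1,  p7 = 1,
#'   qbp^3 * p3 * p6 * p7 = (u * p1)^6,
#'   qbp^4 * p3 * p5 * p6 * p7 = (u * p1)^8.
#' }
#' Dividing the last two gives `p5 = (u p1)^2 / qbp`, and the system is
#' closed by `p3 = (u p1)^6 / (qbp^3 (1 - p5))` and `p1 = 1/2 - p3`. The
#' solver is a deterministic fixed-point iteration on these three
#' assignments starting from `p1 = 0.5`; it converges rapidly because
#' `p3 << 1`. With the default emissions the solution rounds to
#' p1 = p2 = 0.499, p3 = p4 = 0.001, p5 = 0.103, p6 = 0.897, p7 = 1.
#'
#' @param em an [emission_model()].
#' @param tol convergence tolerance on successive (p1, p3, p5) iterates.
#' @param max_iter iteration cap before a solver-failure error.
#' @return An object of class `grammar_params`: list with `p` (named vector
#'   p1..p7), `qbp`, and `u` (the unpaired probability used).
#' @examples
#' round(solve_rule_probabilities(emission_model())$p, 3)
#' @export
solve_rule_probabilities <- function(em = emission_model(), tol = 1e-12,
                                     max_iter = 1000L) {
  stopifnot(inherits(em, "emission_model"))
  qbp <- compute_qbp(em)
  if (any(em$unpaired <= 0))
    stop("unpaired probabilities must be > 0 to solve the constraint system")
  u <- exp(mean(log(em$unpaired)))

  p1 <- 0.5; p3 <- 0; p5 <- 0
  for (it in seq_len(max_iter)) {
    p5_new <- (u * p1)^2 / qbp
    p3_new <- (u * p1)^6 / (qbp^3 * (1 - p5_new))
    p1_new <- 0.5 - p3_new
    delta <- max(abs(c(p1_new - p1, p3_new - p3, p5_new - p5)))
    p1 <- p1_new; p3 <- p3_new; p5 <- p5_new
    if (delta < tol) break
    if (it == max_iter)
      stop("rule-probability solver failed to converge in ", max_iter,
           " iterations")
  }
  p <- c(p1 = p1, p2 = p1, p3 = p3, p4 = p3, p5 = p5, p6 = 1 - p5, p7 = 1)
  if (any(p < 0) || any(p > 1))
    stop("solved rule probabilities left [0, 1]; emission model is too ",
         "skewed for the constraint system")

  res <- c(qbp^3 * p[["p3"]] * p[["p6"]] - (u * p[["p1"]])^6,
           qbp^4 * p[["p3"]] * p[["p5"]] * p[["p6"]] - (u * p[["p1"]])^8)
  if (any(abs(res) > 1e-9))
    stop("constraint residuals exceed 1e-9 at the returned solution")

  structure(list(p = p, qbp = qbp, u = u), class = "grammar_params")
}

#' @export
print.grammar_params <- function(x, ...) {
  cat("<grammar_params>",
      paste(sprintf("%s=%.4g", names(x$p), x$p), collapse = " "),
      sprintf("(qbp=%.4g)\n", x$qbp))
  invisible(x)
}

#' Bundle the grammar, its rule probabilities and emissions
#'
#' Convenience constructor solving the rule probabilities from the emission
#' model at creation time (they are never hard-coded) and precomputing the
#' log-space parameter tables used by the chart algorithms.
#'
#' @param em an [emission_model()].
#' @param tol solver tolerance passed to [solve_rule_probabilities()].
#' @return An object of class `triple_model`.
#' @export
triple_model <- function(em = emission_model(), tol = 1e-12) {
  params <- solve_rule_probabilities(em, tol = tol)
  lpi <- suppressWarnings(log(em$pair_matrix))   # -Inf at non-canonical pairs
  structure(list(grammar = triple_grammar(), em = em, params = params,
                 lp = log(params$p), lu = log(em$unpaired), lpi = lpi),
            class = "triple_model")
}

#' @export
print.triple_model <- function(x, ...) {
  cat("<triple_model>\n")
  print(x$params)
  print(x$em)
  invisible(x)
}
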