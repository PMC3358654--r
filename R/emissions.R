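CANONICAL_PAIRS <- c("GC", "CG", "AU", "UA", "GU", "UG")

#' Emission model for unpaired bases and base pairs
#'
#' The grammar emits terminals with two separate distributions: one over the
#' four unpaired bases and one over the six canonical ordered base pairs
#' (Watson-Crick plus wobble); all non-canonical pairs have probability
#' exactly zero. Defaults are the uniform 0.25 per base and
#' \{G-C: 0.25, C-G: 0.25, A-U: 0.17, U-A: 0.17, G-U: 0.08, U-G: 0.08\}.
#'
#' @param unpaired named numeric vector of probabilities for A, C, G, U;
#'   must sum to 1.
#' @param paired named numeric vector of probabilities for the six ordered
#'   canonical pairs "GC", "CG", "AU", "UA", "GU", "UG"; must sum to 1 and
#'   be strictly positive.
#' @return An object of class `emission_model` with elements `unpaired`,
#'   `paired`, and `pair_matrix` (4x4 matrix over A,C,G,U with zeros at
#'   non-canonical entries).
#' @examples
#' em <- emission_model()
#' compute_qbp(em)
#' @export
emission_model <- function(unpaired = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                           paired = c(GC = 0.25, CG = 0.25, AU = 0.17,
                                      UA = 0.17, GU = 0.08, UG = 0.08)) {
  unpaired <- unpaired[BASES]
  paired <- paired[CANONICAL_PAIRS]
  if (anyNA(unpaired)) stop("unpaired must name all of A, C, G, U")
  if (anyNA(paired)) stop("paired must name all six canonical pairs")
  if (any(unpaired < 0) || abs(sum(unpaired) - 1) > 1e-9)
    stop("unpaired probabilities must be nonnegative and sum to 1")
  if (any(paired <= 0))
    stop("all six canonical pair probabilities must be > 0")
  if (abs(sum(paired) - 1) > 1e-9)
    stop("paired probabilities must sum to 1")

  pm <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (p in CANONICAL_PAIRS) {
    pm[substr(p, 1, 1), substr(p, 2, 2)] <- paired[[p]]
  }
  structure(list(unpaired = unpaired, paired = paired, pair_matrix = pm),
            class = "emission_model")
}

#' Geometric mean of the canonical pair probabilities
#'
#' `qbp` is the sixth root of the product of the six canonical pair
#' probabilities; it is the per-pair emission scale entering the
#' maximum-entropy constraints on the rule probabilities.
#'
#' @param em an [emission_model()].
#' @return A single probability.
#' @export
compute_qbp <- function(em) {
  stopifnot(inherits(em, "emission_model"))
  if (any(em$paired <= 0)) stop("invalid emission model: pair probability <= 0")
  exp(mean(log(em$paired)))
}

#' @export
print.emission_model <- function(x, ...) {
  cat("<emission_model>\n  unpaired:",
      paste(sprintf("%s=%.3g", names(x$unpaired), x$unpaired), collapse = " "),
      "\n  paired:  ",
      paste(sprintf("%s=%.3g", names(x$paired), x$paired), collapse = " "),
      "\n  qbp:", format(compute_qbp(x), digits = 6), "\n")
  invisible(x)
}
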