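#' Enumerate every derivation of a short sequence
#'
#' Exhaustive recursion over the seven rules, for validation only. Each
#' complete derivation is returned with its exact probability (product of
#' rule and emission probabilities) and its set of base pairs. Derivations
#' are kept distinct even when they carry identical pair sets: the grammar is
#' ambiguous at the structure level (a long helix can be split between
#' nested stems), and the chart algorithms marginalize derivations, so the
#' oracle does the same to keep the equivalence well-posed.
#'
#' @param x an [rna_seq()] (or string).
#' @param model a [triple_model()].
#' @param max_n refuse sequences longer than this (combinatorial blow-up
#'   guard; enumeration is exponential-ish in n).
#' @return A list of structures, each a list with `pairs` (2-column matrix,
#'   1-based, i < j) and `prob`. Probabilities sum to the total inside
#'   probability of the sequence.
#' @export
enumerate_derivations <- function(x, model = triple_model(), max_n = 14L) {
  x <- as_rna_seq(x)
  if (x$n > max_n)
    stop("refusing to enumerate n = ", x$n, " > ", max_n)
  p <- model$params$p
  u <- model$em$unpaired
  pm <- model$em$pair_matrix
  b <- strsplit(x$seq, "", fixed = TRUE)[[1L]]
  no_pairs <- matrix(integer(), ncol = 2)
  memo <- new.env(parent = emptyenv())

  scale_all <- function(ds, f, add = NULL) {
    lapply(ds, function(d) list(
      pairs = if (is.null(add)) d$pairs else rbind(add, d$pairs),
      prob = d$prob * f))
  }

  derive <- function(nt, i, j) {
    key <- paste(nt, i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    len <- j - i + 1L
    if (nt == "X") {
      if (i == j) {
        out <- list(list(pairs = no_pairs, prob = p[["p1"]] * u[[b[i]]]))
      } else {
        out <- scale_all(derive("X", i + 1L, j), p[["p2"]] * u[[b[i]]])
        if (len >= 7L && pm[b[i], b[j]] > 0)
          out <- c(out, scale_all(derive("H", i + 1L, j - 1L),
                                  p[["p3"]] * pm[b[i], b[j]],
                                  add = c(i, j)))
        if (len >= 8L) {
          for (k in (i + 6L):(j - 1L)) {
            if (pm[b[i], b[k]] == 0) next
            for (dh in derive("H", i + 1L, k - 1L))
              for (dx in derive("X", k + 1L, j))
                out <- c(out, list(list(
                  pairs = rbind(c(i, k), dh$pairs, dx$pairs),
                  prob = p[["p4"]] * pm[b[i], b[k]] * dh$prob * dx$prob)))
          }
        }
      }
    } else if (nt == "H") {
      if (len >= 5L && pm[b[i], b[j]] > 0) {
        if (len >= 7L)
          out <- scale_all(derive("H", i + 1L, j - 1L),
                           p[["p5"]] * pm[b[i], b[j]], add = c(i, j))
        out <- c(out, scale_all(derive("Y", i + 1L, j - 1L),
                                p[["p6"]] * pm[b[i], b[j]], add = c(i, j)))
      }
    } else {                                  # Y
      if (len >= 3L && pm[b[i], b[j]] > 0)
        out <- scale_all(derive("X", i + 1L, j - 1L),
                         p[["p7"]] * pm[b[i], b[j]], add = c(i, j))
    }
    memo[[key]] <- out
    out
  }
  derive("X", 1L, x$n)
}

#' Pair probabilities by brute-force enumeration
#'
#' Definitional computation: the probability-weighted frequency of each pair
#' across all enumerated derivations, normalized by the total probability.
#' Used as the independent oracle for the inside-outside implementation.
#'
#' @inheritParams enumerate_derivations
#' @return a `pair_prob_matrix`.
#' @export
oracle_pair_probabilities <- function(x, model = triple_model(), max_n = 14L) {
  x <- as_rna_seq(x)
  ds <- enumerate_derivations(x, model, max_n = max_n)
  P <- matrix(0, x$n, x$n)
  total <- sum(vapply(ds, `[[`, numeric(1), "prob"))
  for (d in ds) {
    if (nrow(d$pairs) > 0)
      P[d$pairs] <- P[d$pairs] + d$prob
  }
  structure(P / total, class = c("pair_prob_matrix", "matrix"),
            id = x$id, n = x$n)
}

# Total inside probability by direct naive recursion (no memoization, no
# enumeration): an independently coded cross-check for the enumerator and
# the chart algorithms on tiny inputs.
naive_total_probability <- function(x, model = triple_model()) {
  x <- as_rna_seq(x)
  p <- model$params$p
  u <- model$em$unpaired
  pm <- model$em$pair_matrix
  b <- strsplit(x$seq, "", fixed = TRUE)[[1L]]
  fX <- function(i, j) {
    if (i == j) return(p[["p1"]] * u[[b[i]]])
    tot <- p[["p2"]] * u[[b[i]]] * fX(i + 1, j)
    if (j - i >= 6 && pm[b[i], b[j]] > 0)
      tot <- tot + p[["p3"]] * pm[b[i], b[j]] * fH(i + 1, j - 1)
    if (j - i >= 7)
      for (k in (i + 6):(j - 1))
        if (pm[b[i], b[k]] > 0)
          tot <- tot + p[["p4"]] * pm[b[i], b[k]] * fH(i + 1, k - 1) * fX(k + 1, j)
    tot
  }
  fH <- function(i, j) {
    if (j - i < 4 || pm[b[i], b[j]] == 0) return(0)
    tot <- p[["p6"]] * pm[b[i], b[j]] * fY(i + 1, j - 1)
    if (j - i >= 6)
      tot <- tot + p[["p5"]] * pm[b[i], b[j]] * fH(i + 1, j - 1)
    tot
  }
  fY <- function(i, j) {
    if (j - i < 2 || pm[b[i], b[j]] == 0) return(0)
    p[["p7"]] * pm[b[i], b[j]] * fX(i + 1, j - 1)
  }
  fX(1L, x$n)
}

# Linear-space inside/outside/pair-probability reference in plain R.
# Independent of the compiled log-space kernels; valid while linear-space
# probabilities stay above the double-precision underflow floor (n <~ 300;
# we use it for n <= 60).
pair_probs_linear <- function(x, model = triple_model()) {
  x <- as_rna_seq(x)
  n <- x$n
  p <- unname(model$params$p)
  b <- seq_codes(x) + 1L
  u <- unname(model$em$unpaired)[b]
  pm <- unname(model$em$pair_matrix)
  aX <- aH <- aY <- matrix(0, n, n)
  for (i in seq_len(n)) aX[i, i] <- p[1] * u[i]
  if (n >= 2) for (len in 2:n) for (i in 1:(n - len + 1)) {
    j <- i + len - 1
    pij <- pm[b[i], b[j]]
    if (len >= 3 && pij > 0) aY[i, j] <- p[7] * pij * aX[i + 1, j - 1]
    if (len >= 5 && pij > 0) {
      v <- p[6] * pij * aY[i + 1, j - 1]
      if (len >= 7) v <- v + p[5] * pij * aH[i + 1, j - 1]
      aH[i, j] <- v
    }
    v <- p[2] * u[i] * aX[i + 1, j]
    if (len >= 7 && pij > 0) v <- v + p[3] * pij * aH[i + 1, j - 1]
    if (len >= 8) for (k in (i + 6):(j - 1))
      if (pm[b[i], b[k]] > 0 && aH[i + 1, k - 1] > 0)
        v <- v + p[4] * pm[b[i], b[k]] * aH[i + 1, k - 1] * aX[k + 1, j]
    aX[i, j] <- v
  }
  Z <- aX[1, n]

  bX <- bH <- bY <- matrix(0, n, n)
  bX[1, n] <- 1
  if (n >= 2) for (len in n:2) for (i in 1:(n - len + 1)) {
    j <- i + len - 1
    pij <- pm[b[i], b[j]]
    oX <- bX[i, j]
    if (oX > 0) {
      bX[i + 1, j] <- bX[i + 1, j] + p[2] * u[i] * oX
      if (len >= 7 && pij > 0)
        bH[i + 1, j - 1] <- bH[i + 1, j - 1] + p[3] * pij * oX
      if (len >= 8) for (k in (i + 6):(j - 1))
        if (pm[b[i], b[k]] > 0 && aH[i + 1, k - 1] > 0) {
          bH[i + 1, k - 1] <- bH[i + 1, k - 1] +
            p[4] * pm[b[i], b[k]] * aX[k + 1, j] * oX
          bX[k + 1, j] <- bX[k + 1, j] +
            p[4] * pm[b[i], b[k]] * aH[i + 1, k - 1] * oX
        }
    }
    oH <- bH[i, j]
    if (len >= 5 && pij > 0 && oH > 0) {
      if (len >= 7) bH[i + 1, j - 1] <- bH[i + 1, j - 1] + p[5] * pij * oH
      bY[i + 1, j - 1] <- bY[i + 1, j - 1] + p[6] * pij * oH
    }
    oY <- bY[i, j]
    if (len >= 3 && pij > 0 && oY > 0)
      bX[i + 1, j - 1] <- bX[i + 1, j - 1] + p[7] * pij * oY
  }

  P <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pij <- pm[b[i], b[j]]
    if (pij == 0) next
    len <- j - i + 1
    acc <- 0
    if (len >= 7) acc <- acc + p[3] * pij * aH[i + 1, j - 1] * bX[i, j] +
        p[5] * pij * aH[i + 1, j - 1] * bH[i, j]
    if (len >= 5) acc <- acc + p[6] * pij * aY[i + 1, j - 1] * bH[i, j]
    if (len >= 3) acc <- acc + p[7] * pij * aX[i + 1, j - 1] * bY[i, j]
    if (len >= 7 && j < n && aH[i + 1, j - 1] > 0)
      for (k in (j + 1):n)
        acc <- acc + p[4] * pij * aH[i + 1, j - 1] * bX[i, k] * aX[j + 1, k]
    P[i, j] <- acc / Z
  }
  structure(P, class = c("pair_prob_matrix", "matrix"), id = x$id, n = n)
}

#' Decompose a structure's pairs into stems
#'
#' A stem is a maximal run of directly nested pairs (i, j), (i+1, j-1), ...
#' Every structure the grammar derives has stems of length >= 3.
#'
#' @param pairs 2-column matrix of base pairs (i < j).
#' @return Integer vector of stem lengths (empty for an unpaired structure).
#' @export
stem_lengths <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) return(integer())
  key <- paste(pairs[, 1], pairs[, 2])
  has <- function(i, j) paste(i, j) %in% key
  lens <- integer()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (has(i - 1, j + 1)) next             # not the outermost pair of a run
    l <- 1L
    while (has(i + l, j - l)) l <- l + 1L
    lens <- c(lens, l)
  }
  lens
}

#' Deterministic fixture panel of test sequences
#'
#' Mixes uniform-random sequences, structured sequences sampled from the
#' grammar (with the fixture parameterization of [fixture_model()]), and
#' degenerate cases (poly-A, alternating GC, alternating GU) across the
#' requested sizes.
#'
#' @param seed integer seed; the same seed always yields the same panel.
#' @param sizes integer vector of sequence lengths, each in 1..500.
#' @return A named list of [rna_seq()] objects.
#' @export
make_fixture_panel <- function(seed, sizes) {
  stopifnot(all(sizes >= 1), all(sizes <= 500))
  with_seed(seed, {
    panel <- list()
    for (n in sizes) {
      panel[[paste0("rand", n)]] <- rna_seq(
        paste(sample(BASES, n, replace = TRUE), collapse = ""),
        id = paste0("rand", n))
      panel[[paste0("polyA", n)]] <- rna_seq(strrep("A", n),
                                             id = paste0("polyA", n))
      panel[[paste0("gc", n)]] <- rna_seq(
        substr(strrep("GC", n), 1, n), id = paste0("gc", n))
      panel[[paste0("gu", n)]] <- rna_seq(
        substr(strrep("GU", n), 1, n), id = paste0("gu", n))
      if (n >= 12) {
        s <- sample_structured(fixture_model(), min_length = max(1L, n %/% 2L),
                               max_length = n)
        s$sequence$id <- paste0("struct", n)
        panel[[paste0("struct", n)]] <- s$sequence
      }
    }
    panel
  })
}
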