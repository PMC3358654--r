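p_of <- function(m) m$params$p

test_that("inside chart matches hand-computed single-derivation products", {
  m <- default_model
  p <- p_of(m)
  expect_equal(exp(scfg_inside("A", m)$logZ), p[["p1"]] * 0.25,
               tolerance = 1e-12)
  # no canonical pairs: one unpaired chain derivation
  expect_equal(exp(scfg_inside("AAAA", m)$logZ),
               (p[["p2"]] * 0.25)^3 * p[["p1"]] * 0.25, tolerance = 1e-12)
})

test_that("outside chart has unit root context and hand-checked cells", {
  m <- default_model
  x <- rna_seq("AAAA")
  ins <- scfg_inside(x, m)
  out <- scfg_outside(x, ins)
  expect_identical(out$beta$X[1, 4], 0)             # log beta(X,1,n) = 0
  # only rule 2 at position 1 exposes span (2, 4)
  expect_equal(exp(out$beta$X[2, 4]), p_of(m)[["p2"]] * 0.25,
               tolerance = 1e-12)
  expect_error(scfg_outside(rna_seq("AAAAA"), ins), "length")
})

test_that("sequences below the minimal pair-bearing span have zero pairs", {
  m <- default_model
  for (s in c("ACGU", "GGGCCC", "GCGCGC", "A")) {
    P <- pair_prob_matrix(s, m)
    expect_true(all(P == 0))
    expect_identical(shannon_entropy(P)$Q, 0)
  }
  expect_true(all(pair_prob_matrix(strrep("A", 30), m) == 0))
})

test_that("pair probabilities equal the enumeration oracle on small panels", {
  m <- default_model
  set.seed(11)
  seqs <- c("GGGAAACCCC", replicate(30, random_rna(sample(7:12, 1))))
  for (s in seqs) {
    P <- pair_prob_matrix(s, m)
    O <- oracle_pair_probabilities(s, m)
    expect_equal(unclass(P), unclass(O), tolerance = 1e-9)
  }
})

test_that("alpha*beta never exceeds the total probability", {
  m <- default_model
  set.seed(5)
  for (s in replicate(10, random_rna(sample(8:14, 1)))) {
    x <- rna_seq(s)
    ins <- scfg_inside(x, m)
    out <- scfg_outside(x, ins)
    for (nt in c("X", "H", "Y")) {
      ab <- ins$alpha[[nt]] + out$beta[[nt]]
      expect_true(all(ab[is.finite(ab)] <= ins$logZ + 1e-9))
    }
  }
})

test_that("entropy follows the closed form with 0 log 0 = 0", {
  mk <- function(P, n) structure(P, class = c("pair_prob_matrix", "matrix"),
                                 id = "t", n = n)
  Z <- matrix(0, 5, 5)
  expect_identical(shannon_entropy(mk(Z, 5))$Q, 0)
  P1 <- matrix(0, 5, 5); P1[1, 5] <- 1
  expect_identical(shannon_entropy(mk(P1, 5))$Q, 0)
  Ph <- matrix(0, 10, 10); Ph[2, 9] <- 0.5
  expect_equal(shannon_entropy(mk(Ph, 10))$Q, -(0.5 * log(0.5)) / 10,
               tolerance = 1e-12)
  expect_equal(shannon_entropy(mk(Ph, 10))$Q, 0.034657, tolerance = 1e-4)
})

test_that("log-space and linear-space computations agree for moderate n", {
  m <- default_model
  set.seed(21)
  for (n in c(20, 40, 60)) {
    s <- random_rna(n)
    P_log <- pair_prob_matrix(s, m)
    P_lin <- triple:::pair_probs_linear(s, m)
    expect_equal(unclass(P_log), unclass(P_lin), tolerance = 1e-9)
    expect_equal(shannon_entropy(P_log)$Q, shannon_entropy(P_lin)$Q,
                 tolerance = 1e-9)
  }
})

test_that("charts stay finite and consistent for long sequences", {
  m <- default_model
  set.seed(31)
  x <- rna_seq(random_rna(400))
  ins <- scfg_inside(x, m)
  expect_true(is.finite(ins$logZ))
  P <- pair_probabilities(x, ins, scfg_outside(x, ins))
  expect_true(all(is.finite(P)))
  expect_true(all(P >= 0 & P <= 1))
})

test_that("runtime grows roughly cubically with sequence length", {
  m <- default_model
  set.seed(41)
  s1 <- random_rna(120); s2 <- random_rna(240)
  t1 <- min(replicate(3, system.time(pair_prob_matrix(s1, m))[["elapsed"]]))
  t2 <- min(replicate(3, system.time(pair_prob_matrix(s2, m))[["elapsed"]]))
  expect_gt(t2 / t1, 4)
  expect_lt(t2 / t1, 16)
})
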