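test_that("qbp is the geometric mean of the six canonical pair probabilities", {
  expect_equal(compute_qbp(emission_model()),
               (0.25 * 0.25 * 0.17 * 0.17 * 0.08 * 0.08)^(1 / 6),
               tolerance = 1e-12)
  expect_equal(compute_qbp(emission_model()), 0.15037, tolerance = 1e-4)

  # identical pair probabilities: geometric mean is that value
  em <- emission_model(paired = c(GC = 1/6, CG = 1/6, AU = 1/6,
                                  UA = 1/6, GU = 1/6, UG = 1/6))
  expect_equal(compute_qbp(em), 1/6, tolerance = 1e-12)

  set.seed(42)
  for (r in 1:20) {
    em <- random_emissions()
    expect_equal(compute_qbp(em), prod(em$paired)^(1/6), tolerance = 1e-12)
  }

  expect_error(emission_model(paired = c(GC = 0, CG = 0.5, AU = 0.17,
                                         UA = 0.17, GU = 0.08, UG = 0.08)),
               "canonical pair probabilities")
})

test_that("maximum-entropy solve reproduces the known parameter values", {
  gp <- solve_rule_probabilities(emission_model())
  expect_equal(round(gp$p[["p1"]], 3), 0.499)
  expect_equal(round(gp$p[["p2"]], 3), 0.499)
  expect_equal(round(gp$p[["p3"]], 3), 0.001)
  expect_equal(round(gp$p[["p4"]], 3), 0.001)
  expect_equal(round(gp$p[["p5"]], 3), 0.103)
  expect_equal(round(gp$p[["p6"]], 3), 0.897)
  expect_identical(gp$p[["p7"]], 1)
})

test_that("solved parameters satisfy the constraint system for any emissions", {
  set.seed(7)
  ems <- c(list(emission_model()), lapply(1:10, function(i) random_emissions()))
  for (em in ems) {
    gp <- tryCatch(solve_rule_probabilities(em), error = function(e) NULL)
    if (is.null(gp)) next          # system can be infeasible for skewed draws
    p <- gp$p; u <- gp$u; qbp <- gp$qbp
    expect_equal(p[["p2"]], p[["p1"]], tolerance = 1e-12)
    expect_equal(p[["p4"]], p[["p3"]], tolerance = 1e-12)
    expect_equal(sum(p[1:4]), 1, tolerance = 1e-9)
    expect_equal(p[["p5"]] + p[["p6"]], 1, tolerance = 1e-9)
    expect_identical(p[["p7"]], 1)
    expect_true(all(p >= 0 & p <= 1))
    expect_lt(abs(qbp^3 * p[["p3"]] * p[["p6"]] - (u * p[["p1"]])^6), 1e-9)
    expect_lt(abs(qbp^4 * p[["p3"]] * p[["p5"]] * p[["p6"]] -
                  (u * p[["p1"]])^8), 1e-9)
  }
})

test_that("fixed-point solution matches an independent root-finder", {
  # Scalar residual in p1 alone; solved with uniroot instead of iteration.
  for (em in list(emission_model(),
                  emission_model(paired = c(GC = 1/6, CG = 1/6, AU = 1/6,
                                            UA = 1/6, GU = 1/6, UG = 1/6)))) {
    qbp <- compute_qbp(em)
    u <- exp(mean(log(em$unpaired)))
    g <- function(p1) {
      p5 <- (u * p1)^2 / qbp
      p3 <- (u * p1)^6 / (qbp^3 * (1 - p5))
      0.5 - p3 - p1
    }
    root <- stats::uniroot(g, c(0.3, 0.5), tol = 1e-14)$root
    expect_equal(solve_rule_probabilities(em)$p[["p1"]], root,
                 tolerance = 1e-9)
  }
})

test_that("grammar structure encodes the seven rules and the span minima", {
  g <- triple_grammar()
  expect_identical(g$rules$rhs,
                   c("a", "aX", "aHb", "aHbX", "aHb", "aYb", "aXb"))
  expect_identical(g$rules$lhs, c("X", "X", "X", "X", "H", "H", "Y"))
  expect_identical(g$min_span, c(X = 1L, H = 5L, Y = 3L))
})
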