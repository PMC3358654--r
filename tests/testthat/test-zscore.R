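test_that("Z-score follows (mu - Q)/sigma with sample sd", {
  z <- zscore(1.0, c(2.0, 3.0, 4.0))
  expect_equal(z$mu, 3.0)
  expect_equal(z$sigma, 1.0)            # sample (n-1) sd
  expect_equal(z$Z, 2.0)
  expect_equal(zscore(3.0, c(2.0, 3.0, 4.0))$Z, 0)
  expect_error(zscore(1.0, c(2, 2, 2)), "zero standard deviation")
  expect_error(zscore(1.0, 2), "at least 2")
})

test_that("KS check accepts normal draws and rejects gross alternatives", {
  set.seed(29)
  normal_ok <- mean(replicate(100, ks_normality(rnorm(100, 5, 2)) >= 0.05))
  expect_gte(normal_ok, 0.90)
  twopoint_rej <- mean(replicate(100, {
    ks_normality(sample(c(0, 1), 100, replace = TRUE)) < 0.05
  }))
  expect_gte(twopoint_rej, 0.95)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("threshold table counts inclusively and stays monotone", {
  tab <- threshold_table(c(2.5, 1.6, 0.7), c(2, 1.5, 1, 0.5))
  expect_equal(tab$percent, c(100 / 3, 200 / 3, 200 / 3, 100),
               tolerance = 1e-9)
  expect_equal(threshold_table(c(-1, -2), c(2, 1.5, 1, 0.5))$percent,
               rep(0, 4))
  # boundary counts: greater than or equal
  expect_equal(threshold_table(2, 2)$percent, 100)
  # undefined Z excluded from numerator and denominator
  expect_equal(threshold_table(c(2.5, NA, NA), 2)$percent, 100)
  # monotone as thresholds decrease
  set.seed(37)
  z <- rnorm(50)
  pct <- threshold_table(z, c(2, 1.5, 1, 0.5))$percent
  expect_true(all(diff(pct) >= 0))
})

test_that("pipeline flags unscorable sequences and keeps the Z identity", {
  m <- default_model
  seqs <- list(rna_seq(strrep("A", 30), id = "polyA"),
               rna_seq("GGGCAUCGGGAAACCCGAAGCCC", id = "hp"))
  out <- run_pipeline(seqs, mode = "mono", count = 20, seed = 4, model = m)
  res <- out$results
  expect_identical(res$flag[res$id == "polyA"], "sigma_zero")
  expect_true(is.na(res$Z[res$id == "polyA"]))
  expect_identical(res$Q[res$id == "polyA"], 0)
  ok <- res[res$flag == "ok", ]
  expect_equal(ok$Z, (ok$mu - ok$Q) / ok$sigma, tolerance = 1e-12)
})

test_that("pipeline reruns are byte-identical for the same seed", {
  set.seed(101)
  seqs <- lapply(1:3, function(k) rna_seq(random_rna(40), id = paste0("s", k)))
  d1 <- tempfile(); d2 <- tempfile()
  o1 <- run_pipeline(seqs, mode = "dinuc", count = 15, seed = 8)
  o2 <- run_pipeline(seqs, mode = "dinuc", count = 15, seed = 8)
  write_results(o1$results, o1$table, d1)
  write_results(o2$results, o2$table, d2)
  expect_identical(readLines(file.path(d1, "results.tsv")),
                   readLines(file.path(d2, "results.tsv")))
  expect_identical(readLines(file.path(d1, "summary.tsv")),
                   readLines(file.path(d2, "summary.tsv")))
})

test_that("invalid FASTA records are skipped with a reason, not fatal", {
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">good", "GGGAAACCCC", ">bad", "ACGNNACGU"), tf)
  out <- run_pipeline(tf, mode = "mono", count = 10, seed = 2)
  expect_identical(out$results$flag, c("ok", "invalid"))
  tf2 <- tempfile(fileext = ".fa")
  writeLines(c(">bad", "NNNN"), tf2)
  expect_error(run_pipeline(tf2, mode = "mono", count = 10, seed = 2),
               "all input sequences are invalid")
})
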