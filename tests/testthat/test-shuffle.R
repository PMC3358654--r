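test_that("mono shuffle preserves nucleotide counts exactly", {
  x <- rna_seq(paste(c(rep("A", 20), rep("C", 10), rep("G", 10),
                       rep("U", 10)), collapse = ""), id = "comp")
  ss <- mono_shuffle(x, count = 100, seed = 2)
  ref <- count_bases(x$seq)
  for (s in ss$members) expect_identical(count_bases(s), ref)

  expect_identical(unique(mono_shuffle("AAAA", count = 10, seed = 1)$members),
                   "AAAA")
  for (s in mono_shuffle("ACGU", count = 100, seed = 3)$members)
    expect_identical(as.vector(count_bases(s)), rep(1L, 4))
})

test_that("dinucleotide shuffle preserves dinucleotide counts and endpoints", {
  set.seed(23)
  fixtures <- c("GGGAAACCCUUU", "ACGUACGUACGUGGCC",
                replicate(5, random_rna(50)))
  for (f in fixtures) {
    ss <- dinucleotide_shuffle(f, count = 200, seed = 7)
    ref <- count_dinucs(f)
    n <- nchar(f)
    for (s in ss$members) {
      expect_identical(count_dinucs(s), ref)
      expect_identical(substr(s, 1, 1), substr(f, 1, 1))
      expect_identical(substr(s, n, n), substr(f, n, n))
    }
  }
  expect_error(dinucleotide_shuffle("A", count = 1), "n >= 2")
})

test_that("dinucleotide shuffle is degenerate only when forced", {
  # "ACAC" is the unique sequence with dinucleotides {AC, CA, AC}
  expect_identical(unique(dinucleotide_shuffle("ACAC", count = 50,
                                               seed = 1)$members), "ACAC")
  # homopolymer-block input: every transition is forced, the only Euler
  # path is the sequence itself
  expect_identical(unique(dinucleotide_shuffle("GGGAAACCCUUU", count = 100,
                                               seed = 7)$members),
                   "GGGAAACCCUUU")
  # branching transition graph: many Euler paths, members must differ
  ss <- dinucleotide_shuffle("GAUCGAUGGAUCCGAU", count = 100, seed = 7)
  expect_gte(length(unique(ss$members)), 2L)
})

test_that("shuffles are deterministic in (x, count, seed, mode)", {
  for (f in c(mono_shuffle, dinucleotide_shuffle)) {
    a <- f("GGGAAACCCUUU", count = 20, seed = 11)
    b <- f("GGGAAACCCUUU", count = 20, seed = 11)
    expect_identical(a$members, b$members)
  }
})

test_that("mono shuffle is uniform over distinct permutations", {
  draws <- mono_shuffle("ACGUACGU", count = 10000, seed = 13)$members
  tab <- table(draws)
  n_perm <- factorial(8) / 2^4            # 2520 distinct permutations
  p <- 1 / n_perm
  se <- sqrt(10000 * p * (1 - p))
  # observed cells
  expect_true(all(abs(tab - 10000 * p) <= 5 * se))
  # unseen cells: expected count ~4, absence is within 5 se too
  expect_lte(10000 * p, 5 * se)
})

test_that("external backgrounds sample length-matched segments", {
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">bg1", strrep("ACGU", 25)), tf)       # length 100
  target <- rna_seq(random_rna(40), id = "t")
  ss <- load_background(tf, target, count = 50, seed = 3)
  expect_true(all(nchar(ss$members) == 40))
  expect_identical(ss$mode, "external")
  expect_identical(load_background(tf, target, count = 50, seed = 3)$members,
                   ss$members)

  # the only possible segment is the sequence itself
  tf2 <- tempfile(fileext = ".fa")
  writeLines(c(">bg", "GGGAAACCC"), tf2)
  one <- load_background(tf2, rna_seq("UUUUUUUUU"), count = 1, seed = 1)
  expect_identical(one$members, "GGGAAACCC")

  # everywhere too short
  expect_error(load_background(tf2, rna_seq(strrep("A", 50)), count = 1),
               "long enough")
})
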