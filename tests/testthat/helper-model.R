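# Shared fixtures: solving the rule probabilities is cheap but building the
# model once keeps the suite tidy.
default_model <- triple_model()
fix_model <- fixture_model()

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Random valid emission model (positive pair probabilities).
random_emissions <- function() {
  u <- stats::runif(4, 0.05, 1); u <- u / sum(u)
  q <- stats::runif(6, 0.02, 1); q <- q / sum(q)
  emission_model(unpaired = stats::setNames(u, c("A", "C", "G", "U")),
                 paired = stats::setNames(q, c("GC", "CG", "AU", "UA",
                                               "GU", "UG")))
}

count_bases <- function(s) table(factor(strsplit(s, "")[[1]],
                                        levels = c("A", "C", "G", "U")))

count_dinucs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  table(factor(paste0(ch[-n], ch[-1]),
               levels = as.vector(outer(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U"), paste0))))
}
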