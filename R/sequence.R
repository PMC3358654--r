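BASES <- c("A", "C", "G", "U")

#' Construct a validated RNA sequence
#'
#' Normalizes a nucleotide string to RNA: upper-cases it and maps T to U.
#' Any other symbol (IUPAC wildcards, gaps, ...) makes the sequence invalid;
#' such sequences are rejected here and skipped (with a reason) by the
#' pipeline, matching the usual cleaning step of removing wildcard-containing
#' records before entropy scoring.
#'
#' @param seq single character string of nucleotides (case-insensitive,
#'   T and U both accepted).
#' @param id sequence identifier.
#' @return An object of class `rna_seq`: a list with elements `id`, `seq`
#'   (normalized ACGU string), and `n` (length).
#' @examples
#' rna_seq("acgt")$seq   # "ACGU"
#' @export
rna_seq <- function(seq, id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("t", "u", toupper(seq))
  s <- chartr("T", "U", s)
  if (nchar(s) < 1L) stop("sequence '", id, "' is empty")
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1L]]), BASES)
  if (length(bad) > 0L) {
    stop("sequence '", id, "' contains non-ACGU symbol(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(id = id, seq = s, n = nchar(s)), class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat("<rna_seq> ", x$id, " (n = ", x$n, ")\n", sep = "")
  cat(if (x$n > 60) paste0(substr(x$seq, 1, 60), "...") else x$seq, "\n")
  invisible(x)
}

# Coerce strings / Biostrings records to rna_seq where needed.
as_rna_seq <- function(x, id = "seq") {
  if (inherits(x, "rna_seq")) return(x)
  rna_seq(as.character(x), id = id)
}

# 0-based integer coding (A=0, C=1, G=2, U=3) for the C++ kernels.
seq_codes <- function(x) {
  x <- as_rna_seq(x)
  match(strsplit(x$seq, "", fixed = TRUE)[[1L]], BASES) - 1L
}
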