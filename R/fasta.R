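#' Read a FASTA file of RNA/DNA sequences
#'
#' Parses standard (multi-line, case-insensitive) FASTA via Biostrings and
#' normalizes each record to RNA (T mapped to U). Records containing any
#' other symbol are returned flagged invalid with the offending symbols,
#' so callers can log and skip them — the conventional cleaning step of
#' dropping wildcard-containing sequences before scoring.
#'
#' @param path FASTA file.
#' @return A list of records, each a list with `id`, `seq` (normalized ACGU
#'   string, or the raw string when invalid), `valid` (logical), and
#'   `reason` (NA or the offending symbols).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) warning("FASTA file '", path, "' contains no records")
  recs <- vector("list", length(set))
  ids <- sub("\\s.*$", "", names(set))
  for (k in seq_along(set)) {
    raw <- as.character(set[[k]])
    s <- chartr("T", "U", toupper(raw))
    bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1L]]), BASES)
    recs[[k]] <- if (length(bad) == 0 && nchar(s) > 0) {
      list(id = ids[k], seq = s, valid = TRUE, reason = NA_character_)
    } else {
      list(id = ids[k], seq = s, valid = FALSE,
           reason = if (nchar(s) == 0) "empty" else paste(bad, collapse = ","))
    }
  }
  recs
}

#' Keep only valid records, as rna_seq objects
#'
#' @param recs output of [read_fasta()].
#' @return list of [rna_seq()].
#' @export
valid_sequences <- function(recs) {
  lapply(Filter(function(r) r$valid, recs),
         function(r) rna_seq(r$seq, id = r$id))
}

#' Write sequences to FASTA
#'
#' @param seqs a named character vector, a list of [rna_seq()], or a
#'   `shuffle_set` (members named `sourceid.shuffle.k`).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "shuffle_set")) {
    v <- seqs$members
    names(v) <- paste0(seqs$source_id, ".shuffle.", seq_along(v))
    seqs <- v
  } else if (is.list(seqs)) {
    v <- vapply(seqs, function(s) as_rna_seq(s)$seq, character(1))
    names(v) <- vapply(seqs, function(s) as_rna_seq(s)$id, character(1))
    seqs <- v
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}
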