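new_shuffle_set <- function(source_id, mode, members, seed) {
  structure(list(source_id = source_id, mode = mode, members = members,
                 seed = seed),
            class = "shuffle_set")
}

#' @export
print.shuffle_set <- function(x, ...) {
  cat(sprintf("<shuffle_set> %s  mode=%s  members=%d  seed=%s\n",
              x$source_id, x$mode, length(x$members),
              if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' Mononucleotide shuffle
#'
#' Each member is a uniformly random permutation of the residues of `x`, so
#' single-nucleotide counts are preserved exactly.
#'
#' @param x an [rna_seq()] (or string).
#' @param count number of shuffles (default 100, the standard background
#'   size).
#' @param seed integer seed; identical inputs give identical output.
#' @return A `shuffle_set` with `mode = "mono"`; members are plain ACGU
#'   strings.
#' @export
mono_shuffle <- function(x, count = 100L, seed = NULL) {
  x <- as_rna_seq(x)
  stopifnot(count >= 1L)
  chars <- strsplit(x$seq, "", fixed = TRUE)[[1L]]
  members <- with_seed(seed, vapply(
    seq_len(count),
    function(i) paste(sample(chars), collapse = ""),
    character(1)))
  new_shuffle_set(x$id, "mono", members, seed)
}

#' Dinucleotide shuffle (Euler-path construction)
#'
#' Each member preserves the exact multiset of ordered adjacent
#' dinucleotides of `x` — hence also the mononucleotide counts and the first
#' and last residues. Sampling uses the Altschul-Erickson construction:
#' residues are vertices of a multigraph whose edges are the adjacent pairs;
#' a random in-tree toward the final residue designates each vertex's last
#' outgoing edge, the remaining edges are permuted, and the Eulerian walk
#' from the first residue spells the shuffled sequence.
#'
#' @inheritParams mono_shuffle
#' @return A `shuffle_set` with `mode = "dinuc"`.
#' @export
dinucleotide_shuffle <- function(x, count = 100L, seed = NULL) {
  x <- as_rna_seq(x)
  stopifnot(count >= 1L)
  if (x$n < 2L) stop("dinucleotide shuffle requires n >= 2")
  chars <- strsplit(x$seq, "", fixed = TRUE)[[1L]]
  members <- with_seed(seed, vapply(
    seq_len(count),
    function(i) paste(dinuc_shuffle_once(chars), collapse = ""),
    character(1)))
  new_shuffle_set(x$id, "dinuc", members, seed)
}

# One Altschul-Erickson draw. `chars` is the residue vector (length >= 2).
dinuc_shuffle_once <- function(chars) {
  n <- length(chars)
  verts <- unique(chars)
  from <- match(chars[-n], verts)
  to <- match(chars[-1], verts)
  first <- match(chars[1], verts)
  last <- match(chars[n], verts)
  out <- split(to, factor(from, levels = seq_along(verts)))

  active <- which(lengths(out) > 0 & seq_along(verts) != last)
  repeat {
    # designate one random last edge per non-terminal vertex
    last_edge <- rep(NA_integer_, length(verts))
    for (v in active) last_edge[v] <- out[[v]][sample.int(length(out[[v]]), 1L)]
    # accept iff following designated edges from every vertex reaches `last`
    ok <- TRUE
    for (v in active) {
      cur <- v
      for (step in seq_along(verts)) {
        cur <- last_edge[cur]
        if (is.na(cur) || cur == last) break
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }

  ordered <- vector("list", length(verts))
  for (v in seq_along(verts)) {
    edges <- out[[v]]
    if (length(edges) == 0) next
    if (!is.na(last_edge[v])) {
      pos <- which(edges == last_edge[v])[1L]
      edges <- c(sample_vec(edges[-pos]), edges[pos])
    } else {
      edges <- sample_vec(edges)
    }
    ordered[[v]] <- edges
  }

  next_idx <- rep(1L, length(verts))
  walk <- integer(n)
  walk[1] <- first
  cur <- first
  for (t in 2:n) {
    e <- ordered[[cur]][next_idx[cur]]
    next_idx[cur] <- next_idx[cur] + 1L
    walk[t] <- e
    cur <- e
  }
  verts[walk]
}

# sample() misbehaves on length-1 numeric input; this permutes verbatim.
sample_vec <- function(v) {
  if (length(v) <= 1L) return(v)
  v[sample.int(length(v))]
}

#' Length-matched background segments from a genome-style FASTA
#'
#' Draws `count` segments of exactly the target's length, uniformly over all
#' eligible (record, start position) pairs of the background set — the
#' "genome background" alternative to shuffling.
#'
#' @param path FASTA file of background sequences (records with non-ACGU
#'   symbols are skipped).
#' @param target the sequence being scored (fixes the segment length).
#' @param count number of segments.
#' @param seed integer seed.
#' @return A `shuffle_set` with `mode = "external"`.
#' @export
load_background <- function(path, target, count = 100L, seed = NULL) {
  target <- as_rna_seq(target)
  stopifnot(count >= 1L)
  recs <- Filter(function(r) r$valid, read_fasta(path))
  lens <- vapply(recs, function(r) nchar(r$seq), integer(1))
  slots <- pmax(lens - target$n + 1L, 0L)
  if (sum(slots) == 0L)
    stop("no background sequence is long enough for a segment of length ",
         target$n)
  members <- with_seed(seed, vapply(seq_len(count), function(i) {
    r <- sample.int(length(recs), 1L, prob = slots)
    s <- sample.int(slots[r], 1L)
    substr(recs[[r]]$seq, s, s + target$n - 1L)
  }, character(1)))
  new_shuffle_set(target$id, "external", members, seed)
}
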