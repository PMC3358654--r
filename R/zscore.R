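#' Entropy Z-score against a background
#'
#' Z = (mu - Q_x) / sigma, where mu and sigma are the sample mean and sample
#' (n-1 denominator) standard deviation of the background entropies. A
#' sequence whose entropy is *lower* than its background — i.e. one that
#' folds with more certainty than its shuffles — gets a *positive* Z.
#'
#' @param Q_x entropy of the real sequence.
#' @param background numeric vector (>= 2) of background entropies.
#' @return A list of class `zscore_result`: `Q_x`, `mu`, `sigma`, `Z`,
#'   `background_size`.
#' @examples
#' zscore(1.0, c(2.0, 3.0, 4.0))$Z   # 2
#' @export
zscore <- function(Q_x, background) {
  stopifnot(is.numeric(Q_x), length(Q_x) == 1L)
  if (length(background) < 2L)
    stop("Z-score needs a background of at least 2 entropies")
  mu <- mean(background)
  sigma <- stats::sd(background)
  if (sigma == 0)
    stop("background entropies have zero standard deviation; Z undefined")
  structure(list(Q_x = Q_x, mu = mu, sigma = sigma, Z = (mu - Q_x) / sigma,
                 background_size = length(background)),
            class = "zscore_result")
}

#' Kolmogorov-Smirnov normality check of background entropies
#'
#' Tests the background entropies against a normal distribution with the
#' sample's own mean and standard deviation. With estimated parameters the
#' p-value is approximate (conservative); it is used only as the usual
#' sanity check that a Z-score is a meaningful summary of the background.
#' Failing to reject at 95% confidence corresponds to p >= 0.05.
#'
#' @param background numeric vector of >= 5 entropies with positive spread.
#' @return The KS p-value.
#' @export
ks_normality <- function(background) {
  if (length(background) < 5L)
    stop("KS normality check needs at least 5 background values")
  s <- stats::sd(background)
  if (!is.finite(s) || s == 0)
    stop("background is (numerically) constant; normality check undefined")
  suppressWarnings(
    stats::ks.test(background, "pnorm", mean(background), s)$p.value)
}

#' Percentage of sequences at or above Z-score thresholds
#'
#' For each threshold t, reports 100 * #\{Z >= t\} / #results — the
#' comparison is inclusive (greater than or equal). Sequences with an
#' undefined Z (NA) are excluded from both numerator and denominator.
#'
#' @param results a data.frame with a `Z` column (e.g. from
#'   [run_pipeline()]), a list of `zscore_result`s, or a numeric vector of
#'   Z values.
#' @param thresholds decreasing numeric vector (default `c(2, 1.5, 1, 0.5)`).
#' @return A data.frame of class `threshold_table` with columns `threshold`
#'   and `percent`.
#' @export
threshold_table <- function(results, thresholds = c(2, 1.5, 1, 0.5)) {
  if (length(thresholds) == 0) stop("no thresholds given")
  z <- if (is.data.frame(results)) results$Z
       else if (is.numeric(results)) results
       else vapply(results, function(r) r$Z, numeric(1))
  if (length(z) == 0) stop("no results given")
  z <- z[!is.na(z)]
  if (length(z) == 0) stop("all Z-scores are undefined")
  pct <- vapply(thresholds, function(t) 100 * mean(z >= t), numeric(1))
  structure(data.frame(threshold = thresholds, percent = pct),
            class = c("threshold_table", "data.frame"))
}

#' Score a FASTA file: entropies, Z-scores and the threshold summary
#'
#' For each valid sequence, builds a background (mono- or di-nucleotide
#' shuffles, or length-matched segments from an external FASTA), computes
#' the base-pairing entropy of the sequence and of every background member,
#' and emits the Z-score together with a KS normality p-value of the
#' background. Invalid records (non-ACGU symbols) are reported in the result
#' with `flag = "invalid"` and skipped. Backgrounds with zero entropy spread
#' (e.g. a poly-A sequence, where nothing can pair) yield `Z = NA` and
#' `flag = "sigma_zero"`. Each sequence's background stream is derived from
#' `(seed, id)`, so results do not depend on processing order.
#'
#' @param fasta path to a FASTA file, or a list of [rna_seq()] objects.
#' @param mode background type: `"dinuc"` (default), `"mono"`, or
#'   `"external"`.
#' @param background FASTA path of background sequences (required for
#'   `mode = "external"`).
#' @param count background size per sequence (default 100).
#' @param seed integer seed for all shuffling/sampling.
#' @param thresholds Z thresholds for the summary table.
#' @param model scoring model (default [triple_model()]).
#' @param verbose log per-sequence progress to stderr.
#' @return A list with `results` (data.frame: id, n, Q, mu, sigma, Z, ks_p,
#'   flag) and `table` (a [threshold_table()]).
#' @export
run_pipeline <- function(fasta, mode = c("dinuc", "mono", "external"),
                         background = NULL, count = 100L, seed = 1L,
                         thresholds = c(2, 1.5, 1, 0.5),
                         model = triple_model(), verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "external" && is.null(background))
    stop("mode = 'external' requires a background FASTA")

  if (is.character(fasta)) {
    recs <- read_fasta(fasta)
  } else {
    recs <- lapply(fasta, function(s) {
      s <- as_rna_seq(s)
      list(id = s$id, seq = s$seq, valid = TRUE, reason = NA_character_)
    })
  }
  if (length(recs) == 0) stop("no sequences in input")

  rows <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    if (!r$valid) {
      if (verbose)
        message("[", k, "/", length(recs), "] ", r$id,
                ": skipped (", r$reason, ")")
      rows[[k]] <- data.frame(id = r$id, n = nchar(r$seq), Q = NA_real_,
                              mu = NA_real_, sigma = NA_real_, Z = NA_real_,
                              ks_p = NA_real_, flag = "invalid")
      next
    }
    x <- rna_seq(r$seq, id = r$id)
    sseed <- derive_seed(seed, x$id)
    bg <- switch(mode,
      mono = mono_shuffle(x, count = count, seed = sseed),
      dinuc = dinucleotide_shuffle(x, count = count, seed = sseed),
      external = load_background(background, x, count = count, seed = sseed))
    Q_x <- base_pairing_entropy(x, model)$Q
    Q_bg <- vapply(bg$members,
                   function(s) base_pairing_entropy(s, model)$Q,
                   numeric(1), USE.NAMES = FALSE)
    ks_p <- if (stats::sd(Q_bg) > 0 && length(Q_bg) >= 5)
      ks_normality(Q_bg) else NA_real_
    row <- if (stats::sd(Q_bg) == 0) {
      data.frame(id = x$id, n = x$n, Q = Q_x, mu = mean(Q_bg), sigma = 0,
                 Z = NA_real_, ks_p = ks_p, flag = "sigma_zero")
    } else {
      zs <- zscore(Q_x, Q_bg)
      data.frame(id = x$id, n = x$n, Q = Q_x, mu = zs$mu, sigma = zs$sigma,
                 Z = zs$Z, ks_p = ks_p, flag = "ok")
    }
    if (verbose)
      message("[", k, "/", length(recs), "] ", x$id, ": Q = ",
              format(Q_x, digits = 6), ", Z = ", format(row$Z, digits = 4))
    rows[[k]] <- row
  }
  results <- do.call(rbind, rows)
  if (all(results$flag == "invalid"))
    stop("all input sequences are invalid; nothing to score")
  list(results = results, table = threshold_table(results, thresholds))
}

#' Write pipeline outputs as TSV files
#'
#' `results.tsv` holds one row per sequence (entropies to 6 decimals, Z to
#' 4); `summary.tsv` holds the threshold table (percentages to 2 decimals).
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param rows the `results` data.frame from [run_pipeline()].
#' @param table the [threshold_table()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(rows, table, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x, d) ifelse(is.na(x), "NA", sprintf(paste0("%.", d, "f"), x))
  rfile <- file.path(outdir, "results.tsv")
  out <- data.frame(id = rows$id, n = rows$n, Q = fmt(rows$Q, 6),
                    mu = fmt(rows$mu, 6), sigma = fmt(rows$sigma, 6),
                    Z = fmt(rows$Z, 4), ks_p = fmt(rows$ks_p, 4),
                    flag = rows$flag)
  utils::write.table(out, rfile, sep = "\t", quote = FALSE, row.names = FALSE)
  sfile <- file.path(outdir, "summary.tsv")
  stab <- data.frame(threshold = table$threshold,
                     percent = fmt(table$percent, 2))
  utils::write.table(stab, sfile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(results = rfile, summary = sfile))
}
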