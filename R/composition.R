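RNA_BASES <- c("A", "C", "G", "U")

.seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)

#' Nucleotide content of a sequence set
#'
#' Pooled fractions (total occurrences of each base over total length of
#' the set) and per-sequence fraction vectors, plus GC fraction. The pooled
#' numbers are the ones quoted as set-level percentages; the per-sequence
#' vectors feed the two-sample tests.
#'
#' @param sequences character vector of RNA sequences (or a
#'   `mirna_catalogue`, whose `sequence` column is used).
#' @return list with `pooled` (named fractions, sums to 1), `per_sequence`
#'   (matrix, one row per sequence, rows sum to 1), `gc` (pooled G+C),
#'   `total_length`.
#' @export
base_fractions <- function(sequences) {
  if (inherits(sequences, "mirna_catalogue")) sequences <- sequences$sequence
  if (length(sequences) == 0) stop("empty sequence set", call. = FALSE)
  chars <- .seq_chars(sequences)
  per <- t(vapply(chars, function(x) {
    tab <- table(factor(x, levels = RNA_BASES))
    as.numeric(tab) / length(x)
  }, numeric(4)))
  colnames(per) <- RNA_BASES
  lens <- nchar(sequences)
  pooled_counts <- colSums(per * lens)
  pooled <- pooled_counts / sum(lens)
  list(pooled = pooled, per_sequence = per,
       gc = unname(pooled["G"] + pooled["C"]),
       total_length = sum(lens))
}

#' Homopolymer run counts
#'
#' Counts maximal runs of identical nucleotides of length at least
#' `min_len`, per base. Maximal-run semantics: a stretch of ten U counts
#' once at every `min_len` it reaches, not once per window.
#'
#' @param sequence one RNA sequence.
#' @param min_len minimum run length (>= 2).
#' @return named integer vector over A, C, G, U.
#' @export
homopolymer_runs <- function(sequence, min_len = 2) {
  stopifnot(min_len >= 2)
  x <- .seq_chars(sequence)[[1]]
  r <- rle(x)
  keep <- r$lengths >= min_len
  tab <- table(factor(r$values[keep], levels = RNA_BASES))
  stats::setNames(as.integer(tab), RNA_BASES)
}

#' Homopolymer run table for a sequence set
#'
#' @param sequences character vector or `mirna_catalogue`.
#' @param min_lens run-length thresholds (default 2, 3, 4).
#' @return data.frame: one row per sequence x threshold, columns `min_len`
#'   and per-base run counts.
#' @export
homopolymer_table <- function(sequences, min_lens = c(2, 3, 4)) {
  if (inherits(sequences, "mirna_catalogue")) sequences <- sequences$sequence
  rows <- lapply(min_lens, function(L) {
    counts <- t(vapply(sequences, homopolymer_runs, integer(4), min_len = L))
    data.frame(sequence = sequences, min_len = L, counts,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximal homopolymer run length per base
#' @param sequence one RNA sequence.
#' @return named integer vector over A, C, G, U: longest run of each base.
#' @export
max_run_lengths <- function(sequence) {
  x <- .seq_chars(sequence)[[1]]
  r <- rle(x)
  out <- stats::setNames(integer(4), RNA_BASES)
  for (b in RNA_BASES) {
    w <- r$lengths[r$values == b]
    out[b] <- if (length(w)) max(w) else 0L
  }
  out
}

#' Two-sample t-test on per-sequence statistics
#'
#' Thin wrapper with the degenerate case pinned down: when both groups
#' have zero variance and equal means, p = 1 rather than an error.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param variant `"welch"` (unequal variances, default) or `"pooled"`.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Compare nucleotide composition between two sequence sets
#'
#' Per base: Welch (or pooled) t-test on per-sequence fractions, with the
#' pooled-fraction difference reported alongside, and BH adjustment across
#' the four bases.
#'
#' @param set_a,set_b character vectors or `mirna_catalogue`s.
#' @param variant t-test variant, see [two_sample_ttest()].
#' @return data.frame: `base`, `pooled_a`, `pooled_b`, `delta`
#'   (pooled_a - pooled_b), `mean_a`, `mean_b`, `t`, `df`, `p`, `q`.
#' @export
composition_compare <- function(set_a, set_b, variant = "welch") {
  fa <- base_fractions(set_a)
  fb <- base_fractions(set_b)
  rows <- lapply(RNA_BASES, function(b) {
    tt <- two_sample_ttest(fa$per_sequence[, b], fb$per_sequence[, b],
                           variant = variant)
    data.frame(base = b,
               pooled_a = unname(fa$pooled[b]),
               pooled_b = unname(fb$pooled[b]),
               delta = unname(fa$pooled[b] - fb$pooled[b]),
               mean_a = mean(fa$per_sequence[, b]),
               mean_b = mean(fb$per_sequence[, b]),
               t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}
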