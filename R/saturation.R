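#' Subsample a count column without replacement
#'
#' Draws `round(fraction * N)` reads without replacement from the read
#' multiset implied by a count vector (multivariate hypergeometric,
#' realized by chained hypergeometric draws). Uses the current RNG state;
#' seed control lives in [saturation_curve()].
#'
#' @param column named numeric vector of per-miRNA counts.
#' @param fraction sampling fraction in (0, 1].
#' @return named integer vector of subsampled counts (same names/order),
#'   summing to `round(fraction * sum(column))`.
#' @export
subsample_reads <- function(column, fraction) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  k <- as.integer(round(column))
  total <- sum(k)
  draw <- as.integer(round(fraction * total))
  if (draw >= total) return(stats::setNames(k, names(column)))
  out <- integer(length(k))
  remaining <- total
  left <- draw
  for (i in seq_along(k)) {
    if (left == 0L) break
    remaining <- remaining - k[i]
    # reads of miRNA i are "white balls" among the reads not yet considered
    x <- stats::rhyper(1, k[i], remaining, left)
    out[i] <- x
    left <- left - x
  }
  stats::setNames(out, names(column))
}

#' Rarefaction/saturation curve of distinct miRNAs
#'
#' For each sampling fraction, counts the miRNAs with at least one read in
#' a without-replacement subsample, averaged over repeats. In nested mode
#' (default) each repeat draws its largest subsample first and derives the
#' smaller fractions by subsampling it, so every repeat's curve is
#' non-decreasing by construction. Detection in a subsample means >= 1
#' read; presence thresholds apply to full data only.
#'
#' @param column named numeric vector of per-miRNA counts.
#' @param fractions ordered fractions in (0, 1] (default 1%..100%).
#' @param repeats number of Monte-Carlo repeats (default 10).
#' @param seed RNG seed (required: curves are deterministic given seed).
#' @param nested nest subsamples across fractions within a repeat.
#' @return a `saturation_curve` data.frame: `fraction`, `mean_distinct`,
#'   `sd_distinct`; attribute `per_repeat` holds the repeats x fractions
#'   matrix.
#' @export
saturation_curve <- function(column, fractions = seq(0.01, 1, by = 0.01),
                             repeats = 10, seed, nested = TRUE) {
  if (sum(column) <= 0) stop("column total must be positive", call. = FALSE)
  fractions <- sort(fractions)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  withr::with_seed(seed, {
    per <- matrix(NA_real_, nrow = repeats, ncol = length(fractions))
    total <- sum(round(column))
    for (r in seq_len(repeats)) {
      if (nested) {
        cur <- column
        cur_frac <- 1
        for (j in rev(seq_along(fractions))) {
          f <- fractions[j]
          if (f < 1 || cur_frac < 1) {
            # draw size is always relative to the full column so nested
            # draws hit round(f * total) exactly
            target <- round(f * total)
            cur <- subsample_reads(cur, min(1, target / sum(cur)))
          }
          per[r, j] <- sum(cur > 0)
          cur_frac <- f
        }
      } else {
        for (j in seq_along(fractions)) {
          per[r, j] <- sum(subsample_reads(column, fractions[j]) > 0)
        }
      }
    }
    out <- data.frame(fraction = fractions,
                      mean_distinct = colMeans(per),
                      sd_distinct = apply(per, 2, stats::sd))
    attr(out, "per_repeat") <- per
    class(out) <- c("saturation_curve", "data.frame")
    out
  })
}

#' Write a saturation curve as TSV
#' @param curve a `saturation_curve`.
#' @param path output file path.
#' @export
write_saturation_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
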