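#' Reads per million (CPM)
#'
#' Cell-wise `k_ij / N_j * 1e6`. When library sizes equal column sums the
#' columns of the result sum to one million.
#'
#' @param cm a `count_matrix`.
#' @return numeric matrix of reads per million.
#' @export
cpm <- function(cm) {
  if (any(cm$lib_sizes <= 0)) stop("zero library size", call. = FALSE)
  sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6
}

#' Reads per kilobase per million (RPKM)
#'
#' `k_ij / (N_j / 1e6) / (L_i / 1e3)`: depth- and length-normalized
#' abundance.
#'
#' @param cm a `count_matrix`.
#' @param lengths named vector of feature lengths in nt, covering every row.
#' @return numeric matrix.
#' @export
rpkm <- function(cm, lengths) {
  ids <- rownames(cm$counts)
  L <- lengths[ids]
  if (anyNA(L)) {
    stop("missing length for id: ", ids[which(is.na(L))[1]], call. = FALSE)
  }
  if (any(L <= 0)) stop("lengths must be positive", call. = FALSE)
  cpm(cm) / (L / 1e3)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over features (restricted to rows with a
#' positive geometric mean across samples) of `k_ij / geomean_i`; factors
#' are then rescaled so their geometric mean is one. When no row is
#' positive in all samples, the geometric mean is taken over the positive
#' subset of each remaining row (documented fallback).
#'
#' @param cm a `count_matrix`.
#' @return named numeric vector of size factors, geometric mean 1.
#' @export
size_factors <- function(cm) {
  k <- cm$counts
  all_pos <- rowSums(k > 0) == ncol(k)
  if (any(all_pos)) {
    sub <- k[all_pos, , drop = FALSE]
    logg <- rowMeans(log(sub))
    ratios <- exp(sweep(log(sub), 1, logg, "-"))
  } else {
    any_pos <- rowSums(k > 0) > 0
    if (!any(any_pos)) stop("no positive counts; size factors undefined",
                            call. = FALSE)
    sub <- k[any_pos, , drop = FALSE]
    logg <- apply(sub, 1, function(r) mean(log(r[r > 0])))
    ratios <- sweep(sub, 1, exp(logg), "/")
    ratios[sub == 0] <- NA
  }
  s <- apply(ratios, 2, stats::median, na.rm = TRUE)
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(k))
}

#' Variance-stabilizing transform (shifted log)
#'
#' `log2(k_ij / s_j + 1)`: a monotone transform of size-factor-normalized
#' counts used before correlation analysis. Unlike a dispersion-fitted
#' transform, it requires no mean-dispersion model; it anchors zero counts
#' at zero and is strictly monotone in `k` for fixed `s`.
#'
#' @param cm a `count_matrix`.
#' @param s optional size factors (computed via [size_factors()] if absent).
#' @return numeric matrix of stabilized values.
#' @export
vst <- function(cm, s = NULL) {
  if (is.null(s)) s <- size_factors(cm)
  log2(sweep(cm$counts, 2, s[colnames(cm$counts)], "/") + 1)
}

#' Pearson correlation between two samples on stabilized values
#'
#' @param stabilized matrix (e.g. from [vst()]).
#' @param pair two column labels.
#' @return list with `r`, `r_squared`, `n`; `r` is `NA` when either vector
#'   has zero variance.
#' @export
platform_correlation <- function(stabilized, pair) {
  stopifnot(length(pair) == 2, all(pair %in% colnames(stabilized)))
  x <- stabilized[, pair[1]]; y <- stabilized[, pair[2]]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 shared rows", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, n = length(x)))
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2, n = length(x))
}

#' Fold change between two normalized abundances
#'
#' `num / den`; a zero denominator (or both zero) yields `NA`, rendered as
#' `"N.A."` by [format_fold()]. Vectorized.
#'
#' @param num,den reads-per-million values.
#' @return numeric vector (NA where undefined).
#' @export
fold_change <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Format fold changes as printed in differential tables
#' @param fc numeric fold changes.
#' @param digits significant figures (default 4).
#' @return character vector; `"N.A."` for undefined values.
#' @export
format_fold <- function(fc, digits = 4) {
  vapply(fc, function(x) {
    if (is.na(x)) "N.A."
    else format(signif(x, digits), trim = TRUE, scientific = FALSE)
  }, character(1))
}

#' Two-proportion z-test with continuity correction (vectorized)
#'
#' Tests whether a feature's share of library 1 differs from its share of
#' library 2: `z = (p1 - p2 -/+ cc) / sqrt(p(1-p)(1/N1 + 1/N2))` with
#' pooled `p` and continuity correction `cc = (1/N1 + 1/N2)/2` shrinking
#' the difference toward zero. Signed z; two-tailed normal p.
#'
#' @param k1,k2 counts in each library.
#' @param n1,n2 library totals.
#' @return list of vectors `z`, `p`.
#' @export
two_prop_ztest <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  cc <- 0.5 * (1 / n1 + 1 / n2)
  d <- p1 - p2
  dcc <- sign(d) * pmax(abs(d) - cc, 0)
  z <- ifelse(se == 0, 0, dcc / se)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' Cross-platform differential-representation table
#'
#' For one cell line (two columns: the low- and high-throughput platform
#' libraries of the same sample), tests each miRNA's proportion of the two
#' libraries with the two-proportion z-test, BH-adjusts across miRNAs, and
#' reports reads/million, fold change (larger/smaller by default, or a
#' fixed direction), direction of enrichment, and the IQR outlier flag on
#' the absolute cross-platform difference of stabilized values.
#'
#' @param cm a `count_matrix` containing the two columns.
#' @param low,high column labels of the low- and high-throughput libraries.
#' @param alpha significance level for the `direction` call (on q).
#' @return data.frame: `id`, `count_low`, `count_high`, `rpm_low`,
#'   `rpm_high`, `fold_change` (high/low or low/high, whichever >= 1; NA if
#'   undefined), `z`, `p_value`, `q_value`, `direction`, `outlier`.
#' @export
differential_table <- function(cm, low, high, alpha = 0.05) {
  stopifnot(all(c(low, high) %in% colnames(cm$counts)))
  k1 <- cm$counts[, high]; k2 <- cm$counts[, low]
  n1 <- cm$lib_sizes[high]; n2 <- cm$lib_sizes[low]
  rpm <- cpm(cm)
  rpm_low <- rpm[, low]; rpm_high <- rpm[, high]
  zt <- two_prop_ztest(k1, n1, k2, n2)
  q <- bh_adjust(zt$p)
  hi <- pmax(rpm_low, rpm_high); lo <- pmin(rpm_low, rpm_high)
  fc <- fold_change(hi, lo)
  direction <- rep("none", length(k1))
  direction[q <= alpha & zt$z > 0] <- "high-enriched"
  direction[q <= alpha & zt$z < 0] <- "low-enriched"
  sub <- count_matrix(cm$counts[, c(low, high), drop = FALSE],
                      lib_sizes = cm$lib_sizes[c(low, high)])
  v <- vst(sub)
  diffs <- abs(v[, high] - v[, low])
  out_fl <- if (length(diffs) >= 4) iqr_outliers(diffs)$flags
            else rep(FALSE, length(diffs))
  data.frame(id = rownames(cm$counts),
             count_low = k2, count_high = k1,
             rpm_low = rpm_low, rpm_high = rpm_high,
             fold_change = fc, z = zt$z, p_value = zt$p, q_value = q,
             direction = direction, outlier = out_fl,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Interquartile-range outlier rule
#'
#' Flags values strictly greater than `Q3 + 1.5 * IQR`, with quartiles by
#' linear interpolation (`stats::quantile` type 7). Needs at least four
#' values.
#'
#' @param x numeric vector (e.g. per-miRNA normalized cross-platform
#'   differences).
#' @return list with `flags` (logical) and `rule` (Q1, Q3, IQR, threshold).
#' @export
iqr_outliers <- function(x) {
  if (length(x) < 4) stop("need at least 4 values for the IQR rule",
                          call. = FALSE)
  qs <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  thr <- qs[2] + 1.5 * iqr
  list(flags = x > thr,
       rule = list(q1 = qs[1], q3 = qs[2], iqr = iqr, threshold = thr))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment across a family of p-values.
#'
#' @param p numeric vector in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
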