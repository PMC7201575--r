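#' Read-assignment policy
#'
#' Reads are assigned to catalogue sequences under a seed-and-mismatch rule:
#' the first `seed_length` nucleotides must match exactly (no seed
#' mismatches by default) and the full overlap, aligned at position 1 with
#' no gaps or shifting, may contain at most `max_mismatches` mismatches.
#' Reads extending past the mature 3' end by more than `max_overhang`
#' nucleotides (untrimmed adapter remnant) are left unassigned.
#'
#' @param seed_length exact-match prefix length in nt.
#' @param max_mismatches mismatch budget over the read/mature overlap.
#' @param seed_mismatches mismatches tolerated inside the seed.
#' @param max_overhang tolerated 3' overhang of the read past the mature end.
#' @return a `mapping_policy` list.
#' @export
mapping_policy <- function(seed_length = 18L, max_mismatches = 1L,
                           seed_mismatches = 0L, max_overhang = 4L) {
  stopifnot(seed_length >= 1, max_mismatches >= seed_mismatches,
            seed_mismatches >= 0, max_overhang >= 0)
  structure(list(seed_length = as.integer(seed_length),
                 max_mismatches = as.integer(max_mismatches),
                 seed_mismatches = as.integer(seed_mismatches),
                 max_overhang = as.integer(max_overhang)),
            class = "mapping_policy")
}

# hamming distance between equal-length strings, by raw byte comparison
.hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

#' Assign one read to a catalogue entry
#'
#' A catalogue entry matches iff its first `seed_length` nt equal the read's
#' first `seed_length` nt exactly and the positional comparison over
#' `min(len_read, len_mature)` has at most `max_mismatches` mismatches.
#' Among multiple matches the fewest-mismatch entry wins; residual ties are
#' broken by the lexicographically smallest miRNA id and flagged ambiguous.
#'
#' @param read read sequence (canonical RNA).
#' @param catalogue a `mirna_catalogue`.
#' @param policy a `mapping_policy`.
#' @return list with `read`, `mirna_id` (or `NA`), `mismatches`,
#'   `ambiguous`, `reason` (`"assigned"`, `"too-short"`, `"no-match"`,
#'   `"overhang"`).
#' @export
assign_read <- function(read, catalogue, policy = mapping_policy()) {
  res <- list(read = read, mirna_id = NA_character_,
              mismatches = NA_integer_, ambiguous = FALSE,
              reason = "no-match")
  n <- nchar(read)
  if (n < policy$seed_length) {
    res$reason <- "too-short"
    return(res)
  }
  read_seed <- substr(read, 1L, policy$seed_length)
  cand <- which(substr(catalogue$sequence, 1L, policy$seed_length) ==
                  read_seed & catalogue$length >= policy$seed_length)
  if (length(cand) == 0) return(res)
  over <- n - catalogue$length[cand]
  keep <- over <= policy$max_overhang
  if (!any(keep)) {
    res$reason <- "overhang"
    return(res)
  }
  cand <- cand[keep]
  mm <- vapply(cand, function(i) {
    L <- min(n, catalogue$length[i])
    .hamming(substr(read, 1L, L), substr(catalogue$sequence[i], 1L, L))
  }, numeric(1))
  ok <- mm <= policy$max_mismatches
  if (!any(ok)) return(res)
  cand <- cand[ok]; mm <- mm[ok]
  best <- mm == min(mm)
  ids <- sort(catalogue$id[cand][best])
  res$mirna_id <- ids[1]
  res$mismatches <- as.integer(min(mm))
  res$ambiguous <- length(ids) > 1
  res$reason <- "assigned"
  res
}

#' Count catalogue assignments of a collapsed read set
#'
#' Produces a one-column count matrix over catalogue ids: per-miRNA count is
#' the sum of multiplicities of reads assigned to it. The column library
#' size is the total of assigned reads; unassigned and ambiguous totals are
#' attached as attributes so multiplicity is conserved.
#'
#' @param reads a `collapsed_read_set`.
#' @param catalogue a `mirna_catalogue`.
#' @param policy a `mapping_policy`.
#' @param keep_ambiguous count ambiguous reads at their tie-broken id
#'   (default) instead of discarding them.
#' @return a `count_matrix` (one column, named by the platform label), with
#'   attributes `unassigned` and `ambiguous_discarded`.
#' @export
count_assignments <- function(reads, catalogue, policy = mapping_policy(),
                              keep_ambiguous = TRUE) {
  stopifnot(inherits(reads, "collapsed_read_set"), nrow(catalogue) > 0)
  counts <- stats::setNames(numeric(nrow(catalogue)), catalogue$id)
  unassigned <- 0
  ambiguous_discarded <- 0
  for (k in seq_along(reads$entries)) {
    seqk <- names(reads$entries)[k]
    mult <- reads$entries[[k]]
    a <- assign_read(seqk, catalogue, policy)
    if (a$reason != "assigned") {
      unassigned <- unassigned + mult
    } else if (a$ambiguous && !keep_ambiguous) {
      ambiguous_discarded <- ambiguous_discarded + mult
    } else {
      counts[a$mirna_id] <- counts[a$mirna_id] + mult
    }
  }
  lab <- if (is.na(reads$platform_label)) "sample" else reads$platform_label
  m <- matrix(counts, ncol = 1, dimnames = list(names(counts), lab))
  assigned_total <- sum(counts)
  cm <- count_matrix(m, lib_sizes = stats::setNames(max(assigned_total, 1), lab))
  attr(cm, "unassigned") <- unassigned
  attr(cm, "ambiguous_discarded") <- ambiguous_discarded
  cm
}

#' Throughput correction coefficient
#'
#' Ratio of total valid reads between the high- and low-throughput
#' platforms, and its rounded form used to scale presence thresholds.
#'
#' @param total_low,total_high total valid reads on each platform.
#' @return list with `ratio` (high/low) and integer `coefficient`
#'   (nearest-integer rounding).
#' @export
throughput_coefficient <- function(total_low, total_high) {
  if (total_low <= 0 || total_high <= 0)
    stop("read totals must be positive", call. = FALSE)
  ratio <- total_high / total_low
  list(ratio = ratio, coefficient = as.integer(round(ratio)))
}

#' Presence thresholds scaled by throughput
#'
#' A miRNA is considered detected on the low-throughput platform with at
#' least `low_min` reads, and on the high-throughput platform with at least
#' `low_min * coefficient` reads (default 2 and 8 at a 4x throughput
#' difference).
#'
#' @param low_min minimum reads on the low-throughput platform.
#' @param coefficient rounded throughput ratio (see
#'   [throughput_coefficient()]).
#' @return a `presence_thresholds` list with `low_min`, `coefficient`,
#'   `high_min`.
#' @export
presence_thresholds <- function(low_min = 2L, coefficient = 4L) {
  stopifnot(low_min >= 1, coefficient > 0)
  structure(list(low_min = as.integer(low_min),
                 coefficient = coefficient,
                 high_min = as.integer(round(low_min * coefficient))),
            class = "presence_thresholds")
}

#' Apply throughput-corrected presence thresholds
#'
#' @param cm a `count_matrix`.
#' @param thresholds a `presence_thresholds`.
#' @param roles named character vector mapping each sample label to
#'   `"low"` or `"high"` (throughput role).
#' @return list with `presence` (logical matrix, same dims as counts),
#'   `detected` (list of id vectors per sample), and the input `cm`.
#' @export
apply_presence_filter <- function(cm, thresholds, roles) {
  samples <- colnames(cm$counts)
  roles <- roles[samples]
  if (anyNA(roles) || !all(roles %in% c("low", "high")))
    stop("every sample must be labelled 'low' or 'high' throughput",
         call. = FALSE)
  mins <- ifelse(roles == "low", thresholds$low_min, thresholds$high_min)
  presence <- sweep(cm$counts, 2, mins, `>=`)
  detected <- lapply(samples, function(s) rownames(cm$counts)[presence[, s]])
  names(detected) <- samples
  list(presence = presence, detected = detected, counts = cm)
}

#' Venn-style detection sets for a platform pair
#'
#' @param presence logical presence matrix from [apply_presence_filter()].
#' @param pair two sample labels.
#' @return list with `both`, `only_1`, `only_2`, `union` id vectors.
#' @export
presence_venn <- function(presence, pair) {
  stopifnot(length(pair) == 2, all(pair %in% colnames(presence)))
  a <- presence[, pair[1]]; b <- presence[, pair[2]]
  ids <- rownames(presence)
  list(both = ids[a & b], only_1 = ids[a & !b], only_2 = ids[!a & b],
       union = ids[a | b])
}
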