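.sw_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                           baseOnly = FALSE)
}

# distances of many candidate sequences against one subject, one vectorized
# Smith-Waterman call; same semantics as pair_mismatch_distance()
.mismatch_distances <- function(seqs, subject) {
  if (length(seqs) == 0) return(numeric(0))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(chartr("U", "T", seqs)),
    chartr("U", "T", subject),
    type = "local", substitutionMatrix = .sw_submat(),
    gapOpening = 10, gapExtension = 0.5)
  ind <- Biostrings::nindel(aln)
  gaps <- Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  span <- Biostrings::nchar(aln)
  minlen <- pmin(nchar(seqs), nchar(subject))
  # positions of the shorter sequence trimmed by the local alignment count
  # as differences, so an end mismatch trimmed away is not free
  d <- as.numeric(Biostrings::nmismatch(aln)) + (minlen - span)
  d[gaps > 0 | span < minlen - 1] <- Inf
  d[seqs == subject] <- 0
  d
}

#' Mismatch distance between two mature sequences
#'
#' Smith-Waterman local alignment (match +5, mismatch -4, gap open/extend
#' 10/0.5) between two mature sequences. Returns the number of mismatching
#' columns in the optimal local alignment, plus any positions of the
#' shorter sequence the alignment trims (an end mismatch trimmed by the
#' aligner still counts), when the alignment is gap-free and spans at
#' least `min(len_a, len_b) - 1` positions; otherwise `Inf` (the pair is
#' not clusterable). The near-identity relation used for clustering is
#' `distance <= 1`.
#'
#' @param a,b sequences (character).
#' @return mismatch count (numeric), or `Inf`.
#' @export
pair_mismatch_distance <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  stopifnot(nzchar(a), nzchar(b))
  if (a == b) return(0)
  .mismatch_distances(a, b)
}

#' Cluster near-identical mature miRNAs
#'
#' Single-linkage transitive closure over the "no or a single mismatch"
#' relation ([pair_mismatch_distance()] `<= 1`): if A~B and B~C, then
#' {A,B,C} form one cluster even when A and C differ by two. The result is
#' a partition of the catalogue; singletons are their own cluster. The
#' representative is the lexicographically smallest member id and the
#' cluster label concatenates member ids with "/".
#'
#' @param catalogue a `mirna_catalogue`.
#' @param max_mismatch near-identity threshold (default 1).
#' @return data.frame with one row per cluster: `cluster_id`,
#'   `representative`, `members` ("/"-joined), `member_count`; plus
#'   attribute `membership`, a named vector mapping each catalogue id to
#'   its `cluster_id`.
#' @export
build_clusters <- function(catalogue, max_mismatch = 1) {
  n <- nrow(catalogue)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      js <- seq(i + 1, n)
      d <- .mismatch_distances(catalogue$sequence[js], catalogue$sequence[i])
      for (j in js[d <= max_mismatch]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(catalogue$id, root)
  reps <- vapply(groups, function(g) min(g), character(1))
  ord <- order(reps)
  groups <- groups[ord]; reps <- reps[ord]
  out <- data.frame(
    cluster_id = reps,
    representative = reps,
    members = vapply(groups, function(g) paste(sort(g), collapse = "/"),
                     character(1)),
    member_count = lengths(groups),
    stringsAsFactors = FALSE, row.names = NULL)
  membership <- stats::setNames(rep(out$cluster_id, out$member_count),
                                unlist(lapply(groups, sort)))
  attr(out, "membership") <- membership
  out
}

#' Aggregate counts over miRNA clusters
#'
#' Cluster count = sum of member counts per sample; library sizes are
#' unchanged. Column sums are conserved.
#'
#' @param cm a `count_matrix` over catalogue ids.
#' @param clusters output of [build_clusters()].
#' @return a `count_matrix` over cluster ids.
#' @export
aggregate_cluster_counts <- function(cm, clusters) {
  membership <- attr(clusters, "membership")
  ids <- rownames(cm$counts)
  missing <- setdiff(ids, names(membership))
  if (length(missing) > 0)
    stop("count rows absent from every cluster: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  grp <- membership[ids]
  agg <- rowsum(cm$counts, group = grp, reorder = TRUE)
  count_matrix(agg, lib_sizes = cm$lib_sizes)
}

#' Write a cluster map as TSV
#' @param clusters output of [build_clusters()].
#' @param path output file path.
#' @export
write_cluster_map <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
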