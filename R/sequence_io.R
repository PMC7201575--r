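#' Canonicalize a nucleotide string to the RNA alphabet
#'
#' The package works internally in the RNA alphabet {A, C, G, U}. Input is
#' uppercased; with `alphabet_policy = "dna-to-rna"` any `T` is transliterated
#' to `U` at the boundary so downstream code never sees mixed alphabets.
#'
#' @param x character vector of sequences.
#' @param alphabet_policy `"rna"` (reject `T`) or `"dna-to-rna"`
#'   (transliterate `T` to `U`).
#' @param what label used in error messages (e.g. a record id).
#' @return uppercase RNA character vector.
#' @export
canonicalize_rna <- function(x, alphabet_policy = c("rna", "dna-to-rna"),
                             what = NULL) {
  alphabet_policy <- match.arg(alphabet_policy)
  x <- toupper(x)
  if (alphabet_policy == "dna-to-rna") x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    lab <- if (is.null(what)) which(bad)[1] else what[bad][1]
    stop("sequence contains residues outside {A,C,G,U}",
         if (alphabet_policy == "rna") " (use alphabet_policy = \"dna-to-rna\" for DNA input)",
         ": record ", lab, call. = FALSE)
  }
  x
}

#' Construct a mature-miRNA catalogue
#'
#' A catalogue is a `data.frame` with columns `id`, `sequence`, `length`,
#' one row per mature sequence, ids unique, sequences canonical RNA. It is
#' the unit all counting, composition and graph statistics attach to.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of sequences (canonicalized on entry).
#' @param alphabet_policy see [canonicalize_rna()].
#' @return a `mirna_catalogue` data.frame.
#' @export
mirna_catalogue <- function(id, sequence, alphabet_policy = "dna-to-rna") {
  stopifnot(length(id) == length(sequence))
  id <- as.character(id)
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0)
    stop("duplicate catalogue id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  sequence <- canonicalize_rna(as.character(sequence), alphabet_policy,
                               what = id)
  out <- data.frame(id = id, sequence = sequence, length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("mirna_catalogue", "data.frame")
  out
}

#' Read a mature-miRNA catalogue from FASTA
#'
#' Reads a miRBase-mature style FASTA file. The record id is the first
#' whitespace-delimited token of the header. Lowercase residues are accepted
#' and uppercased; with the default policy, DNA (`T`) is transliterated to
#' RNA (`U`).
#'
#' @param path FASTA file path.
#' @param alphabet_policy see [canonicalize_rna()].
#' @return a `mirna_catalogue` data.frame.
#' @export
read_mirna_fasta <- function(path, alphabet_policy = "dna-to-rna") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  mirna_catalogue(ids, as.character(set), alphabet_policy = alphabet_policy)
}

#' Write a catalogue to FASTA
#' @param catalogue a `mirna_catalogue`.
#' @param path output file path.
#' @export
write_mirna_fasta <- function(catalogue, path) {
  set <- Biostrings::BStringSet(catalogue$sequence)
  names(set) <- catalogue$id
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Collapse raw reads into distinct sequences with multiplicities
#'
#' @param raw character vector of read sequences (already trimmed).
#' @param platform_label sample/platform tag carried through the pipeline.
#' @return a `collapsed_read_set`: list with `entries` (named integer vector,
#'   names = distinct sequences, sorted for order independence),
#'   `platform_label`, and `total_reads`.
#' @export
collapse_reads <- function(raw, platform_label = NA_character_) {
  if (length(raw) > 0 && any(!nzchar(raw)))
    stop("empty read sequence in input", call. = FALSE)
  if (length(raw) == 0) {
    entries <- stats::setNames(integer(0), character(0))
  } else {
    tab <- table(raw)
    entries <- stats::setNames(as.integer(tab), names(tab))
    entries <- entries[order(names(entries))]
  }
  structure(list(entries = entries,
                 platform_label = platform_label,
                 total_reads = sum(entries)),
            class = "collapsed_read_set")
}

#' @export
print.collapsed_read_set <- function(x, ...) {
  cat("collapsed_read_set:", length(x$entries), "distinct sequences,",
      x$total_reads, "reads",
      if (!is.na(x$platform_label)) paste0("[", x$platform_label, "]"), "\n")
  invisible(x)
}

#' Read collapsed reads from a count-annotated FASTA
#'
#' Headers follow the `id-count` convention used by small-RNA collapsers
#' (e.g. `>r1-17` means 17 copies). The multiplicity pattern is configurable.
#'
#' @param path FASTA file path.
#' @param platform_label platform tag.
#' @param count_pattern regex whose first capture group is the multiplicity.
#' @param alphabet_policy see [canonicalize_rna()].
#' @return a `collapsed_read_set`.
#' @export
read_collapsed_fasta <- function(path, platform_label = NA_character_,
                                 count_pattern = "-([0-9]+)$",
                                 alphabet_policy = "dna-to-rna") {
  set <- Biostrings::readBStringSet(path)
  m <- regmatches(names(set), regexec(count_pattern, names(set)))
  counts <- vapply(m, function(g) {
    if (length(g) < 2) NA_integer_ else as.integer(g[2])
  }, integer(1))
  if (anyNA(counts))
    stop("header without '", count_pattern, "' multiplicity: ",
         names(set)[which(is.na(counts))[1]], call. = FALSE)
  seqs <- canonicalize_rna(as.character(set), alphabet_policy)
  entries <- tapply(counts, seqs, sum)
  entries <- stats::setNames(as.integer(entries), names(entries))
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, platform_label = platform_label,
                 total_reads = sum(entries)),
            class = "collapsed_read_set")
}

#' Write collapsed reads as a count-annotated FASTA
#' @param crs a `collapsed_read_set`.
#' @param path output file path.
#' @param prefix read id prefix; headers are `<prefix><i>-<count>`.
#' @export
write_collapsed_fasta <- function(crs, path, prefix = "r") {
  set <- Biostrings::BStringSet(names(crs$entries))
  names(set) <- sprintf("%s%d-%d", prefix, seq_along(crs$entries),
                        as.integer(crs$entries))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}
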