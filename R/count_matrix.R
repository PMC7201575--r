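#' Construct a count matrix with per-sample library sizes
#'
#' The container for raw or normalized counts: a numeric matrix with miRNA
#' (or cluster) ids as rownames and sample labels as colnames, plus
#' per-sample library sizes. Library sizes default to column sums; supplying
#' them externally (e.g. total valid reads including unassigned) is allowed
#' as long as each is at least the corresponding column sum.
#'
#' @param counts numeric matrix, non-negative, with dimnames.
#' @param lib_sizes optional named numeric vector of library sizes.
#' @param raw if `TRUE`, warn when cells are non-integer (raw-count intake).
#' @return a `count_matrix`: list with `counts`, `lib_sizes`.
#' @export
count_matrix <- function(counts, lib_sizes = NULL, raw = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row and column names", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (raw && any(counts != round(counts)))
    warning("non-integer cells in matrix declared as raw counts")
  cs <- colSums(counts)
  if (is.null(lib_sizes)) {
    lib_sizes <- cs
  } else {
    lib_sizes <- lib_sizes[colnames(counts)]
    if (anyNA(lib_sizes))
      stop("lib_sizes must be named for every sample", call. = FALSE)
    if (any(lib_sizes < cs - 1e-8))
      stop("library size smaller than column sum", call. = FALSE)
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive", call. = FALSE)
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("library sizes:",
      paste(sprintf("%s=%g", colnames(x$counts), x$lib_sizes),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a TSV count table
#'
#' Tab-separated, UTF-8, `#` comment lines allowed, header row of sample
#' labels, first column miRNA ids. Cells may be decimal (e.g. reads/million
#' fixtures); use `raw = TRUE` to warn on non-integers when ingesting raw
#' counts.
#'
#' @param path TSV file path.
#' @param lib_sizes optional named library sizes overriding column sums.
#' @param raw declare the table as raw counts (integer check).
#' @return a `count_matrix`.
#' @export
read_count_table <- function(path, lib_sizes = NULL, raw = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 2) stop("count table needs a header and data rows",
                              call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  samples <- fields[[1]][-1]
  rows <- fields[-1]
  bad <- which(lengths(rows) != ncols)
  if (length(bad) > 0)
    stop("ragged row ", bad[1] + 1, " in ", path, call. = FALSE)
  ids <- vapply(rows, `[`, character(1), 1)
  cells <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    v
  }, numeric(ncols - 1)))
  if (ncols == 2) cells <- matrix(cells, ncol = 1)
  if (anyNA(cells)) {
    idx <- which(is.na(cells), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at row '", ids[idx[1]], "', column '",
         samples[idx[2]], "'", call. = FALSE)
  }
  if (any(cells < 0)) {
    idx <- which(cells < 0, arr.ind = TRUE)[1, ]
    stop("negative cell at row '", ids[idx[1]], "', column '",
         samples[idx[2]], "'", call. = FALSE)
  }
  dimnames(cells) <- list(ids, samples)
  count_matrix(cells, lib_sizes = lib_sizes, raw = raw)
}

#' Write a count matrix as TSV
#' @param cm a `count_matrix`.
#' @param path output file path.
#' @param digits significant digits for non-integer cells.
#' @export
write_count_table <- function(cm, path, digits = 10) {
  m <- cm$counts
  df <- data.frame(id = rownames(m),
                   signif(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
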