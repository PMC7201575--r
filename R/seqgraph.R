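#' Nucleotide-adjacency graph of one sequence
#'
#' Nodes are the four nucleotides; every adjacent pair `s[i] s[i+1]`
#' increments the weight of the directed edge `s[i] -> s[i+1]`. The total
#' directed weight therefore equals `length - 1`. The undirected graph is
#' derived: weight of {x,y} (x != y) is the sum of both directions; a
#' self-pair {x,x} keeps the self-loop weight.
#'
#' @param s one RNA sequence (character) of length >= 2, or a single-row
#'   catalogue entry.
#' @return a `seq_graph`: 4x4 numeric matrix (rows = from, cols = to).
#' @export
sequence_graph <- function(s) {
  s <- toupper(as.character(s))
  if (nchar(s) < 2) stop("sequence must have length >= 2", call. = FALSE)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  from <- factor(x[-length(x)], levels = RNA_BASES)
  to <- factor(x[-1], levels = RNA_BASES)
  m <- table(from, to)
  g <- matrix(as.numeric(m), 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  class(g) <- c("seq_graph", class(g))
  g
}

#' Undirected edge weights of a sequence graph
#' @param g a `seq_graph`.
#' @return symmetric 4x4 matrix; off-diagonal {x,y} = x->y + y->x,
#'   diagonal = self-loop weight.
#' @export
undirected_edges <- function(g) {
  u <- unclass(g) + t(unclass(g))
  diag(u) <- diag(unclass(g))
  u
}

#' Twelve-group weighted degree vector
#'
#' For each nucleotide x: `x_in` = total weight of edges into x, `x_out` =
#' total weight out of x, `x_both` = in + out (a self-loop therefore
#' contributes twice to the undirected degree; set
#' `self_loop_both = "once"` to count it once). Degrees are weighted sums,
#' not distinct-edge counts.
#'
#' @param g a `seq_graph`.
#' @param self_loop_both `"twice"` (default) or `"once"`.
#' @return named numeric vector of length 12: `a_in`, `a_out`, `a_both`,
#'   ..., `u_both`.
#' @export
degree_vector <- function(g, self_loop_both = c("twice", "once")) {
  self_loop_both <- match.arg(self_loop_both)
  m <- unclass(g)
  deg_in <- colSums(m)
  deg_out <- rowSums(m)
  both <- deg_in + deg_out
  if (self_loop_both == "once") both <- both - diag(m)
  out <- numeric(12)
  nm <- character(12)
  for (i in seq_along(RNA_BASES)) {
    b <- tolower(RNA_BASES[i])
    idx <- (i - 1) * 3
    out[idx + 1:3] <- c(deg_in[i], deg_out[i], both[i])
    nm[idx + 1:3] <- paste0(b, c("_in", "_out", "_both"))
  }
  stats::setNames(out, nm)
}

#' Degree vectors for a set of sequences
#'
#' @param sequences character vector or `mirna_catalogue`.
#' @param normalize_length divide each vector by (length - 1); off by
#'   default (raw degrees).
#' @param self_loop_both see [degree_vector()].
#' @return matrix, one row per sequence, 12 degree-group columns.
#' @export
degree_matrix <- function(sequences, normalize_length = FALSE,
                          self_loop_both = "twice") {
  if (inherits(sequences, "mirna_catalogue")) sequences <- sequences$sequence
  m <- t(vapply(sequences,
                function(s) degree_vector(sequence_graph(s),
                                          self_loop_both = self_loop_both),
                numeric(12)))
  rownames(m) <- NULL
  if (normalize_length) m <- m / (nchar(sequences) - 1)
  m
}

#' Aggregate ("overplot") graph of a sequence set
#'
#' Edge-wise sum of the member graphs; min and max edge weights are
#' attached for rendering scales.
#'
#' @param sequences character vector or `mirna_catalogue` (non-empty).
#' @return a `seq_graph` with attributes `min_weight`, `max_weight`, `n`.
#' @export
aggregate_graph <- function(sequences) {
  if (inherits(sequences, "mirna_catalogue")) sequences <- sequences$sequence
  if (length(sequences) == 0) stop("empty sequence set", call. = FALSE)
  g <- Reduce(`+`, lapply(sequences, function(s) unclass(sequence_graph(s))))
  class(g) <- c("seq_graph", class(g))
  attr(g, "min_weight") <- min(g)
  attr(g, "max_weight") <- max(g)
  attr(g, "n") <- length(sequences)
  g
}

#' Z-tests on the twelve degree groups between two sequence sets
#'
#' Per degree group, an unpaired two-sample z-test with unequal variances:
#' `z = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)`, two-tailed normal
#' p, BH-adjusted across the twelve groups. Zero pooled variance gives
#' p = 1 for that group.
#'
#' @param set_a,set_b sequence sets (character vectors, catalogues, or
#'   precomputed degree matrices from [degree_matrix()]).
#' @param normalize_length see [degree_matrix()].
#' @return data.frame: `group`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b`, `z`, `p`, `q`.
#' @export
degree_ztest <- function(set_a, set_b, normalize_length = FALSE) {
  da <- if (is.matrix(set_a)) set_a else degree_matrix(set_a, normalize_length)
  db <- if (is.matrix(set_b)) set_b else degree_matrix(set_b, normalize_length)
  stopifnot(nrow(da) >= 2, nrow(db) >= 2, ncol(da) == 12, ncol(db) == 12)
  groups <- colnames(da)
  rows <- lapply(groups, function(gp) {
    xa <- da[, gp]; xb <- db[, gp]
    va <- stats::var(xa); vb <- stats::var(xb)
    se <- sqrt(va / length(xa) + vb / length(xb))
    if (se == 0) {
      z <- 0; p <- 1
    } else {
      z <- (mean(xa) - mean(xb)) / se
      p <- 2 * stats::pnorm(-abs(z))
    }
    data.frame(group = gp, mean_a = mean(xa), sd_a = stats::sd(xa),
               n_a = length(xa), mean_b = mean(xb), sd_b = stats::sd(xb),
               n_b = length(xb), z = z, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Export a sequence graph as Graphviz DOT
#'
#' @param g a `seq_graph`.
#' @param path output file path.
#' @param directed write a digraph (default) or the undirected graph.
#' @return the path, invisibly.
#' @export
write_dot <- function(g, path, directed = TRUE) {
  m <- if (directed) unclass(g) else undirected_edges(g)
  arrow <- if (directed) "->" else "--"
  lines <- c(if (directed) "digraph adjacency {" else "graph adjacency {",
             paste0("  ", tolower(RNA_BASES), ";"))
  for (i in 1:4) {
    js <- if (directed) 1:4 else i:4
    for (j in js) {
      if (m[i, j] > 0)
        lines <- c(lines, sprintf("  %s %s %s [weight=%g, label=%g];",
                                  tolower(RNA_BASES[i]), arrow,
                                  tolower(RNA_BASES[j]), m[i, j], m[i, j]))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
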