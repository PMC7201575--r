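# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

random_rna <- function(n, lens = 18:25) {
  if (length(lens) == 1) lens <- rep(lens, 2)
  vapply(sample(lens, n, replace = TRUE), function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1))
}

# direct per-position mismatch count via character vectors
oracle_mismatches <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  L <- min(length(x), length(y))
  sum(x[seq_len(L)] != y[seq_len(L)])
}

# enumerate every catalogue entry and apply the stated rules directly
oracle_assign <- function(read, catalogue, seed_len = 18, max_mm = 1,
                          max_overhang = 4) {
  n <- nchar(read)
  if (n < seed_len) return(list(id = NA_character_, mm = NA, amb = FALSE))
  hits <- list()
  for (i in seq_len(nrow(catalogue))) {
    mat <- catalogue$sequence[i]
    if (nchar(mat) < seed_len) next
    if (substr(read, 1, seed_len) != substr(mat, 1, seed_len)) next
    if (n - nchar(mat) > max_overhang) next
    mm <- oracle_mismatches(read, mat)
    if (mm <= max_mm) hits[[length(hits) + 1]] <- list(id = catalogue$id[i],
                                                       mm = mm)
  }
  if (length(hits) == 0) return(list(id = NA_character_, mm = NA, amb = FALSE))
  mms <- vapply(hits, `[[`, numeric(1), "mm")
  ids <- vapply(hits, `[[`, character(1), "id")
  best <- ids[mms == min(mms)]
  list(id = sort(best)[1], mm = min(mms), amb = length(best) > 1)
}

# all-pairs Hamming relation + transitive closure by BFS (equal lengths)
oracle_hamming_clusters <- function(seqs) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- i != j &&
      nchar(seqs[i]) == nchar(seqs[j]) &&
      oracle_mismatches(seqs[i], seqs[j]) <= 1
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# type-7 quantile by the textbook interpolation formula
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# BH step-up computed from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# maximal homopolymer runs via regex
oracle_runs <- function(s, base, min_len) {
  hits <- gregexpr(paste0(base, "{", min_len, ",}"), s)[[1]]
  if (hits[1] == -1) 0L else length(hits)
}
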