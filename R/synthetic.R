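#' Configuration of the two-platform synthetic study
#'
#' Defaults emulate the study design the pipeline targets: ~500 mature
#' miRNAs of 18-25 nt, log-normal true abundances (log10 mean 1.5, sd 1),
#' two platforms sequencing the same material with a ~4x throughput
#' difference (2e6 vs 8e6 reads), negative-binomial overdispersion 0.1,
#' and an optional composition-dependent capture bias: planted miRNAs
#' carrying a uracil run (>= 4 nt) are inflated on the low-throughput
#' platform "P" by `exp(bias_beta_u)`, and adenine-run miRNAs on the
#' high-throughput platform "S" by `exp(bias_beta_a)`. Two cell lines are
#' simulated as abundance vectors correlated at 0.95 in log space.
#'
#' @param n_mirnas catalogue size.
#' @param length_range min/max mature length (nt).
#' @param abundance_mu,abundance_sigma log10-normal abundance parameters.
#' @param library_sizes named per-platform read totals (names "P", "S").
#' @param dispersion negative-binomial overdispersion; 0 gives pure
#'   multinomial sampling (analytic-check mode).
#' @param bias_beta_u log-fold capture multiplier on platform P for planted
#'   U-run miRNAs.
#' @param bias_beta_a log-fold capture multiplier on platform S for planted
#'   A-run miRNAs.
#' @param n_planted number of planted miRNAs per bias type.
#' @param u_run_frac,a_run_frac catalogue fractions built to carry a U-run
#'   (A-run) of at least 4 nt.
#' @param n_cell_lines 1 or 2.
#' @param cell_line_cor abundance correlation between cell lines (log
#'   space).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_mirnas = 500, length_range = c(18, 25),
                             abundance_mu = 1.5, abundance_sigma = 1.0,
                             library_sizes = c(P = 2e6, S = 8e6),
                             dispersion = 0.1,
                             bias_beta_u = 0, bias_beta_a = 0,
                             n_planted = 10,
                             u_run_frac = 0.2, a_run_frac = 0.2,
                             n_cell_lines = 2, cell_line_cor = 0.95) {
  stopifnot(n_mirnas >= 1, length_range[1] >= 6,
            length_range[2] >= length_range[1],
            all(library_sizes > 0), dispersion >= 0,
            n_planted >= 0, u_run_frac >= 0, a_run_frac >= 0,
            u_run_frac + a_run_frac <= 1,
            n_cell_lines %in% c(1, 2),
            cell_line_cor >= -1, cell_line_cor <= 1)
  structure(list(n_mirnas = n_mirnas, length_range = length_range,
                 abundance_mu = abundance_mu,
                 abundance_sigma = abundance_sigma,
                 library_sizes = library_sizes, dispersion = dispersion,
                 bias_beta_u = bias_beta_u, bias_beta_a = bias_beta_a,
                 n_planted = n_planted, u_run_frac = u_run_frac,
                 a_run_frac = a_run_frac, n_cell_lines = n_cell_lines,
                 cell_line_cor = cell_line_cor),
            class = "synthetic_config")
}

.random_seqs <- function(n, length_range) {
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(RNA_BASES, L, replace = TRUE), collapse = ""),
    character(1))
}

.plant_run <- function(s, base, min_run = 4, max_run = 8) {
  L <- nchar(s)
  run <- sample(seq(min_run, max_run), 1)
  run <- min(run, L - 2)
  start <- sample(seq(2, L - run), 1)
  paste0(substr(s, 1, start - 1),
         strrep(base, run),
         substr(s, start + run, L))
}

#' Generate a synthetic mature-miRNA catalogue
#'
#' Random sequences in the configured length range, with sub-populations
#' enriched for uracil runs (>= 4 nt) and adenine runs. Composition
#' annotations (maximal run length per base, run flags) are attached as
#' extra columns.
#'
#' @param config a `synthetic_config`.
#' @param seed RNG seed; same seed, same catalogue.
#' @return a `mirna_catalogue` with extra columns `max_run_a`, `max_run_c`,
#'   `max_run_g`, `max_run_u`, `has_u_run`, `has_a_run`.
#' @export
make_catalogue <- function(config, seed) {
  withr::with_seed(seed, {
    n <- config$n_mirnas
    seqs <- .random_seqs(n, config$length_range)
    n_u <- round(config$u_run_frac * n)
    n_a <- round(config$a_run_frac * n)
    pool <- sample(n)
    u_idx <- pool[seq_len(n_u)]
    a_idx <- pool[n_u + seq_len(n_a)]
    for (i in u_idx) seqs[i] <- .plant_run(seqs[i], "U")
    for (i in a_idx) seqs[i] <- .plant_run(seqs[i], "A")
    # de-duplicate the rare collision so ids map to distinct molecules
    while (anyDuplicated(seqs)) {
      d <- which(duplicated(seqs))
      seqs[d] <- vapply(seqs[d], function(s) {
        pos <- sample(nchar(s), 1)
        substr(s, pos, pos) <- sample(RNA_BASES, 1)
        s
      }, character(1))
    }
    cat <- mirna_catalogue(sprintf("syn-mir-%04d", seq_len(n)), seqs)
    runs <- t(vapply(cat$sequence, max_run_lengths, integer(4)))
    cat$max_run_a <- runs[, "A"]; cat$max_run_c <- runs[, "C"]
    cat$max_run_g <- runs[, "G"]; cat$max_run_u <- runs[, "U"]
    cat$has_u_run <- cat$max_run_u >= 4
    cat$has_a_run <- cat$max_run_a >= 4
    cat
  })
}

#' Simulate two-platform counts with known ground truth
#'
#' True abundances are log10-normal; each platform's capture probability is
#' the abundance times a composition-dependent bias multiplier,
#' renormalized over the catalogue (inflating one miRNA deflates the
#' others, as in real library-prep bias). Counts are multinomial at
#' dispersion 0, otherwise negative binomial with `size = 1/dispersion`
#' around the expected counts. Planted-bias miRNAs are drawn from the
#' U-run (A-run) sub-populations and receive multiplier
#' `exp(bias_beta_u)` on platform P (`exp(bias_beta_a)` on platform S).
#'
#' @param catalogue output of [make_catalogue()].
#' @param config a `synthetic_config`.
#' @param seed RNG seed; fully determines the output.
#' @return list with `counts` (a `count_matrix`, columns
#'   `<platform>_cl<i>`), `truth` (data.frame: id, per-cell-line abundance,
#'   bias multipliers, planted flags), and `planted_u`, `planted_a` id
#'   vectors.
#' @export
simulate_counts <- function(catalogue, config, seed) {
  withr::with_seed(seed, {
    n <- nrow(catalogue)
    mu <- config$abundance_mu; sg <- config$abundance_sigma
    ltheta1 <- stats::rnorm(n, mu, sg)
    rho <- config$cell_line_cor
    lthetas <- list(ltheta1)
    if (config$n_cell_lines == 2) {
      lthetas[[2]] <- mu + rho * (ltheta1 - mu) +
        sqrt(1 - rho^2) * stats::rnorm(n, 0, sg)
    }
    planted_u <- character(0); planted_a <- character(0)
    if (config$n_planted > 0 && config$bias_beta_u != 0) {
      cand <- catalogue$id[catalogue$has_u_run]
      planted_u <- sample(cand, min(config$n_planted, length(cand)))
    }
    if (config$n_planted > 0 && config$bias_beta_a != 0) {
      cand <- setdiff(catalogue$id[catalogue$has_a_run], planted_u)
      planted_a <- sample(cand, min(config$n_planted, length(cand)))
    }
    bias_P <- ifelse(catalogue$id %in% planted_u,
                     exp(config$bias_beta_u), 1)
    bias_S <- ifelse(catalogue$id %in% planted_a,
                     exp(config$bias_beta_a), 1)
    platforms <- names(config$library_sizes)
    cols <- list(); libs <- numeric(0)
    for (cl in seq_len(config$n_cell_lines)) {
      theta <- 10^lthetas[[cl]]
      for (pf in platforms) {
        b <- if (pf == "P") bias_P else bias_S
        prob <- theta * b / sum(theta * b)
        N <- config$library_sizes[[pf]]
        k <- if (config$dispersion == 0) {
          as.numeric(stats::rmultinom(1, N, prob))
        } else {
          stats::rnbinom(n, mu = N * prob, size = 1 / config$dispersion)
        }
        lab <- sprintf("%s_cl%d", pf, cl)
        cols[[lab]] <- k
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- catalogue$id
    truth <- data.frame(id = catalogue$id,
                        log10_abundance_cl1 = lthetas[[1]],
                        bias_P = bias_P, bias_S = bias_S,
                        planted_u = catalogue$id %in% planted_u,
                        planted_a = catalogue$id %in% planted_a,
                        stringsAsFactors = FALSE)
    if (config$n_cell_lines == 2)
      truth$log10_abundance_cl2 <- lthetas[[2]]
    list(counts = count_matrix(m), truth = truth,
         planted_u = planted_u, planted_a = planted_a)
  })
}

#' Expand a count column into error-bearing reads
#'
#' Each count becomes that many copies of the mature sequence, with
#' independent per-base substitution errors at `error_rate`; the read
#' multiset total equals the column total. Exercises the mapping module
#' end-to-end.
#'
#' @param column named numeric vector of per-miRNA counts (names must be
#'   catalogue ids).
#' @param catalogue a `mirna_catalogue`.
#' @param error_rate per-base substitution probability in \[0, 0.05\].
#' @param seed RNG seed.
#' @param platform_label tag for the resulting read set.
#' @return a `collapsed_read_set`.
#' @export
emit_reads <- function(column, catalogue, error_rate = 0, seed,
                       platform_label = NA_character_) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  seqs <- stats::setNames(catalogue$sequence, catalogue$id)
  withr::with_seed(seed, {
    reads <- character(0)
    for (id in names(column)) {
      c_i <- as.integer(round(column[[id]]))
      if (c_i <= 0) next
      s <- seqs[[id]]
      L <- nchar(s)
      if (error_rate == 0) {
        reads <- c(reads, rep(s, c_i))
        next
      }
      nmut <- stats::rbinom(c_i, L, error_rate)
      base <- rep(s, c_i)
      for (r in which(nmut > 0)) {
        chars <- strsplit(base[r], "", fixed = TRUE)[[1]]
        pos <- sample(L, nmut[r])
        for (p in pos) {
          chars[p] <- sample(setdiff(RNA_BASES, chars[p]), 1)
        }
        base[r] <- paste(chars, collapse = "")
      }
      reads <- c(reads, base)
    }
    collapse_reads(reads, platform_label = platform_label)
  })
}
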