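test_that("catalogue generation is seeded and plants run sub-populations", {
  cfg <- synthetic_config(n_mirnas = 1, u_run_frac = 0, a_run_frac = 0)
  one <- make_catalogue(cfg, seed = 1)
  expect_equal(nrow(one), 1)
  expect_true(one$length >= 18 && one$length <= 25)

  cfg2 <- synthetic_config(n_mirnas = 500)
  c1 <- make_catalogue(cfg2, seed = 9)
  c2 <- make_catalogue(cfg2, seed = 9)
  expect_identical(c1, c2)
  expect_false(identical(c1, make_catalogue(cfg2, seed = 10)))

  # U-run sub-population fraction 0.2 at n = 500: at least the planted 100
  # carry a U-run of >= 4 (random background can only add carriers)
  n_u <- sum(c1$has_u_run)
  expect_gte(n_u, 100)
  # binomial band for background carriers among the other 400
  p_bg <- mean(make_catalogue(synthetic_config(n_mirnas = 400,
                                               u_run_frac = 0,
                                               a_run_frac = 0),
                              seed = 11)$has_u_run)
  upper <- 100 + 400 * p_bg + 3 * sqrt(400 * p_bg * (1 - p_bg))
  expect_lte(n_u, upper + 20)
  expect_false(anyDuplicated(c1$sequence) > 0)
})

test_that("count simulation is deterministic and unbiased at beta = 0", {
  cfg <- synthetic_config(n_mirnas = 200, dispersion = 0, n_cell_lines = 1)
  catg <- make_catalogue(cfg, seed = 2)
  s1 <- simulate_counts(catg, cfg, seed = 3)
  s2 <- simulate_counts(catg, cfg, seed = 3)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_equal(unname(colSums(s1$counts$counts)), c(2e6, 8e6))

  # cross-platform CPM ratios concentrate around 1 for well-covered miRNAs
  r <- cpm(s1$counts)
  well <- s1$counts$counts[, "P_cl1"] >= 200
  ratio <- r[well, "P_cl1"] / r[well, "S_cl1"]
  k <- s1$counts$counts[well, "P_cl1"]
  se <- sqrt(1 / k + 1 / s1$counts$counts[well, "S_cl1"])
  expect_true(mean(abs(log(ratio)) < 3 * se) > 0.97)
})

test_that("planted bias produces the configured CPM ratio", {
  cfg <- synthetic_config(n_mirnas = 300, dispersion = 0, n_cell_lines = 1,
                          bias_beta_u = log(32), n_planted = 10)
  catg <- make_catalogue(cfg, seed = 4)
  sim <- simulate_counts(catg, cfg, seed = 5)
  expect_length(sim$planted_u, 10)
  expect_true(all(sim$truth$bias_P[sim$truth$planted_u] == 32))
  r <- cpm(sim$counts)
  ratios <- r[sim$planted_u, "P_cl1"] / r[sim$planted_u, "S_cl1"]
  ratios <- ratios[r[sim$planted_u, "S_cl1"] > 0]
  # analytic expectation: the bias acts on capture probabilities before
  # renormalization, so the CPM ratio is exp(beta) scaled by the ratio of
  # the two platforms' normalizers (inflating one miRNA deflates the rest)
  theta <- 10^sim$truth$log10_abundance_cl1
  expected <- 32 * sum(theta) / sum(theta * sim$truth$bias_P)
  expect_equal(median(ratios), expected, tolerance = 0.1)
})

test_that("two cell lines are correlated abundance draws", {
  cfg <- synthetic_config(n_mirnas = 400, dispersion = 0, n_cell_lines = 2)
  catg <- make_catalogue(cfg, seed = 6)
  sim <- simulate_counts(catg, cfg, seed = 7)
  expect_equal(colnames(sim$counts$counts),
               c("P_cl1", "S_cl1", "P_cl2", "S_cl2"))
  rho <- cor(sim$truth$log10_abundance_cl1, sim$truth$log10_abundance_cl2)
  expect_equal(rho, 0.95, tolerance = 0.05)
})

test_that("emitted reads conserve totals and map back to their source", {
  cfg <- synthetic_config(n_mirnas = 40, dispersion = 0, n_cell_lines = 1,
                          library_sizes = c(P = 3000, S = 12000))
  catg <- make_catalogue(cfg, seed = 8)
  sim <- simulate_counts(catg, cfg, seed = 9)
  col <- sim$counts$counts[, "P_cl1"]

  rs0 <- emit_reads(col, catg, error_rate = 0, seed = 10, "P")
  expect_equal(rs0$total_reads, sum(col))
  cm0 <- count_assignments(rs0, catg)
  expect_equal(unname(cm0$counts[names(col), 1]), unname(col))

  rs_same <- emit_reads(col, catg, error_rate = 0.01, seed = 11, "P")
  rs_same2 <- emit_reads(col, catg, error_rate = 0.01, seed = 11, "P")
  expect_identical(rs_same$entries, rs_same2$entries)

  # assigned fraction tracks the analytic expectation: a read maps back
  # only if its 18-nt seed is error-free (and <= 1 error in the remainder)
  cm1 <- count_assignments(rs_same, catg)
  frac <- sum(cm1$counts) / rs_same$total_reads
  lens <- catg$length
  w <- col[catg$id] / sum(col)
  p_ok <- sum(w * 0.99^18 * vapply(lens, function(L) {
    rest <- L - 18
    stats::pbinom(1, rest, 0.01)
  }, numeric(1)))
  se <- sqrt(p_ok * (1 - p_ok) / rs_same$total_reads)
  # allow a small surplus for error reads rescued by another entry
  expect_gt(frac, p_ok - 4 * se - 0.01)
  expect_lt(frac, p_ok + 4 * se + 0.01)
})
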