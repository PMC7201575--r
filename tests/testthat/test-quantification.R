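make_random_cm <- function(nrow = 50, ncol = 2, lambda = 40, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nrow * ncol, lambda) + 1, nrow, ncol,
              dimnames = list(sprintf("m%03d", seq_len(nrow)),
                              sprintf("s%d", seq_len(ncol))))
  count_matrix(m)
}

test_that("cpm conserves column totals at one million", {
  cm <- make_random_cm(seed = 2)
  r <- cpm(cm)
  expect_equal(unname(colSums(r)), rep(1e6, 2))
  one <- count_matrix(matrix(42, 1, 1, dimnames = list("m", "s")))
  expect_equal(unname(cpm(one)[1, 1]), 1e6)
  # inverse relation: a count x over library N maps back to the target rpm
  N <- 3501788; target <- 23.99
  x <- target * N / 1e6
  cmx <- count_matrix(matrix(x, 1, 1, dimnames = list("m", "s")),
                      lib_sizes = c(s = N))
  expect_equal(unname(cpm(cmx)[1, 1]), 23.99)
})

test_that("rpkm matches its formula", {
  cm <- count_matrix(matrix(10, 1, 1, dimnames = list("m", "s")),
                     lib_sizes = c(s = 1e6))
  expect_equal(unname(rpkm(cm, c(m = 1000))[1, 1]), 10)
  expect_equal(unname(rpkm(cm, c(m = 500))[1, 1]), 20)
  cm2 <- make_random_cm(seed = 3)
  L <- stats::setNames(sample(18:25, 50, TRUE), rownames(cm2$counts))
  want <- sweep(sweep(cm2$counts, 2, cm2$lib_sizes / 1e6, "/"),
                1, L / 1e3, "/")
  expect_equal(rpkm(cm2, L), want)
  expect_error(rpkm(cm2, L[-1]), "missing length.*m001")
})

test_that("size factors follow median-of-ratios with unit geometric mean", {
  m <- matrix(rep(c(3, 10, 40), 2), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(count_matrix(m))), c(1, 1))

  m2 <- cbind(s1 = c(3, 10, 40), s2 = 2 * c(3, 10, 40))
  rownames(m2) <- c("a", "b", "c")
  expect_equal(unname(size_factors(count_matrix(m2))),
               c(1 / sqrt(2), sqrt(2)))

  # brute-force oracle on a random matrix
  cm <- make_random_cm(seed = 4)
  k <- cm$counts
  geo <- apply(k, 1, function(r) prod(r)^(1 / length(r)))
  s_or <- apply(sweep(k, 1, geo, "/"), 2, median)
  s_or <- s_or / prod(s_or)^(1 / length(s_or))
  expect_equal(unname(size_factors(cm)), unname(s_or))

  # row permutation invariance and column-scale covariance
  expect_equal(size_factors(count_matrix(k[sample(nrow(k)), ])),
               size_factors(cm))
  k3 <- k; k3[, 2] <- k3[, 2] * 3
  s3 <- size_factors(count_matrix(k3))
  expect_equal(s3[["s2"]] / s3[["s1"]],
               3 * size_factors(cm)[["s2"]] / size_factors(cm)[["s1"]])
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  # odd row count: the median is an order statistic, so the arithmetic- and
  # log-scale medians coincide and the two estimators agree exactly
  cm <- make_random_cm(nrow = 81, ncol = 3, seed = 5)
  ours <- size_factors(cm)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm$counts)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("the stabilizing transform is anchored and monotone", {
  m <- matrix(c(0, 1, 5, 20, 0, 1, 5, 20), 4, 2,
              dimnames = list(letters[1:4], c("s1", "s2")))
  cm <- count_matrix(m)
  v <- vst(cm, s = c(s1 = 1, s2 = 1))
  expect_equal(unname(v[1, 1]), 0)      # k = 0
  expect_equal(unname(v[2, 1]), 1)      # k = s
  set.seed(6)
  col <- sort(sample(0:500, 30))
  cm2 <- count_matrix(matrix(col + 1, 30, 1,
                             dimnames = list(sprintf("x%d", 1:30), "s")))
  expect_true(all(diff(vst(cm2, s = c(s = 2.7))[, 1]) > 0))
})

test_that("platform correlation handles the degenerate cases", {
  x <- matrix(c(1:10, 1:10), 10, 2,
              dimnames = list(letters[1:10], c("p", "q")))
  expect_equal(platform_correlation(x, c("p", "q"))$r, 1)
  x[, 2] <- -x[, 1]
  expect_equal(platform_correlation(x, c("p", "q"))$r, -1)
  x[, 2] <- 5
  expect_true(is.na(platform_correlation(x, c("p", "q"))$r))
  expect_error(platform_correlation(x[1:2, ], c("p", "q")), "3 shared")
})

test_that("fold changes reproduce table arithmetic and the N.A. sentinel", {
  expect_equal(signif(fold_change(23.99, 0.91), 4), 26.36)
  expect_equal(signif(fold_change(2094.4, 1.21), 4), 1731)
  expect_true(is.na(fold_change(26.02, 0)))
  expect_true(is.na(fold_change(0, 0)))
  expect_equal(format_fold(c(26.3626, NA)), c("26.36", "N.A."))
})

test_that("the two-proportion z-test matches prop.test's chi-square", {
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(1e4:1e6, 1); n2 <- sample(1e4:1e6, 1)
    k1 <- rbinom(1, n1, runif(1, 1e-4, 1e-2))
    k2 <- rbinom(1, n2, runif(1, 1e-4, 1e-2))
    ours <- two_prop_ztest(k1, n1, k2, n2)
    ref <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2)))
    expect_equal(ours$z^2, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("differential table is null on identical columns and ranks a
           planted extreme first", {
  m <- matrix(rep(rpois(30, 50) + 1, 2), 30, 2,
              dimnames = list(sprintf("m%d", 1:30), c("P", "S")))
  cm <- count_matrix(m)
  dt <- differential_table(cm, low = "P", high = "S")
  expect_true(all(dt$p_value == 1))
  expect_true(all(dt$direction == "none"))

  set.seed(8)
  base <- rpois(30, 200) + 1
  m2 <- cbind(P = base, S = base)
  m2[5, ] <- c(1000, 0)
  rownames(m2) <- sprintf("m%d", 1:30)
  dt2 <- differential_table(count_matrix(m2), low = "P", high = "S")
  expect_equal(dt2$id[which.min(dt2$p_value)], "m5")
  expect_equal(dt2$direction[5], "low-enriched")
  expect_true(is.na(dt2$fold_change[5]))  # zero denominator
})

test_that("IQR outlier rule uses interpolated quartiles", {
  x <- c(1, 2, 3, 4, 100)
  got <- iqr_outliers(x)
  q1 <- oracle_quantile7(x, 0.25); q3 <- oracle_quantile7(x, 0.75)
  expect_equal(got$rule$q1, q1)
  expect_equal(got$rule$q3, q3)
  expect_equal(got$rule$threshold, q3 + 1.5 * (q3 - q1))
  expect_equal(which(got$flags), 5L)

  const <- iqr_outliers(rep(2, 6))
  expect_equal(const$rule$iqr, 0)
  expect_false(any(const$flags))

  expect_false(any(iqr_outliers(c(1, 2, 3, 4))$flags))
  expect_error(iqr_outliers(c(1, 2, 3)), "4 values")

  set.seed(9)
  for (i in 1:20) {
    y <- rlnorm(sample(5:40, 1))
    got <- iqr_outliers(y)
    thr <- oracle_quantile7(y, 0.75) +
      1.5 * (oracle_quantile7(y, 0.75) - oracle_quantile7(y, 0.25))
    expect_equal(got$flags, y > thr)
  }
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})
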