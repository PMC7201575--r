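test_that("seed-and-mismatch assignment follows the stated rules", {
  cat <- mirna_catalogue(
    c("mir-a", "mir-b"),
    c("UCUCCCAACCCUUGUACCAGUG",   # 22 nt
      "GGGCUCACAUCACCCCAU"))      # 18 nt
  # exact copy
  r <- assign_read("UCUCCCAACCCUUGUACCAGUG", cat)
  expect_equal(r$mirna_id, "mir-a")
  expect_equal(r$mismatches, 0L)
  expect_false(r$ambiguous)
  # last base changed on a 22-nt mature: outside the 18-nt seed
  r <- assign_read("UCUCCCAACCCUUGUACCAGUA", cat)
  expect_equal(r$mirna_id, "mir-a")
  expect_equal(r$mismatches, 1L)
  # last base changed on an 18-nt mature: inside the seed, so unassigned
  r <- assign_read("GGGCUCACAUCACCCCAA", cat)
  expect_equal(r$reason, "no-match")
  # a single difference inside the first 18 nt always breaks the seed
  r <- assign_read("UCUCCCAACCCUUGUACGAGUG", cat)
  expect_true(is.na(r$mirna_id))
  # shorter than the seed
  r <- assign_read("UCUCCCAACC", cat)
  expect_equal(r$reason, "too-short")
})

test_that("3' overhang is tolerated up to the configured bound", {
  cat <- mirna_catalogue("m", "UCUCCCAACCCUUGUACCAGUG")
  ok <- assign_read(paste0("UCUCCCAACCCUUGUACCAGUG", "ACGU"), cat)
  expect_equal(ok$mirna_id, "m")
  too_long <- assign_read(paste0("UCUCCCAACCCUUGUACCAGUG", "ACGUA"), cat)
  expect_equal(too_long$reason, "overhang")
})

test_that("equal-mismatch ties break to the smallest id and flag ambiguity", {
  shared <- "UCUCCCAACCCUUGUACC"
  cat <- mirna_catalogue(c("mir-z", "mir-a"),
                         c(paste0(shared, "AGUG"), paste0(shared, "AGUG")))
  r <- assign_read(paste0(shared, "AGUG"), cat)
  expect_equal(r$mirna_id, "mir-a")
  expect_true(r$ambiguous)
})

test_that("assignment agrees with the brute-force enumeration oracle", {
  set.seed(101)
  for (rep in 1:4) {
    cat <- mirna_catalogue(sprintf("m%03d", 1:50), random_rna(50, 19:24))
    reads <- c(
      cat$sequence[sample(50, 20)],
      vapply(cat$sequence[sample(50, 20)], function(s) {
        pos <- sample(nchar(s), 1)
        substr(s, pos, pos) <- sample(c("A", "C", "G", "U"), 1)
        s
      }, character(1)),
      random_rna(10, 19:24))
    for (rd in reads) {
      got <- assign_read(rd, cat)
      want <- oracle_assign(rd, cat)
      expect_identical(got$mirna_id, want$id)
      if (!is.na(want$id)) {
        expect_equal(got$mismatches, want$mm)
        expect_equal(got$ambiguous, want$amb)
      }
    }
  }
})

test_that("count_assignments conserves multiplicities and read order", {
  cat <- mirna_catalogue(c("a", "b"),
                         c("ACGUACGUACGUACGUACGAUCGA",
                           "ACGUACGUACGUACGUACGAUCUU"))  # differ at 23/24
  raw <- c(rep(cat$sequence[1], 7), rep(cat$sequence[2], 3),
           rep("UUUUUUUUUUUUUUUUUUUU", 5))
  cm <- count_assignments(collapse_reads(raw, "P"), cat)
  expect_equal(unname(cm$counts[c("a", "b"), 1]), c(7, 3))
  expect_equal(attr(cm, "unassigned"), 5)
  expect_equal(sum(cm$counts) + attr(cm, "unassigned") +
                 attr(cm, "ambiguous_discarded"), 15)
  # permuting the raw reads changes nothing
  cm2 <- count_assignments(collapse_reads(sample(raw), "P"), cat)
  expect_equal(cm2$counts, cm$counts)
  # empty read set gives an all-zero column
  cm0 <- count_assignments(collapse_reads(character(0), "P"), cat)
  expect_true(all(cm0$counts == 0))
})

test_that("throughput coefficient reproduces the platform read-total ratio", {
  tc <- throughput_coefficient(1924046, 7883393)
  expect_equal(round(tc$ratio, 1), 4.1)
  expect_equal(tc$coefficient, 4L)
  expect_equal(throughput_coefficient(100, 100)$coefficient, 1L)
  tc3 <- throughput_coefficient(3, 10)
  expect_equal(tc3$ratio, 10 / 3)
  expect_equal(tc3$coefficient, 3L)
  expect_error(throughput_coefficient(0, 5), "positive")
})

test_that("presence filter applies throughput-scaled minima", {
  thr <- presence_thresholds(2, 4)
  expect_equal(thr$high_min, 8L)
  m <- matrix(c(2, 1, 0, 8, 100, 7), 3, 2,
              dimnames = list(c("x", "y", "z"), c("PGM", "SOLiD")))
  cm <- count_matrix(m)
  roles <- c(PGM = "low", SOLiD = "high")
  pf <- apply_presence_filter(cm, thr, roles)
  expect_equal(unname(pf$presence["x", ]), c(TRUE, TRUE))
  expect_equal(unname(pf$presence["y", ]), c(FALSE, TRUE))
  expect_equal(unname(pf$presence["z", ]), c(FALSE, FALSE))
  v <- presence_venn(pf$presence, c("PGM", "SOLiD"))
  expect_equal(v$both, "x")
  expect_equal(v$only_2, "y")
  expect_equal(sort(v$union), c("x", "y"))
  expect_error(apply_presence_filter(cm, thr, c(PGM = "low")), "labelled")
})

test_that("presence is monotone in counts", {
  set.seed(5)
  thr <- presence_thresholds()
  roles <- c(s1 = "low", s2 = "high")
  m <- matrix(rpois(40, 4), 20, 2,
              dimnames = list(sprintf("m%d", 1:20), c("s1", "s2")))
  base <- apply_presence_filter(count_matrix(m), thr, roles)$presence
  bumped <- m + matrix(rpois(40, 2), 20, 2)
  after <- apply_presence_filter(count_matrix(bumped), thr, roles)$presence
  expect_true(all(after[base]))
})
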