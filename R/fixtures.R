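# In-text fixtures: the published per-platform summary tables, embedded as
# printed (sequences character-for-character, including rows whose printed
# sequence conflicts with the canonical mature sequence of the same name --
# set-level composition percentages are only reproducible from the printed
# characters). rpm_* are reads/million; fold_printed is the printed fold
# change ("N.A." where the smaller platform had zero reads).

.table2_solid <- function() {
  rows <- list(
    list("150-5p",          "C5.2", "N.A.",  0.0084, 26.02,   0,      "ucucccaacccuuguaccagug"),
    list("150-5p",          "HB4a", "26.36", 0.0028, 23.99,   0.91,   "ucucccaacccuuguaccagug"),
    list("142-5p",          "HB4a", "N.A.",  0.0302, 12.57,   0,      "cauaaaguagaaagcacuacu"),
    list("142-5p",          "C5.2", "10.7",  0.1141, 12.01,   1.12,   "cauaaaguagaaagcacuacu"),
    list("223-3p",          "C5.2", "N.A.",  0.0340, 12.55,   0,      "ugucaguuugucaaauacccca"),
    list("223-3p",          "HB4a", "N.A.",  0.1535, 5.14,    0,      "ugucaguuugucaaauacccca"),
    list("3607-5p",         "C5.2", "1731",  0.0367, 2094.4,  1.21,   "gcaugugaugaagcaaaucagu"),
    list("3607-5p",         "HB4a", "1968",  0.0286, 5353.8,  2.73,   "gcaugugaugaagcaaaucagu"),
    list("4284",            "C5.2", "118.8", 0.0002, 287.57,  2.42,   "gggcucacaucaccccau"),
    list("4284",            "HB4a", "14.39", 0.0042, 471.19,  32.75,  "gggcucacaucaccccau"),
    list("199a-3p/199b-3p", "C5.2", "17.6",  0.0429, 21.23,   1.21,   "acaguagucugcacauugguua"),
    list("199a-3p/199b-3p", "HB4a", "12.86", 0.0274, 35.12,   2.73,   "acaguagucugcacauugguua"),
    list("1249",            "C5.2", "16.13", 0.0180, 39.03,   2.42,   "acgcccuucccccccuucuuca"),
    list("1249",            "HB4a", "N.A.",  0.2007, 43.98,   0,      "acgcccuucccccccuucuuca"),
    list("181b-3p",         "HB4a", "13.18", 0.0424, 23.99,   1.82,   "cucacugaacaaugaaugcaa"),
    list("181b-3p",         "C5.2", "1.69",  0.7040, 2.05,    1.21,   "cucacugaacaaugaaugcaa"),
    list("29a-3p/29c-3p",   "C5.2", "4.19",  0.0266, 11927,   2849,   "uagcaccaucugaaaucgguua"),
    list("29a-3p/29c-3p",   "HB4a", "10.48", 0.0062, 37988,   3622,   "uagcaccaucugaaaucgguua"),
    list("103a-3p",         "C5.2", "8.41",  0.0060, 128212,  15233,  "agcagcauuguacagggcuauga"),
    list("103a-3p",         "HB4a", "4.03",  0.0406, 70822,   17552,  "agcagcauuguacagggcuauga"),
    list("152-5p",          "HB4a", "8.07",  0.0202, 102.8,   12.74,  "agguucugugauacacuccgacu"),
    list("152-5p",          "C5.2", "7.78",  0.0517, 28.30,   3.64,   "agguucugugauacacuccgacu"),
    list("4521",            "C5.2", "5.61",  0.0200, 217.73,  38.79,  "gcuaaggaaguccugugcucag"),
    list("4521",            "HB4a", "2.99",  0.0842, 261.30,  87.34,  "gcuaaggaaguccugugcucag"),
    list("301b",            "C5.2", "4.39",  0.0270, 532.68,  121.23, "cagugcaaugauauugucaaagc"),
    list("301b",            "HB4a", "2.06",  0.1569, 589.98,  286.58, "cagugcaaugauauugucaaagc"),
    list("107",             "C5.2", "3.82",  0.0324, 3831.24, 1000.16, "agcagcauuguacagggcuauca"),
    list("107",             "HB4a", "2.55",  0.0999, 3918.28, 1535.69, "agcagcauuguacagggcuauca"))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(mirna = r[[1]], cell_line = r[[2]], fold_printed = r[[3]],
               p_printed = r[[4]], rpm_high = r[[5]], rpm_low = r[[6]],
               sequence = toupper(r[[7]]), stringsAsFactors = FALSE)))
  # second sequence printed for the 29a-3p/29c-3p cluster row
  attr(df, "extra_sequences") <- toupper("uagcaccauuugaaaucgguua")
  attr(df, "high_platform") <- "SOLiD"
  attr(df, "low_platform") <- "PGM"
  df
}

.table3_pgm <- function() {
  rows <- list(
    list("3613-5p",   "C5.2", "N.A.",  0.0062, 24.25,   0,      "uguuguacuuuuuuuuuuguuc"),
    list("3613-5p",   "HB4a", "25.52", 0.1131, 14.55,   0.57,   "uguuguacuuuuuuuuuuguuc"),
    list("4455",      "HB4a", "N.A.",  0.0472, 10.92,   0,      "aggguguguguguuuuu"),
    list("4455",      "C5.2", "N.A.",  NA,     0,       0,      "aggguguguguguuuuu"),
    list("424-3p",    "HB4a", "118.1", 0.0270, 67.32,   0.57,   "cagugcaaugauauugucaaagc"),
    list("424-3p",    "C5.2", "6.76",  0.1348, 50.92,   7.53,   "cagugcaaugauauugucaaagc"),
    list("16-1-3p",   "HB4a", "67.03", 0.0028, 76.42,   1.14,   "ucucccaacccuuguaccagug"),
    list("16-1-3p",   "C5.2", "45.13", 0.0084, 61.83,   1.37,   "ucucccaacccuuguaccagug"),
    list("25-5p",     "HB4a", "46.28", 0.0340, 26.38,   0.57,   "ugucaguuugucaaauacccca"),
    list("25-5p",     "C5.2", "19.99", 0.0873, 18.19,   0.91,   "ugucaguuugucaaauacccca"),
    list("20a-3p",    "HB4a", "48.37", 0.0274, 1215.45, 25.13,  "acaguagucugcacauugguua"),
    list("20a-3p",    "C5.2", "11.08", 0.0429, 1446.3,  130.55, "acaguagucugcacauugguua"),
    list("let-7i-5p", "C5.2", "8.16",  0.0060, 1659.7,  203.35, "agcagcauuguacagggcuauga"),
    list("let-7i-5p", "HB4a", "11.43", 0.0406, 1563.0,  136.79, "agcagcauuguacagggcuauga"),
    list("1296-5p",   "C5.2", "12.75", 0.0324, 189.12,  14.83,  "uuagggcccuggcuccaucucc"),
    list("1296-5p",   "HB4a", "8.62",  0.0797, 118.27,  13.71,  "uuagggcccuggcuccaucucc"),
    list("200c-3p",   "C5.2", "11.23", 0.0202, 602.52,  53.63,  "agguucugugauacacuccgacu"),
    list("200c-3p",   "HB4a", "5.27",  0.1320, 2037.88, 386.66, "agguucugugauacacuccgacu"),
    list("1307-5p",   "C5.2", "8.59",  0.0180, 1574.8,  183.27, "acgcccuucccccccuucuuca"),
    list("1307-5p",   "HB4a", "6.55",  0.0872, 1924.16, 293.56, "acgcccuucccccccuucuuca"))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(mirna = r[[1]], cell_line = r[[2]], fold_printed = r[[3]],
               p_printed = r[[4]], rpm_high = r[[5]], rpm_low = r[[6]],
               sequence = toupper(r[[7]]), stringsAsFactors = FALSE)))
  attr(df, "high_platform") <- "PGM"
  attr(df, "low_platform") <- "SOLiD"
  df
}

.table1_totals <- function() {
  data.frame(
    platform = c("PGM", "PGM", "SOLiD", "SOLiD"),
    cell_line = c("HB4a", "C5.2", "HB4a", "C5.2"),
    valid_reads = c(1099181, 824865, 3501788, 4381605),
    distinct_mirnas = c(416, 429, 407, 438),
    stringsAsFactors = FALSE)
}

#' Load an in-text fixture table
#'
#' Packaged summary data used throughout the tests and the acceptance
#' checks: `"table2_solid"` (the 14 miRNAs more abundant on the
#' high-throughput SOLiD platform; one row per miRNA x cell line with
#' printed fold change, p, reads/million on each platform, and the printed
#' sequence), `"table3_pgm"` (the 10 miRNAs more abundant on PGM, same
#' shape), and `"table1_totals"` (per platform x cell line valid-read
#' totals and distinct-miRNA counts).
#'
#' In each differential table `rpm_high` is reads/million on the platform
#' the set is enriched in (the fold-change numerator) and `rpm_low` the
#' other platform.
#'
#' @param name fixture name.
#' @return a data.frame (see above).
#' @export
load_fixture <- function(name) {
  fixtures <- c("table2_solid", "table3_pgm", "table1_totals")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  switch(name,
         table2_solid = .table2_solid(),
         table3_pgm = .table3_pgm(),
         table1_totals = .table1_totals())
}

#' Unique printed sequences of a differential fixture
#'
#' One sequence per miRNA row, in table order. Rows listing two miRNA
#' names contribute the first printed sequence.
#'
#' @param fixture a table fixture from [load_fixture()].
#' @return character vector of sequences.
#' @export
fixture_sequences <- function(fixture) {
  fixture$sequence[!duplicated(fixture$mirna)]
}

#' Recompute fold changes of a differential fixture
#'
#' Fold change = enriched-platform rpm over other-platform rpm, `NA`
#' (printed "N.A.") when the denominator is zero.
#'
#' @param fixture a table fixture from [load_fixture()].
#' @return the fixture with `fold_recomputed` (numeric) and
#'   `fold_formatted` (4 significant figures, "N.A." sentinel) appended.
#' @export
fixture_fold_changes <- function(fixture) {
  fc <- fold_change(fixture$rpm_high, fixture$rpm_low)
  fixture$fold_recomputed <- fc
  fixture$fold_formatted <- format_fold(fc)
  fixture
}
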