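#' Validate an end-to-end run configuration
#'
#' @param counts a `count_matrix` (already mapped/aggregated).
#' @param catalogue a `mirna_catalogue` covering the count rows (optional;
#'   required for composition and graph stages).
#' @param roles named vector mapping every sample to `"low"` or `"high"`
#'   throughput.
#' @param pairs list of `c(low, high)` column pairs to compare (default:
#'   auto-paired by the `_cl<i>` suffix of the column names).
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed for the stochastic stages (saturation).
#' @param thresholds a `presence_thresholds`.
#' @param cluster collapse near-identical catalogue sequences before
#'   quantification.
#' @param fractions,repeats saturation-curve settings.
#' @param alpha significance level for enriched-set selection.
#' @return a validated `run_config` list.
#' @export
run_config <- function(counts, catalogue = NULL, roles, pairs = NULL,
                       out_dir, seed, thresholds = presence_thresholds(),
                       cluster = FALSE,
                       fractions = seq(0.05, 1, by = 0.05), repeats = 3,
                       alpha = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  samples <- colnames(counts$counts)
  if (!all(samples %in% names(roles)))
    stop("roles must label every sample", call. = FALSE)
  if (is.null(pairs)) {
    suffix <- sub("^.*_", "", samples)
    pairs <- lapply(unique(suffix), function(sfx) {
      cols <- samples[suffix == sfx]
      if (length(cols) != 2)
        stop("cannot auto-pair columns for suffix '", sfx,
             "'; supply pairs explicitly", call. = FALSE)
      c(cols[roles[cols] == "low"], cols[roles[cols] == "high"])
    })
  }
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(counts = counts, catalogue = catalogue,
                 roles = roles[samples], pairs = pairs, out_dir = out_dir,
                 seed = as.integer(seed), thresholds = thresholds,
                 cluster = cluster, fractions = fractions,
                 repeats = repeats, alpha = alpha),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full cross-platform comparison
#'
#' Orchestrates every stage on a prepared count matrix: optional
#' near-identical clustering, presence filtering and Venn sets, CPM and
#' stabilized matrices, per-pair Pearson correlation, differential
#' representation with IQR outlier flags, saturation curves, and -- when a
#' catalogue is supplied -- composition comparison and adjacency-graph
#' degree tests between the platform-enriched sets, plus aggregate DOT
#' graphs. All artifacts are TSV/DOT text; a manifest records every
#' parameter consumed. Outputs are byte-identical across reruns with the
#' same config and seed.
#'
#' @param config a `run_config`.
#' @return invisibly, a named list of artifact paths.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- list()
  cm <- config$counts
  stage <- "clustering"
  res <- tryCatch({
    if (config$cluster) {
      if (is.null(config$catalogue))
        stop("clustering requires a catalogue")
      clusters <- build_clusters(config$catalogue)
      paths$clusters <- write_cluster_map(clusters, out("clusters.tsv"))
      cm <- aggregate_cluster_counts(cm, clusters)
    }
    stage <- "counts"
    paths$counts <- write_count_table(cm, out("counts.tsv"))

    stage <- "presence"
    pf <- apply_presence_filter(cm, config$thresholds, config$roles)
    pres <- data.frame(id = rownames(pf$presence),
                       pf$presence + 0, check.names = FALSE)
    paths$presence <- .write_tsv(pres, out("presence.tsv"))
    venn_rows <- lapply(config$pairs, function(pr) {
      v <- presence_venn(pf$presence, pr)
      data.frame(pair = paste(pr, collapse = " vs "),
                 both = length(v$both), only_low = length(v$only_1),
                 only_high = length(v$only_2), union = length(v$union))
    })
    paths$venn <- .write_tsv(do.call(rbind, venn_rows), out("venn.tsv"))

    stage <- "normalization"
    rpm <- cpm(cm)
    paths$cpm <- .write_tsv(data.frame(id = rownames(rpm), rpm,
                                       check.names = FALSE),
                            out("normalized_cpm.tsv"))
    s <- size_factors(cm)
    v <- vst(cm, s)
    paths$vst <- .write_tsv(data.frame(id = rownames(v), v,
                                       check.names = FALSE),
                            out("vst.tsv"))

    stage <- "correlation"
    cor_rows <- lapply(config$pairs, function(pr) {
      pc <- platform_correlation(v, pr)
      data.frame(low = pr[1], high = pr[2], r = pc$r,
                 r_squared = pc$r_squared, n = pc$n)
    })
    paths$correlation <- .write_tsv(do.call(rbind, cor_rows),
                                    out("correlation.tsv"))

    stage <- "differential"
    diff_tables <- list()
    for (pr in config$pairs) {
      dt <- differential_table(cm, low = pr[1], high = pr[2],
                               alpha = config$alpha)
      dt$fold_change <- format_fold(dt$fold_change)
      key <- paste(pr, collapse = "_vs_")
      diff_tables[[key]] <- dt
      paths[[paste0("differential_", key)]] <-
        .write_tsv(dt, out(sprintf("differential_%s.tsv", key)))
    }

    stage <- "saturation"
    for (col in colnames(cm$counts)) {
      curve <- saturation_curve(cm$counts[, col],
                                fractions = config$fractions,
                                repeats = config$repeats,
                                seed = config$seed +
                                  match(col, colnames(cm$counts)))
      paths[[paste0("saturation_", col)]] <-
        write_saturation_curve(curve, out(sprintf("saturation_%s.tsv", col)))
    }

    stage <- "composition"
    if (!is.null(config$catalogue) && !config$cluster) {
      low_ids <- unique(unlist(lapply(diff_tables, function(dt)
        dt$id[dt$direction == "low-enriched"])))
      high_ids <- unique(unlist(lapply(diff_tables, function(dt)
        dt$id[dt$direction == "high-enriched"])))
      seq_of <- stats::setNames(config$catalogue$sequence,
                                config$catalogue$id)
      low_seqs <- unname(seq_of[low_ids])
      high_seqs <- unname(seq_of[high_ids])
      if (length(low_seqs) >= 2 && length(high_seqs) >= 2) {
        paths$composition <- .write_tsv(
          composition_compare(low_seqs, high_seqs),
          out("composition_low_vs_high.tsv"))
        stage <- "seqgraph"
        all_deg <- degree_matrix(config$catalogue)
        zt_low <- degree_ztest(degree_matrix(low_seqs), all_deg)
        zt_low$comparison <- "low_vs_catalogue"
        zt_high <- degree_ztest(degree_matrix(high_seqs), all_deg)
        zt_high$comparison <- "high_vs_catalogue"
        zt_lh <- degree_ztest(degree_matrix(low_seqs),
                              degree_matrix(high_seqs))
        zt_lh$comparison <- "low_vs_high"
        paths$degree_tests <- .write_tsv(rbind(zt_low, zt_high, zt_lh),
                                         out("degree_tests.tsv"))
        paths$graph_low <- write_dot(aggregate_graph(low_seqs),
                                     out("aggregate_low.dot"))
        paths$graph_high <- write_dot(aggregate_graph(high_seqs),
                                      out("aggregate_high.dot"))
      }
      paths$graph_all <- write_dot(aggregate_graph(config$catalogue),
                                   out("aggregate_catalogue.dot"))
    }

    stage <- "manifest"
    manifest <- c(
      sprintf("package=mirplat %s",
              as.character(utils::packageVersion("mirplat"))),
      sprintf("seed=%d", config$seed),
      sprintf("samples=%s", paste(colnames(cm$counts), collapse = ",")),
      sprintf("roles=%s", paste(names(config$roles), config$roles,
                                sep = ":", collapse = ",")),
      sprintf("pairs=%s", paste(vapply(config$pairs, paste,
                                       character(1), collapse = "|"),
                                collapse = ",")),
      sprintf("presence_low_min=%d", config$thresholds$low_min),
      sprintf("presence_high_min=%d", config$thresholds$high_min),
      sprintf("throughput_coefficient=%g", config$thresholds$coefficient),
      sprintf("cluster=%s", config$cluster),
      sprintf("saturation_fractions=%s",
              paste(config$fractions, collapse = ",")),
      sprintf("saturation_repeats=%d", config$repeats),
      sprintf("alpha=%g", config$alpha))
    writeLines(manifest, out("manifest.txt"))
    paths$manifest <- out("manifest.txt")
    paths
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
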