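#' Run the full synthetic-data pipeline end to end
#'
#' Simulates all five modalities under one config, then runs every
#' analysis stage: temporal classification, maternal fraction, TF-share
#' time course, tissue enrichment, ubiquity/specificity, co-expression
#' conservation, and ChIP co-occupancy transitions. All randomness flows
#' from the config seed.
#'
#' @param config a [simulation_config()].
#' @param anatomy a [slim_anatomy()].
#' @param outdir optional directory for the simulated files and a summary
#'   TSV.
#' @param n_iterations resampling iterations for the enrichment null.
#' @param n_perm reshuffles for the conservation permutation null.
#' @param linkage_cut tree cut height for adult clusters (Jaccard
#'   distances; default 0.9).
#' @return A list of class `tfscape_report` with the per-stage outputs and
#'   a `headline` data.frame of summary numbers.
#' @export
run_all <- function(config, anatomy = default_slim_anatomy(),
                    outdir = NULL, n_iterations = 10000L, n_perm = 1000L,
                    linkage_cut = 0.9) {
  sim <- simulate_all(config, anatomy, outdir)
  aux_seed <- derive_substreams(config$seed)[["aux"]]

  classes <- temporal_class_table(sim$matrix)
  class_counts <- table(factor(classes$class, levels = temporal_classes()))
  mat_frac <- maternal_fraction(sim$matrix, sim$catalog)

  expressed_sets <- lapply(seq_len(N_STAGES), function(s)
    names(stm_sets(sim$matrix, s)))
  names(expressed_sets) <- stage_labels()
  share <- tf_share_timecourse(expressed_sets, sim$catalog)

  enr <- enrich_all(sim$matrix, sim$catalog,
                    sampling_null(n_iterations, seed = aux_seed))
  ubiq <- ubiquity_by_stage(sim$matrix, sim$catalog)
  cons <- conservation_z_all(sim$matrix,
                             genes = sim$catalog$gene_id[sim$catalog$is_tf],
                             k = 2L, n_iter = n_perm, seed = aux_seed + 1L)
  up_tf <- call_table_up(sim$calls)[
    sim$catalog$gene_id[sim$catalog$is_tf], , drop = FALSE]
  clusters <- adult_specificity_clusters(up_tf, linkage_cut)
  trans <- chip_cooccupancy(sim$chip$peaks$A_t1, sim$chip$peaks$B_t1,
                            sim$chip$peaks$A_t2, sim$chip$peaks$B_t2)

  headline <- data.frame(
    quantity = c("genes", "tfs", "maternal_fraction_tf",
                 "peak_tf_share_stage", "n_significant_cells",
                 "n_adult_clusters", "frac_A_only_to_double"),
    value = c(config$n_genes, sum(sim$catalog$is_tf), mat_frac,
              which.max(share$tf_share),
              sum(enr$significant, na.rm = TRUE),
              clusters$n_clusters,
              trans$transitions$fractions["A_only", "double"]),
    stringsAsFactors = FALSE)

  report <- structure(list(
    config = config, catalog = sim$catalog, matrix = sim$matrix,
    truth = sim$truth, classes = classes, class_counts = class_counts,
    maternal_fraction = mat_frac, tf_share = share, enrichment = enr,
    ubiquity = ubiq, conservation = cons, adult_clusters = clusters,
    chip = trans, headline = headline), class = "tfscape_report")
  if (!is.null(outdir)) {
    utils::write.table(headline, file.path(outdir, "headline.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cons, file.path(outdir, "conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @export
print.tfscape_report <- function(x, ...) {
  cat("tfscape_report\n")
  cat("  temporal classes:",
      paste(names(x$class_counts), as.integer(x$class_counts),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  maternal TF fraction: %.3f\n", x$maternal_fraction))
  cat("  significant enrichment cells:",
      sum(x$enrichment$significant, na.rm = TRUE), "of",
      nrow(x$enrichment), "\n")
  cat("  adult clusters:", x$adult_clusters$n_clusters, "\n")
  cat(sprintf("  A_only -> double transition: %.3f\n",
              x$chip$transitions$fractions["A_only", "double"]))
  invisible(x)
}

worked_example_row <- function(label, num, den, expected, digits = 0,
                               tol = 0, scale = 100) {
  computed <- round(scale * num / den, digits)
  data.frame(label = label, numerator = num, denominator = den,
             computed = computed, expected = expected,
             pass = abs(computed - expected) <= tol,
             stringsAsFactors = FALSE)
}

#' Recompute the printed worked-example count pairs
#'
#' Self-contained checks of the headline percentages and approximations a
#' reader can recompute from printed count pairs: each row recomputes the
#' percentage (or rounded product) from its counts and compares with the
#' printed value at the printed precision. Values hedged with "about" in
#' prose are allowed one point of slack.
#'
#' @return data.frame with columns `label`, `numerator`, `denominator`,
#'   `computed`, `expected`, `pass`.
#' @export
worked_examples <- function() {
  rows <- list(
    worked_example_row("active transcription overlaps TF gene (pct of TFs on array)",
                       694, 731, 95),
    worked_example_row("average-or-high time-course expression (pct of TFs on array)",
                       667, 679, 98),
    worked_example_row("detected in embryo by in situ (pct of TFs in database)",
                       351, 373, 94),
    worked_example_row("expressed in >=1 adult tissue (pct of TFs on array, 'about')",
                       687, 724, 94, tol = 1),
    worked_example_row("TF repertoire mappable to genes (pct of repertoire)",
                       731, 753, 97),
    worked_example_row("in situ database coverage of TF genes (pct)",
                       373, 731, 51),
    worked_example_row("maternally contributed TFs (pct of TFs in database)",
                       219, 373, 58.7, digits = 1),
    worked_example_row("high expression at 1-2 h AEL (pct of TFs on array)",
                       327, 679, 48.2, digits = 1),
    worked_example_row("expressed at 0-30 min AEL (pct of TFs on array)",
                       337, 715, 47.1, digits = 1),
    worked_example_row("transcribed at 0-2 h AEL (pct of expressed TFs)",
                       429, 731, 58.7, digits = 1),
    worked_example_row("exclusively ubiquitous among ever-ubiquitous TFs (pct)",
                       28, 146, 19),
    data.frame(label = "potential TF pairs, coarse n^2/2 (nearest 500)",
               numerator = 373^2, denominator = 2,
               computed = round(373^2 / 2 / 500) * 500, expected = 69500,
               pass = round(373^2 / 2 / 500) * 500 == 69500,
               stringsAsFactors = FALSE),
    data.frame(label = "potential TF pairs, exact C(373,2)",
               numerator = 373 * 372, denominator = 2,
               computed = choose(373, 2), expected = 69378,
               pass = choose(373, 2) == 69378,
               stringsAsFactors = FALSE),
    worked_example_row("TF share among expressed vs genomic share (ratio)",
                       0.10, 0.05, 2, scale = 1)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
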