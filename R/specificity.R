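#' Ubiquitous vs restricted expression, TFs vs non-TFs
#'
#' For each stage range (or pooled over a stage window), cross-tabulates
#' the genes expressed at the stage by TF status and by whether their
#' annotation at that stage includes the "ubiquitous" term, and tests the
#' 2x2 table with a Pearson chi-square (1 df, no continuity correction).
#' Tables with a zero marginal are flagged degenerate and get a missing
#' p-value.
#'
#' @param m a `stage_tissue_matrix`.
#' @param catalog a `gene_catalog`.
#' @param pool optional integer vector of stage indices to pool into a
#'   single table (e.g. `2:5` for the stage 4-12 window); default `NULL`
#'   reports one row per stage. Pooling counts gene-stage observations.
#' @return data.frame with columns `stage` (NA when pooled), `tf_ubiq`,
#'   `tf_restricted`, `nontf_ubiq`, `nontf_restricted`, `chisq`, `p`,
#'   `degenerate`.
#' @export
ubiquity_by_stage <- function(m, catalog, pool = NULL) {
  is_tf <- stats::setNames(catalog$is_tf, catalog$gene_id)
  one_stage <- function(s) {
    sets <- stm_sets(m, s)
    if (!length(sets))
      return(c(tf_ubiq = 0L, tf_restricted = 0L,
               nontf_ubiq = 0L, nontf_restricted = 0L))
    ubiq <- vapply(sets, function(x) "ubiquitous" %in% x, logical(1))
    tf <- is_tf[names(sets)]
    c(tf_ubiq = sum(tf & ubiq), tf_restricted = sum(tf & !ubiq),
      nontf_ubiq = sum(!tf & ubiq), nontf_restricted = sum(!tf & !ubiq))
  }
  test_counts <- function(cnt) {
    tab <- matrix(cnt, 2, 2, byrow = TRUE)  # rows TF/non-TF, cols ubiq/restr
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(list(chisq = NA_real_, p = NA_real_, degenerate = TRUE))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(chisq = unname(ht$statistic), p = unname(ht$p.value),
         degenerate = FALSE)
  }
  if (is.null(pool)) {
    rows <- lapply(seq_len(N_STAGES), function(s) {
      cnt <- one_stage(s); tst <- test_counts(cnt)
      data.frame(stage = s, stage_label = stage_labels()[s],
                 t(cnt), chisq = tst$chisq, p = tst$p,
                 degenerate = tst$degenerate, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    cnt <- Reduce(`+`, lapply(pool, one_stage))
    tst <- test_counts(cnt)
    data.frame(stage = NA_integer_,
               stage_label = paste(stage_labels()[range(pool)],
                                   collapse = ".."),
               t(cnt), chisq = tst$chisq, p = tst$p,
               degenerate = tst$degenerate, stringsAsFactors = FALSE)
  }
}

#' Narrowly expressed, never-ubiquitous TFs
#'
#' TFs that are never annotated as ubiquitous at any embryonic stage and
#' whose expression breadth -- distinct slim terms over all stages -- is
#' strictly below `max_breadth`.
#'
#' @param m a `stage_tissue_matrix`.
#' @param catalog a `gene_catalog`.
#' @param max_breadth exclusive upper bound on breadth (default 3, i.e.
#'   "expressed in less than three anatomical structures").
#' @return Character vector of gene ids.
#' @export
never_ubiquitous_narrow_tfs <- function(m, catalog, max_breadth = 3L) {
  tfs <- intersect(unique(m$ann$gene_id), catalog$gene_id[catalog$is_tf])
  if (!length(tfs)) return(character())
  ubiq_any <- unique(m$ann$gene_id[m$ann$term == "ubiquitous"])
  keep <- setdiff(tfs, ubiq_any)
  breadth <- stm_breadth(m)[keep]
  sort(keep[breadth < max_breadth])
}

#' Exclusively ubiquitous genes
#'
#' Among genes annotated ubiquitous at one or more stages, those whose
#' every nonempty stage annotation is exactly `{ubiquitous}` -- i.e. genes
#' that never show a restricted pattern.
#'
#' @param m a `stage_tissue_matrix`.
#' @return Character vector of gene ids.
#' @export
exclusively_ubiquitous <- function(m) {
  if (!nrow(m$ann)) return(character())
  ubiq_any <- unique(m$ann$gene_id[m$ann$term == "ubiquitous"])
  nonubiq_any <- unique(m$ann$gene_id[m$ann$term != "ubiquitous"])
  sort(setdiff(ubiq_any, nonubiq_any))
}

#' Cluster adult tissue-specificity profiles
#'
#' Hierarchically clusters the binary up-call vectors of genes over adult
#' tissues (Jaccard distance, average linkage) and cuts the tree at a
#' caller-supplied height. Genes with no up call anywhere are excluded
#' (their Jaccard distance is undefined) and reported. Each cluster is
#' named after the tissues with the largest number of up calls among its
#' members.
#'
#' @param ct a [call_table()], or a logical gene x tissue up-call matrix.
#' @param linkage_cut height at which to cut the average-linkage tree
#'   (required; Jaccard distances live in \[0, 1\]).
#' @param n_name_tissues how many top tissues to use in cluster names.
#' @return A list of class `adult_clusters` with elements `membership`
#'   (data.frame `gene_id`, `cluster`), `defining_tissues` (named list per
#'   cluster), `excluded` (genes with all-zero vectors), `n_clusters`.
#' @export
adult_specificity_clusters <- function(ct, linkage_cut,
                                       n_name_tissues = 3L) {
  if (missing(linkage_cut))
    stop("linkage_cut is required (no default cut height)", call. = FALSE)
  up <- if (inherits(ct, "call_table")) call_table_up(ct) else ct
  storage.mode(up) <- "logical"
  excluded <- rownames(up)[rowSums(up) == 0]
  up <- up[rowSums(up) > 0, , drop = FALSE]
  if (nrow(up) < 2L)
    stop("need at least two genes with an up call to cluster",
         call. = FALSE)
  up <- up[order(rownames(up)), , drop = FALSE]  # input-order invariance
  d <- stats::dist(up, method = "binary")        # Jaccard distance
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = linkage_cut)
  membership <- data.frame(gene_id = rownames(up), cluster = unname(cl),
                           stringsAsFactors = FALSE)
  defining <- lapply(sort(unique(cl)), function(k) {
    counts <- colSums(up[cl == k, , drop = FALSE])
    counts <- sort(counts[counts > 0], decreasing = TRUE)
    names(utils::head(counts, n_name_tissues))
  })
  names(defining) <- as.character(sort(unique(cl)))
  structure(list(membership = membership, defining_tissues = defining,
                 excluded = excluded, n_clusters = length(defining)),
            class = "adult_clusters")
}

#' @export
print.adult_clusters <- function(x, ...) {
  cat("adult_clusters:", x$n_clusters, "clusters over",
      nrow(x$membership), "genes (", length(x$excluded), "excluded )\n")
  for (k in names(x$defining_tissues))
    cat("  cluster", k, ":",
        sum(x$membership$cluster == as.integer(k)), "genes --",
        paste(x$defining_tissues[[k]], collapse = ", "), "\n")
  invisible(x)
}

#' Cross-tabulate adult clusters against late-embryo annotation
#'
#' For each adult specificity cluster: how many members carry late-embryo
#' (stage range 13-16) annotation, their breadth distribution at that
#' stage, and the most frequent embryonic terms with percentages of the
#' annotated members.
#'
#' @param clusters an `adult_clusters` object.
#' @param m a `stage_tissue_matrix` (embryonic annotation).
#' @param stage stage index to cross against (default 6, range 13-16).
#' @param top_n number of top terms to report per cluster.
#' @return data.frame with columns `cluster`, `n_members`, `n_annotated`,
#'   `term`, `n_with_term`, `pct` (rounded to integer percent); clusters
#'   with no annotated member yield one flagged row with NA term.
#' @export
embryo_adult_crosstab <- function(clusters, m, stage = 6L, top_n = 5L) {
  sets <- stm_sets(m, stage)
  rows <- list()
  for (k in sort(unique(clusters$membership$cluster))) {
    members <- clusters$membership$gene_id[clusters$membership$cluster == k]
    annotated <- intersect(members, names(sets))
    if (!length(annotated)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, n_members = length(members), n_annotated = 0L,
        term = NA_character_, n_with_term = NA_integer_, pct = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    tab <- sort(table(unlist(sets[annotated])), decreasing = TRUE)
    tab <- utils::head(tab, top_n)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = k, n_members = length(members),
      n_annotated = length(annotated),
      term = names(tab), n_with_term = as.integer(tab),
      pct = round(100 * as.integer(tab) / length(annotated)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
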