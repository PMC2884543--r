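#' Temporal expression class labels
#' @return Character vector of the six class labels.
#' @export
temporal_classes <- function() {
  c("no_expression", "early_only", "late_only", "continuous_zygotic",
    "maternal_continuous", "diverse")
}

#' Classify a gene's temporal expression pattern
#'
#' Assigns one of six classes from the binary support over the six stage
#' ranges:
#' \describe{
#'   \item{no_expression}{no stage with expression.}
#'   \item{maternal_continuous}{expressed at every stage range, i.e.
#'     maternally contributed and continuously expressed to the end.}
#'   \item{continuous_zygotic}{not maternal, but a contiguous run of at
#'     least two stage ranges reaching the final range ("not maternal but
#'     continuous").}
#'   \item{early_only}{a contiguous run starting at the first range and
#'     ending at or before `early_cutoff`.}
#'   \item{late_only}{a contiguous run starting after `early_cutoff` that
#'     does not qualify as continuous_zygotic (it either stops before the
#'     final range, or is a single window).}
#'   \item{diverse}{everything else (gapped supports, mid-development
#'     blocks).}
#' }
#' The six classes partition all 2^6 possible supports.
#'
#' @param support logical (or 0/1) vector of length 6, ordered by stage.
#' @param early_cutoff last stage index still counted as "early"
#'   (default 3, i.e. stage range 7-8).
#' @return A single class label.
#' @export
#' @examples
#' classify_temporal_class(c(1, 1, 1, 1, 1, 1))  # maternal_continuous
#' classify_temporal_class(c(0, 0, 0, 1, 1, 1))  # continuous_zygotic
#' classify_temporal_class(c(1, 0, 1, 0, 1, 0))  # diverse
classify_temporal_class <- function(support, early_cutoff = 3L) {
  s <- as.logical(support)
  if (length(s) != N_STAGES || anyNA(s))
    stop("support must be 6 non-missing booleans", call. = FALSE)
  idx <- which(s)
  if (!length(idx)) return("no_expression")
  if (any(diff(idx) != 1L)) return("diverse")
  first <- idx[1]; last <- idx[length(idx)]
  if (first == 1L && last == N_STAGES) return("maternal_continuous")
  if (first == 1L) {
    if (last <= early_cutoff) return("early_only") else return("diverse")
  }
  if (last == N_STAGES && length(idx) >= 2L) return("continuous_zygotic")
  if (first >= early_cutoff + 1L) return("late_only")
  "diverse"
}

#' Classify every gene in a stage-by-tissue matrix
#'
#' @param m a `stage_tissue_matrix`.
#' @param early_cutoff see [classify_temporal_class()].
#' @return data.frame with columns `gene_id`, `class`.
#' @export
temporal_class_table <- function(m, early_cutoff = 3L) {
  supp <- stm_support(m)
  cls <- apply(supp, 1, classify_temporal_class, early_cutoff = early_cutoff)
  data.frame(gene_id = rownames(supp), class = unname(cls),
             stringsAsFactors = FALSE)
}

#' Maternal fraction of the TF repertoire
#'
#' The fraction of TFs (among TFs in the matrix universe, i.e. TFs with any
#' expression information) expressed at the first stage range -- transcripts
#' present before the onset of zygotic transcription are maternally
#' deposited.
#'
#' @param m a `stage_tissue_matrix`.
#' @param catalog a `gene_catalog`.
#' @return Proportion in \[0, 1\].
#' @export
maternal_fraction <- function(m, catalog) {
  tfs <- intersect(m$genes, catalog$gene_id[catalog$is_tf])
  if (!length(tfs)) stop("no TFs in the matrix universe", call. = FALSE)
  supp <- stm_support(m)
  mean(supp[tfs, 1L])
}

#' Per-family temporal utilization profile
#'
#' For each DBD family and stage range: the number of expressed family
#' members, and the percentage of all expressed TFs at that stage that the
#' family contributes. TFs with family `"none"` are skipped by the
#' percentage denominator as well (no recognized DBD).
#'
#' @param m a `stage_tissue_matrix`.
#' @param catalog a `gene_catalog`.
#' @return data.frame with columns `family`, `stage`, `stage_label`,
#'   `n_expressed`, `pct_of_expressed_tfs` (NA where no family-resolved TF
#'   is expressed at the stage, never 0/0).
#' @export
family_temporal_profile <- function(m, catalog) {
  supp <- stm_support(m)
  tf <- catalog[catalog$is_tf & catalog$dbd_family != "none", ]
  tf <- tf[tf$gene_id %in% m$genes, ]
  fams <- sort(unique(tf$dbd_family))
  out <- expand.grid(family = fams, stage = seq_len(N_STAGES),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$stage_label <- stage_labels()[out$stage]
  totals <- vapply(seq_len(N_STAGES),
                   function(s) sum(supp[tf$gene_id, s]), numeric(1))
  out$n_expressed <- mapply(function(f, s) {
    sum(supp[tf$gene_id[tf$dbd_family == f], s, drop = FALSE])
  }, out$family, out$stage)
  out$pct_of_expressed_tfs <-
    ifelse(totals[out$stage] > 0, 100 * out$n_expressed / totals[out$stage],
           NA_real_)
  out
}

#' TF share of the expressed transcriptome along a time axis
#'
#' For each timepoint, the proportion of TFs among the expressed genes, and
#' the ratio of that share to the genomic TF share (the TF fraction of the
#' whole catalog). A ratio of 2 means TFs are twice as prevalent among
#' expressed genes as in the genome.
#'
#' @param expressed_sets named list: per timepoint, the character vector of
#'   expressed gene ids (subsets of the catalog).
#' @param catalog a `gene_catalog`.
#' @return data.frame with columns `timepoint`, `n_expressed`, `n_tf`,
#'   `tf_share`, `ratio_to_genomic` (NA for empty sets).
#' @export
tf_share_timecourse <- function(expressed_sets, catalog) {
  genomic <- mean(catalog$is_tf)
  is_tf <- stats::setNames(catalog$is_tf, catalog$gene_id)
  rows <- lapply(seq_along(expressed_sets), function(i) {
    set <- expressed_sets[[i]]
    extra <- setdiff(set, catalog$gene_id)
    if (length(extra))
      stop("expressed set ", i, " contains genes outside the catalog: ",
           paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
    n <- length(set)
    ntf <- sum(is_tf[set])
    share <- if (n > 0) ntf / n else NA_real_
    data.frame(timepoint = names(expressed_sets)[i] %||% as.character(i),
               n_expressed = n, n_tf = ntf, tf_share = share,
               ratio_to_genomic = share / genomic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || is.na(a) || !nzchar(a)) b else a
}
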