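#' Construct a stage-by-tissue expression matrix
#'
#' The central object of the temporal/spatial analyses: for every gene in an
#' explicit universe, the set of slim anatomy terms annotated at each of the
#' six stage ranges. A gene is "expressed at a stage" iff its term set at
#' that stage is nonempty. Genes in the universe with no annotation rows are
#' genuinely annotated as unexpressed ("no expression"), which is distinct
#' from genes absent from the universe altogether.
#'
#' @param genes character vector: the gene universe (unique ids).
#' @param annotations data.frame with columns `gene_id`, `stage` (integer
#'   1..6 or stage-range label), `term`. Duplicate rows are collapsed.
#' @param anatomy a [slim_anatomy()].
#' @return An object of class `stage_tissue_matrix` with elements `genes`,
#'   `anatomy`, and `ann` (long-format annotation data.frame with integer
#'   `stage`).
#' @export
stage_tissue_matrix <- function(genes, annotations, anatomy) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("gene universe contains duplicate ids", call. = FALSE)
  stopifnot(inherits(anatomy, "slim_anatomy"))
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) {
    ann <- data.frame(gene_id = character(), stage = integer(),
                      term = character(), stringsAsFactors = FALSE)
  } else {
    for (col in c("gene_id", "stage", "term"))
      if (!col %in% names(ann))
        stop("annotations are missing column '", col, "'", call. = FALSE)
    if (is.character(ann$stage) || is.factor(ann$stage))
      ann$stage <- stage_index(as.character(ann$stage))
    ann$stage <- as.integer(ann$stage)
    if (any(ann$stage < 1L | ann$stage > N_STAGES))
      stop("stage indices must be in 1..", N_STAGES, call. = FALSE)
    bad <- setdiff(unique(ann$term), anatomy$terms)
    if (length(bad))
      stop("annotation term(s) not in anatomy: ",
           paste(bad, collapse = ", "), call. = FALSE)
    missing <- setdiff(unique(ann$gene_id), genes)
    if (length(missing))
      stop("annotated gene(s) not in universe: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    ann <- unique(ann[c("gene_id", "stage", "term")])
    ann <- ann[order(ann$gene_id, ann$stage, ann$term), ]
    rownames(ann) <- NULL
  }
  structure(list(genes = genes, anatomy = anatomy, ann = ann),
            class = "stage_tissue_matrix")
}

#' @export
print.stage_tissue_matrix <- function(x, ...) {
  cat("stage_tissue_matrix:", length(x$genes), "genes,",
      nrow(x$ann), "annotation rows,",
      length(unique(x$ann$gene_id)), "genes with expression\n")
  invisible(x)
}

#' Validate a stage-by-tissue matrix
#'
#' Re-checks every structural invariant (term vocabulary, stage range,
#' id uniqueness, universe membership). Called by downstream modules.
#'
#' @param m a `stage_tissue_matrix`.
#' @return `m`, invisibly; errors if an invariant is violated.
#' @export
validate_stm <- function(m) {
  stopifnot(inherits(m, "stage_tissue_matrix"))
  stage_tissue_matrix(m$genes, m$ann, m$anatomy)
  invisible(m)
}

#' Binary stage support per gene
#'
#' @param m a `stage_tissue_matrix`.
#' @return Logical matrix (genes x 6 stage ranges); `TRUE` where the gene's
#'   term set at that stage is nonempty. Row names are gene ids, column
#'   names stage labels.
#' @export
stm_support <- function(m) {
  out <- matrix(FALSE, length(m$genes), N_STAGES,
                dimnames = list(m$genes, stage_labels()))
  if (nrow(m$ann)) {
    idx <- cbind(match(m$ann$gene_id, m$genes), m$ann$stage)
    out[idx] <- TRUE
  }
  out
}

#' Term sets at one stage
#'
#' @param m a `stage_tissue_matrix`.
#' @param stage stage index (1..6) or stage-range label.
#' @return Named list mapping each gene expressed at `stage` to its
#'   character vector of terms (sorted). Genes with empty sets are omitted.
#' @export
stm_sets <- function(m, stage) {
  if (is.character(stage)) stage <- stage_index(stage)
  rows <- m$ann[m$ann$stage == stage, ]
  if (!nrow(rows)) return(structure(list(), names = character()))
  lapply(split(rows$term, rows$gene_id), sort)
}

#' Per-gene expression breadth
#'
#' Breadth is the number of distinct slim terms in a gene's annotation,
#' either per stage or as the union over all stages.
#'
#' @param m a `stage_tissue_matrix`.
#' @param union if `TRUE` (default) count distinct terms over all stages;
#'   otherwise return a genes x stages count matrix.
#' @return Named integer vector (union) or integer matrix.
#' @export
stm_breadth <- function(m, union = TRUE) {
  if (union) {
    counts <- integer(length(m$genes))
    names(counts) <- m$genes
    if (nrow(m$ann)) {
      tab <- tapply(m$ann$term, m$ann$gene_id, function(x) length(unique(x)))
      counts[names(tab)] <- as.integer(tab)
    }
    counts
  } else {
    out <- matrix(0L, length(m$genes), N_STAGES,
                  dimnames = list(m$genes, stage_labels()))
    if (nrow(m$ann)) {
      tab <- table(factor(m$ann$gene_id, levels = m$genes), m$ann$stage)
      out[, as.integer(colnames(tab))] <- as.integer(tab)
    }
    out
  }
}

#' Read long-format annotations into a stage-by-tissue matrix
#'
#' The file is tab-separated with header `gene_id`, `stage_range`, `term`,
#' one term per row. Both the annotation file and an explicit gene universe
#' are required: genes in the universe but absent from the file carry
#' all-empty term sets (class "no expression").
#'
#' @param path path to the TSV file.
#' @param anatomy a [slim_anatomy()]; every term in the file must belong to
#'   it.
#' @param genes the gene universe (character vector). Defaults to the genes
#'   seen in the file.
#' @return A `stage_tissue_matrix`.
#' @export
read_annotations <- function(path, anatomy, genes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE)
  for (col in c("gene_id", "stage_range", "term"))
    if (!col %in% names(df))
      stop("annotation file is missing column '", col, "'", call. = FALSE)
  # line numbers: header is line 1
  bad_term <- which(!df$term %in% anatomy$terms)
  if (length(bad_term))
    stop("unknown term '", df$term[bad_term[1]], "' at line ",
         bad_term[1] + 1L, call. = FALSE)
  bad_stage <- which(!df$stage_range %in% stage_labels())
  if (length(bad_stage))
    stop("unknown stage range '", df$stage_range[bad_stage[1]],
         "' at line ", bad_stage[1] + 1L, call. = FALSE)
  if (is.null(genes)) genes <- sort(unique(df$gene_id))
  ann <- data.frame(gene_id = df$gene_id,
                    stage = stage_index(df$stage_range),
                    term = df$term, stringsAsFactors = FALSE)
  stage_tissue_matrix(genes, ann, anatomy)
}

#' Write a stage-by-tissue matrix as long-format TSV
#'
#' Inverse of [read_annotations()] up to row order; the gene universe must
#' be carried separately (for example via [write_gene_catalog()]).
#'
#' @param m a `stage_tissue_matrix`.
#' @param path output path.
#' @export
write_annotations <- function(m, path) {
  df <- data.frame(gene_id = m$ann$gene_id,
                   stage_range = stage_labels()[m$ann$stage],
                   term = m$ann$term, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
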