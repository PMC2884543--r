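#' DNA-binding-domain family vocabulary
#'
#' The default family vocabulary: the 14 DBD families with more than five
#' members in the fly TF repertoire (the zf-C2H2 zinc finger split into
#' plain and zinc-finger-associated-domain, "zf-AD", carrying subfamilies),
#' plus `"other"` for recognized but rare domains and `"none"` for
#' literature-curated TFs without a recognized DBD (and for non-TF genes).
#'
#' @return Character vector of family labels.
#' @export
dbd_families <- function() {
  c("zf-C2H2", "zf-C2H2+zf-AD", "Homeobox", "HLH", "zf-C4", "BESS",
    "Forkhead", "bZIP1", "bZIP2", "Ets", "T-box", "GATA", "HMG", "HTH",
    "other", "none")
}

#' Construct a gene catalog
#'
#' The gene catalog is the universe for every resampling test in the
#' package: all genes with expression information, flagged as TF or non-TF,
#' with a DBD family label for TFs.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param symbol display symbols (defaults to `gene_id`).
#' @param is_tf logical vector.
#' @param dbd_family family labels; must be drawn from `families`. Non-TFs
#'   must be `"none"`. A TF may be `"none"` (curated TF without a recognized
#'   DBD) but is then skipped by family-level analyses.
#' @param families the allowed family vocabulary.
#' @return A data.frame of class `gene_catalog`.
#' @export
gene_catalog <- function(gene_id, symbol = gene_id, is_tf,
                         dbd_family = ifelse(is_tf, "other", "none"),
                         families = dbd_families()) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    stop("duplicate gene_id in catalog: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  is_tf <- as.logical(is_tf)
  if (anyNA(is_tf)) stop("is_tf must be TRUE/FALSE", call. = FALSE)
  dbd_family <- as.character(dbd_family)
  bad <- setdiff(unique(dbd_family), families)
  if (length(bad))
    stop("unknown dbd_family label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(!is_tf & dbd_family != "none"))
    stop("non-TF genes must have dbd_family 'none'", call. = FALSE)
  structure(
    data.frame(gene_id = gene_id, symbol = as.character(symbol),
               is_tf = is_tf, dbd_family = dbd_family,
               stringsAsFactors = FALSE),
    class = c("gene_catalog", "data.frame")
  )
}

#' Read a gene catalog from TSV
#'
#' Expects a header with at least `gene_id`, `is_tf`, `dbd_family`
#' (optionally `symbol`). `is_tf` may be coded as TRUE/FALSE or 0/1.
#'
#' @param path path to a tab-separated file.
#' @param families allowed family vocabulary.
#' @return A `gene_catalog`.
#' @export
read_gene_catalog <- function(path, families = dbd_families()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE)
  for (col in c("gene_id", "is_tf", "dbd_family")) {
    if (!col %in% names(df))
      stop("catalog file is missing required column '", col, "'",
           call. = FALSE)
  }
  is_tf <- toupper(df$is_tf) %in% c("TRUE", "T", "1")
  ok <- toupper(df$is_tf) %in% c("TRUE", "T", "1", "FALSE", "F", "0")
  if (!all(ok))
    stop("unparseable is_tf value(s): ",
         paste(unique(df$is_tf[!ok]), collapse = ", "), call. = FALSE)
  sym <- if ("symbol" %in% names(df)) df$symbol else df$gene_id
  gene_catalog(df$gene_id, sym, is_tf, df$dbd_family, families = families)
}

#' Write a gene catalog to TSV
#' @param catalog a `gene_catalog`.
#' @param path output path.
#' @export
write_gene_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
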