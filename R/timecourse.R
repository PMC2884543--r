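#' Construct a time-course matrix
#'
#' Per-gene log-ratio expression values (relative to a pooled all-stages
#' reference) over an increasing axis of timepoints in hours AEL.
#'
#' @param genes character vector of gene ids (unique).
#' @param hours numeric vector of timepoints (strictly increasing).
#' @param values numeric gene x timepoint matrix (finite or NA).
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(genes, hours, values) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene ids", call. = FALSE)
  if (length(hours) == 0L) stop("empty timepoint list", call. = FALSE)
  if (any(diff(hours) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  values <- as.matrix(values)
  if (nrow(values) != length(genes) || ncol(values) != length(hours))
    stop("values must be gene x timepoint", call. = FALSE)
  if (any(is.infinite(values)))
    stop("values must be finite or NA", call. = FALSE)
  dimnames(values) <- list(genes, paste0("h", hours))
  structure(list(genes = genes, hours = hours, values = values),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("timecourse:", length(x$genes), "genes x", length(x$hours),
      "timepoints (", min(x$hours), "-", max(x$hours), "h AEL )\n")
  invisible(x)
}

#' Read a time-course matrix from wide TSV
#'
#' Header: `gene_id` then one `h<hours>` column per timepoint.
#'
#' @param path path to the TSV file.
#' @return A [timecourse()].
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE)
  if (!"gene_id" %in% names(df))
    stop("time-course file is missing column 'gene_id'", call. = FALSE)
  hcols <- grep("^h[0-9.]+$", names(df), value = TRUE)
  if (!length(hcols))
    stop("time-course file has no h<hours> columns", call. = FALSE)
  hours <- as.numeric(sub("^h", "", hcols))
  timecourse(df$gene_id, hours, as.matrix(df[hcols]))
}

#' Write a time-course matrix as wide TSV
#' @param tc a [timecourse()].
#' @param path output path.
#' @export
write_timecourse <- function(tc, path) {
  df <- data.frame(gene_id = tc$genes, tc$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
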