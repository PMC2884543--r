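#' Read a BED3 peak file
#'
#' Reads BED intervals (0-based half-open) into a `GRanges` (1-based
#' closed). Zero- and negative-length intervals are rejected with the
#' offending line number. Strand is ignored throughout: the overlap rules
#' used downstream are strand-free.
#'
#' @param path path to a BED3+ file (no header; extra columns ignored).
#' @return A `GRanges` sorted by (contig, start); overlapping intervals are
#'   retained (merging is a downstream operation).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(GenomicRanges::GRanges())
  }
  ln <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", ln[which(nf < 3L)[1]], " has fewer than 3 fields",
         call. = FALSE)
  contig <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("non-numeric coordinates at BED line ", ln[bad[1]], call. = FALSE)
  bad <- which(start0 < 0)
  if (length(bad))
    stop("negative start coordinate at BED line ", ln[bad[1]], call. = FALSE)
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("empty or inverted interval (start >= end) at BED line ",
         ln[bad[1]], call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
  GenomicRanges::sort(gr)
}

#' Write a `GRanges` as BED3
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
write_peaks <- function(gr, path) {
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
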