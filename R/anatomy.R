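#' Embryonic stage-range axis
#'
#' The discrete time axis used throughout the package: six windows of
#' embryonic stages, as used by large-scale in situ annotation databases.
#' Each window is mapped to an approximate interval in hours after egg lay
#' (AEL) so that array timepoints can be aligned with the in situ axis.
#'
#' @return A data.frame with columns `index` (1..6), `label`
#'   (`"1-3"` ... `"13-16"`), and `hours_start`/`hours_end` (approximate AEL).
#' @export
#' @examples
#' stage_ranges()
stage_ranges <- function() {
  data.frame(
    index = 1:6,
    label = c("1-3", "4-6", "7-8", "9-10", "11-12", "13-16"),
    hours_start = c(0, 2, 4, 6, 8, 10),
    hours_end   = c(2, 4, 6, 8, 10, 16),
    stringsAsFactors = FALSE
  )
}

#' Stage-range labels
#' @return Character vector of the six stage-range labels, in temporal order.
#' @export
stage_labels <- function() stage_ranges()$label

N_STAGES <- 6L

#' Convert stage labels to indices
#'
#' @param labels character vector of stage-range labels.
#' @return Integer vector of stage indices (1..6).
#' @keywords internal
stage_index <- function(labels) {
  idx <- match(labels, stage_labels())
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown stage range label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Construct a slim anatomy vocabulary
#'
#' A slim anatomy is a reduced anatomical ontology: a flat list of tissue
#' terms, each mapped to a germ-layer/lineage category, plus the
#' distinguished term `"ubiquitous"` used for genes stained throughout the
#' embryo.
#'
#' @param terms character vector of term identifiers; must contain
#'   `"ubiquitous"` exactly once and no duplicates.
#' @param lineage named character vector mapping every term to a lineage
#'   category (total over `terms`).
#' @return An object of class `slim_anatomy` with elements `terms` and
#'   `lineage`.
#' @export
slim_anatomy <- function(terms, lineage) {
  terms <- as.character(terms)
  if (anyDuplicated(terms))
    stop("anatomy terms must be unique", call. = FALSE)
  if (sum(terms == "ubiquitous") != 1L)
    stop("anatomy must contain the term 'ubiquitous' exactly once",
         call. = FALSE)
  if (!all(terms %in% names(lineage)))
    stop("lineage map must be total over terms; missing: ",
         paste(setdiff(terms, names(lineage)), collapse = ", "),
         call. = FALSE)
  structure(
    list(terms = terms, lineage = lineage[terms]),
    class = "slim_anatomy"
  )
}

#' Default slim anatomy (~30 terms)
#'
#' A compact tissue vocabulary emulating the slim representation of the
#' embryonic anatomical ontology: germ layers, their major derivatives, the
#' nervous system, extra-embryonic tissues, and the distinguished
#' `"ubiquitous"` term.
#'
#' @return A `slim_anatomy` object with 30 terms.
#' @export
default_slim_anatomy <- function() {
  spec <- c(
    ubiquitous             = "ubiquitous",
    mesoderm               = "mesoderm",
    `trunk mesoderm`       = "mesoderm",
    `cardiac mesoderm`     = "mesoderm",
    `visceral mesoderm`    = "mesoderm",
    musculature            = "mesoderm",
    `fat body`             = "mesoderm",
    gonad                  = "mesoderm",
    ectoderm               = "ectoderm",
    `procephalic ectoderm` = "ectoderm",
    `dorsal ectoderm`      = "ectoderm",
    `ventral ectoderm`     = "ectoderm",
    `dorsal epidermis`     = "ectoderm",
    `ventral epidermis`    = "ectoderm",
    `head epidermis`       = "ectoderm",
    `tracheal system`      = "ectoderm",
    `salivary gland`       = "ectoderm",
    mesectoderm            = "mesectoderm",
    `ventral nerve cord`   = "mesectoderm",
    brain                  = "neural",
    `peripheral nervous system` = "neural",
    `sensory organs`       = "neural",
    endoderm               = "endoderm",
    midgut                 = "endoderm",
    hindgut                = "endoderm",
    foregut                = "endoderm",
    `malpighian tubules`   = "endoderm",
    `amnioserosa`          = "extraembryonic",
    yolk                   = "extraembryonic",
    `pole cells`           = "germline"
  )
  slim_anatomy(names(spec), spec)
}

#' @export
print.slim_anatomy <- function(x, ...) {
  cat("slim anatomy:", length(x$terms), "terms (",
      length(unique(x$lineage)), "lineages )\n")
  invisible(x)
}
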