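#' Expression-call thresholds
#'
#' Bundle of the thresholds used by the four expression-call rules:
#' the log-ratio cut points for the embryonic time-course reclassification,
#' the replicate-vote minima for present/absent arrays, and the minimum
#' coding-region coverage fraction for transcribed-fragment (transfrag)
#' evidence.
#'
#' @param low_cut values strictly below this are "low" (default -0.5).
#' @param high_cut values strictly above this are "high" (default +0.5);
#'   the boundary values fall into "average".
#' @param min_present_of_3 present calls required out of 3 replicates
#'   (GeneChip-style rule; default 2).
#' @param min_present_of_4 present calls required out of 4 replicates
#'   (adult-tissue-array rule; default 3).
#' @param min_transfrag_frac minimum fraction of a gene's coding region
#'   covered by transfrags (default 0.10; boundary inclusive).
#' @return A list of class `call_thresholds`.
#' @export
call_thresholds <- function(low_cut = -0.5, high_cut = 0.5,
                            min_present_of_3 = 2L, min_present_of_4 = 3L,
                            min_transfrag_frac = 0.10) {
  if (!(low_cut < high_cut)) stop("low_cut must be < high_cut", call. = FALSE)
  if (min_present_of_3 < 1L || min_present_of_3 > 3L)
    stop("min_present_of_3 must be in 1..3", call. = FALSE)
  if (min_present_of_4 < 1L || min_present_of_4 > 4L)
    stop("min_present_of_4 must be in 1..4", call. = FALSE)
  if (min_transfrag_frac <= 0 || min_transfrag_frac > 1)
    stop("min_transfrag_frac must be in (0, 1]", call. = FALSE)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 min_present_of_3 = as.integer(min_present_of_3),
                 min_present_of_4 = as.integer(min_present_of_4),
                 min_transfrag_frac = min_transfrag_frac),
            class = "call_thresholds")
}

#' Classify time-course log-ratios into low/average/high
#'
#' Reclassifies per-timepoint log-ratio values (relative to a pooled
#' all-stages reference) into three bands: "low" (value < low_cut),
#' "average" (low_cut <= value <= high_cut) and "high" (value > high_cut).
#' Missing values yield an explicit `"no_call"`, never a silent "average".
#'
#' @param v numeric vector of log-ratio values (NA allowed).
#' @param thresholds a [call_thresholds()].
#' @return Character vector in `{"low","average","high","no_call"}`.
#' @export
#' @examples
#' classify_timecourse_value(c(0.72, 0.14, -0.5, NA))
classify_timecourse_value <- function(v, thresholds = call_thresholds()) {
  out <- rep("average", length(v))
  out[!is.na(v) & v < thresholds$low_cut] <- "low"
  out[!is.na(v) & v > thresholds$high_cut] <- "high"
  out[is.na(v)] <- "no_call"
  out
}

#' Replicate-vote expression rule
#'
#' A gene is expressed iff it received at least `k_required` present calls
#' among its replicates.
#'
#' @param calls character vector of `"present"`/`"absent"` (or logical).
#' @param k_required minimum number of present calls.
#' @return Logical scalar.
#' @export
expressed_by_replicates <- function(calls, k_required) {
  if (length(calls) == 0L) stop("no replicate calls given", call. = FALSE)
  if (k_required > length(calls))
    stop("k_required (", k_required, ") exceeds replicate count (",
         length(calls), ")", call. = FALSE)
  if (is.character(calls)) {
    bad <- setdiff(unique(calls), c("present", "absent", "P", "A"))
    if (length(bad))
      stop("unknown call value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    calls <- calls %in% c("present", "P")
  }
  sum(calls) >= k_required
}

#' Transfrag-coverage expression rule
#'
#' A gene is expressed iff at least `min_transfrag_frac` of its coding
#' region overlaps transcribed fragments. In the default `"union"` mode the
#' covered fraction is the length of the union of all (cds intersect
#' transfrag) pieces over the total cds length, so abutting transfrag
#' pieces behave like one; in `"single"` mode a single transfrag alone must
#' reach the threshold.
#'
#' @param cds `GRanges` of the gene's coding intervals; must be disjoint
#'   (pre-merged) and nonempty.
#' @param transfrags `GRanges` of transcribed fragments.
#' @param thresholds a [call_thresholds()].
#' @param mode `"union"` (default) or `"single"`.
#' @return Logical scalar.
#' @export
expressed_by_transfrags <- function(cds, transfrags,
                                    thresholds = call_thresholds(),
                                    mode = c("union", "single")) {
  mode <- match.arg(mode)
  if (length(cds) == 0L)
    stop("gene has an empty coding region", call. = FALSE)
  if (!IRanges::isDisjoint(cds))
    stop("cds intervals must be disjoint (pre-merged)", call. = FALSE)
  total <- sum(GenomicRanges::width(cds))
  if (total == 0L) stop("total coding length is zero", call. = FALSE)
  frac <- thresholds$min_transfrag_frac
  if (mode == "union") {
    hit <- GenomicRanges::intersect(cds, GenomicRanges::reduce(transfrags),
                                    ignore.strand = TRUE)
    sum(GenomicRanges::width(hit)) / total >= frac
  } else {
    if (length(transfrags) == 0L) return(FALSE)
    covered <- vapply(seq_along(transfrags), function(i) {
      hit <- GenomicRanges::intersect(cds, transfrags[i],
                                      ignore.strand = TRUE)
      sum(GenomicRanges::width(hit))
    }, numeric(1))
    max(covered) / total >= frac
  }
}

#' Adult-tissue-array expression rule
#'
#' A gene is expressed in an adult tissue iff it received at least three of
#' four present calls, or was significantly up-regulated relative to whole
#' flies (an "up" call) -- a disjunction, so an "up" call alone suffices.
#'
#' @param present character or logical vector of exactly 4 replicate calls.
#' @param direction one of `"up"`, `"down"`, `"none"`.
#' @param thresholds a [call_thresholds()].
#' @return Logical scalar.
#' @export
flyatlas_expressed <- function(present, direction = c("none", "up", "down"),
                               thresholds = call_thresholds()) {
  direction <- match.arg(direction)
  if (length(present) != 4L)
    stop("adult-tissue rule requires exactly 4 replicate calls",
         call. = FALSE)
  expressed_by_replicates(present, thresholds$min_present_of_4) ||
    direction == "up"
}

#' Construct a replicate-level call table
#'
#' Holds per-replicate present/absent detection calls and per-tissue
#' up/down differential calls (relative to a whole-body reference) for a
#' set of genes over a set of tissues.
#'
#' @param genes character vector of gene ids (unique).
#' @param tissues character vector of tissue names (unique).
#' @param present logical array `gene x tissue x replicate` (`TRUE` =
#'   present).
#' @param direction character matrix `gene x tissue` in
#'   `{"up","down","none"}`.
#' @return An object of class `call_table`.
#' @export
call_table <- function(genes, tissues, present, direction) {
  genes <- as.character(genes); tissues <- as.character(tissues)
  if (anyDuplicated(genes) || anyDuplicated(tissues))
    stop("genes and tissues must be unique", call. = FALSE)
  d <- dim(present)
  if (length(d) != 3L || d[1] != length(genes) || d[2] != length(tissues))
    stop("present must be a gene x tissue x replicate array", call. = FALSE)
  if (!identical(dim(direction), c(length(genes), length(tissues))))
    stop("direction must be a gene x tissue matrix", call. = FALSE)
  bad <- setdiff(unique(as.vector(direction)), c("up", "down", "none"))
  if (length(bad))
    stop("unknown direction value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dimnames(present) <- list(genes, tissues, NULL)
  dimnames(direction) <- list(genes, tissues)
  structure(list(genes = genes, tissues = tissues,
                 present = present, direction = direction,
                 n_replicates = d[3]),
            class = "call_table")
}

#' @export
print.call_table <- function(x, ...) {
  cat("call_table:", length(x$genes), "genes x", length(x$tissues),
      "tissues x", x$n_replicates, "replicates\n")
  invisible(x)
}

#' Apply the adult-tissue expression rule to a whole call table
#'
#' @param ct a [call_table()] (4 replicates expected for the default rule).
#' @param thresholds a [call_thresholds()].
#' @return Logical gene x tissue matrix of expressed calls.
#' @export
call_table_expressed <- function(ct, thresholds = call_thresholds()) {
  k <- if (ct$n_replicates == 3L) thresholds$min_present_of_3
       else thresholds$min_present_of_4
  votes <- apply(ct$present, c(1, 2), sum)
  votes >= k | ct$direction == "up"
}

#' Up-call matrix of a call table
#' @param ct a [call_table()].
#' @return Logical gene x tissue matrix (`TRUE` where direction is "up").
#' @export
call_table_up <- function(ct) ct$direction == "up"

#' Read a call table from wide TSV
#'
#' Expected header: `gene_id`, `tissue`, `present_1` .. `present_k`
#' (values `P`/`A`), `direction`.
#'
#' @param path path to the TSV.
#' @return A `call_table`.
#' @export
read_call_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", check.names = FALSE)
  rep_cols <- grep("^present_[0-9]+$", names(df), value = TRUE)
  for (col in c("gene_id", "tissue", "direction"))
    if (!col %in% names(df))
      stop("call table file is missing column '", col, "'", call. = FALSE)
  if (!length(rep_cols))
    stop("call table file has no present_<k> columns", call. = FALSE)
  genes <- sort(unique(df$gene_id)); tissues <- sort(unique(df$tissue))
  k <- length(rep_cols)
  present <- array(FALSE, c(length(genes), length(tissues), k))
  direction <- matrix("none", length(genes), length(tissues))
  gi <- match(df$gene_id, genes); ti <- match(df$tissue, tissues)
  for (r in seq_len(k))
    present[cbind(gi, ti, r)] <- df[[rep_cols[r]]] %in% c("P", "present")
  direction[cbind(gi, ti)] <- df$direction
  call_table(genes, tissues, present, direction)
}

#' Write a call table to wide TSV
#' @param ct a [call_table()].
#' @param path output path.
#' @export
write_call_table <- function(ct, path) {
  grid <- expand.grid(gene_id = ct$genes, tissue = ct$tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(grid$gene_id, ct$genes); ti <- match(grid$tissue, ct$tissues)
  out <- grid
  for (r in seq_len(ct$n_replicates))
    out[[paste0("present_", r)]] <-
      ifelse(ct$present[cbind(gi, ti, r)], "P", "A")
  out$direction <- ct$direction[cbind(gi, ti)]
  out <- out[order(out$gene_id, out$tissue), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
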