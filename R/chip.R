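OCC_STATES <- c("A_only", "B_only", "double", "none")

#' Build the site universe from ChIP peak sets
#'
#' Single-linkage merge of all peaks of both factors at both timepoints:
#' any two peaks sharing at least `min_overlap` bases (transitively) fall
#' into one region. The resulting disjoint regions are the denominator of
#' all occupancy-state fractions; partial or complete peak overlap is read
#' as common action of the factors within the region, since there is no
#' accepted definition of cis-regulatory module boundaries.
#'
#' @param peaks a `GRanges`, or a list of `GRanges` which are concatenated.
#' @param min_overlap minimum shared bases for two peaks to merge
#'   (default 1; abutting half-open intervals do not merge).
#' @return `GRanges` of disjoint, sorted regions (empty input gives an
#'   empty universe).
#' @export
build_site_universe <- function(peaks, min_overlap = 1L) {
  if (is.list(peaks) && !inherits(peaks, "GRanges"))
    peaks <- do.call(c, unname(peaks))
  if (length(peaks) == 0L) return(GenomicRanges::GRanges())
  # reduce() merges intervals that overlap or touch; with min.gapwidth = 0
  # only true overlap (>= 1 shared base) merges. Larger min_overlap is
  # enforced by shrinking both ends before merging and restoring after.
  if (min_overlap == 1L) {
    GenomicRanges::reduce(peaks, min.gapwidth = 0L, ignore.strand = TRUE)
  } else {
    sh <- as.integer(min_overlap) - 1L
    shrunk <- GenomicRanges::resize(peaks,
                                    pmax(GenomicRanges::width(peaks) - sh, 1L),
                                    fix = "center")
    merged <- GenomicRanges::reduce(shrunk, min.gapwidth = 0L,
                                    ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(peaks, merged)
    GenomicRanges::reduce(
      unlist(range(S4Vectors::split(
        peaks[S4Vectors::queryHits(hits)],
        S4Vectors::subjectHits(hits)))),
      min.gapwidth = 0L, ignore.strand = TRUE)
  }
}

#' Occupancy state of each region at one timepoint
#'
#' A factor occupies a region iff at least one of its peaks overlaps it.
#'
#' @param universe `GRanges` of disjoint site regions
#'   (from [build_site_universe()]).
#' @param peaks_a,peaks_b `GRanges` of the two factors' peaks at the
#'   timepoint.
#' @param check if `TRUE` (default), error when a peak overlaps no region
#'   (the universe was not built from these peak families).
#' @return Character vector (one state per region) in
#'   `{"A_only","B_only","double","none"}`.
#' @export
occupancy_states <- function(universe, peaks_a, peaks_b, check = TRUE) {
  if (check) {
    for (p in list(peaks_a, peaks_b)) {
      if (length(p) &&
          !all(IRanges::overlapsAny(p, universe, ignore.strand = TRUE)))
        stop("peak outside the site universe: universe and peaks are ",
             "inconsistent", call. = FALSE)
    }
  }
  a <- IRanges::overlapsAny(universe, peaks_a, ignore.strand = TRUE)
  b <- IRanges::overlapsAny(universe, peaks_b, ignore.strand = TRUE)
  out <- rep("none", length(universe))
  out[a & !b] <- "A_only"
  out[!a & b] <- "B_only"
  out[a & b] <- "double"
  out
}

#' Occupancy-state transition fractions between two timepoints
#'
#' Cross-tabulates the per-region occupancy states at two timepoints over
#' the same site universe. Rows are origin (t1) states and are normalized
#' to sum to 1; origin states with zero regions yield an all-NA row.
#' Summary fractions are reported against two denominators (the ambiguity
#' between them is inherent to percentage statements about "occupied
#' sites"): regions occupied at either timepoint (`ever_occupied`) and
#' regions occupied at t1.
#'
#' @param states_t1,states_t2 character vectors of states (same length,
#'   same region order).
#' @return A list of class `occupancy_transitions` with `counts` (4x4
#'   integer matrix), `fractions` (row-normalized), `n_regions`,
#'   `n_ever_occupied`, `state_fractions` (data.frame: per state and
#'   timepoint, fraction of ever-occupied regions), and
#'   `frac_double_t2_of_t1_occupied`.
#' @export
transition_fractions <- function(states_t1, states_t2) {
  if (length(states_t1) != length(states_t2))
    stop("state vectors must cover the same region universe", call. = FALSE)
  for (s in list(states_t1, states_t2)) {
    bad <- setdiff(unique(s), OCC_STATES)
    if (length(bad))
      stop("unknown occupancy state(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  t1 <- factor(states_t1, levels = OCC_STATES)
  t2 <- factor(states_t2, levels = OCC_STATES)
  counts <- table(t1, t2)
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(from = OCC_STATES, to = OCC_STATES))
  rs <- rowSums(counts)
  fractions <- counts / ifelse(rs > 0, rs, NA_real_)
  ever <- states_t1 != "none" | states_t2 != "none"
  n_ever <- sum(ever)
  state_fractions <- do.call(rbind, lapply(c("t1", "t2"), function(tp) {
    st <- if (tp == "t1") states_t1 else states_t2
    data.frame(timepoint = tp, state = OCC_STATES,
               fraction = if (n_ever > 0)
                 as.vector(table(factor(st[ever], levels = OCC_STATES))) /
                   n_ever
               else rep(0, 4),
               stringsAsFactors = FALSE)
  }))
  occ1 <- states_t1 != "none"
  structure(list(
    counts = counts, fractions = fractions,
    n_regions = length(states_t1), n_ever_occupied = n_ever,
    state_fractions = state_fractions,
    frac_double_t2_of_t1_occupied =
      if (sum(occ1) > 0) mean(states_t2[occ1] == "double") else NA_real_
  ), class = "occupancy_transitions")
}

#' @export
print.occupancy_transitions <- function(x, ...) {
  cat("occupancy_transitions:", x$n_regions, "regions,",
      x$n_ever_occupied, "ever occupied\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Full ChIP co-occupancy analysis from four peak sets
#'
#' Convenience wrapper: builds the site universe from all four peak sets,
#' derives per-region states at both timepoints, and computes transition
#' fractions.
#'
#' @param peaks_a_t1,peaks_b_t1,peaks_a_t2,peaks_b_t2 `GRanges` peak sets
#'   (factor x timepoint).
#' @param min_overlap see [build_site_universe()].
#' @return A list with `universe`, `states_t1`, `states_t2`, `transitions`.
#' @export
chip_cooccupancy <- function(peaks_a_t1, peaks_b_t1, peaks_a_t2, peaks_b_t2,
                             min_overlap = 1L) {
  universe <- build_site_universe(
    list(peaks_a_t1, peaks_b_t1, peaks_a_t2, peaks_b_t2), min_overlap)
  s1 <- occupancy_states(universe, peaks_a_t1, peaks_b_t1)
  s2 <- occupancy_states(universe, peaks_a_t2, peaks_b_t2)
  list(universe = universe, states_t1 = s1, states_t2 = s2,
       transitions = transition_fractions(s1, s2))
}
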