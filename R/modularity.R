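#' Partition genes by exact co-expression at one stage
#'
#' Groups the genes expressed at a stage by exact equality of their slim
#' term sets: two genes fall in the same group iff they are annotated in
#' precisely the same tissues at that stage ("precise co-expression", the
#' minimal requirement for a co-expression module). Genes with empty term
#' sets are excluded.
#'
#' @param m a `stage_tissue_matrix`.
#' @param stage stage index (1..6) or stage-range label.
#' @param genes optional character vector restricting the partition to a
#'   gene subset.
#' @return An object of class `coexpression_partition` with elements
#'   `stage`, `membership` (named integer vector gene -> group id) and
#'   `groups` (list of gene-id vectors).
#' @export
coexpression_partition <- function(m, stage, genes = NULL) {
  if (is.character(stage)) stage <- stage_index(stage)
  sets <- stm_sets(m, stage)
  if (!is.null(genes)) sets <- sets[intersect(names(sets), genes)]
  if (!length(sets)) {
    return(structure(list(stage = stage,
                          membership = stats::setNames(integer(), character()),
                          groups = list()),
                     class = "coexpression_partition"))
  }
  key <- vapply(sets, paste, "", collapse = "\r")
  ids <- match(key, unique(key))
  structure(list(stage = stage,
                 membership = stats::setNames(ids, names(sets)),
                 groups = split(names(sets), ids)),
            class = "coexpression_partition")
}

#' @export
print.coexpression_partition <- function(x, ...) {
  cat("coexpression_partition: stage", x$stage, "--",
      length(x$membership), "genes in", length(x$groups), "groups\n")
  invisible(x)
}

check_k <- function(k) {
  if (!k %in% c(2L, 3L))
    stop("comodule size k must be 2 or 3", call. = FALSE)
  as.integer(k)
}

#' Count co-expression modules of size k
#'
#' The number of unordered pairs (k = 2) or triplets (k = 3) of genes that
#' share a group, i.e. the sum of `choose(|group|, k)` over the partition.
#'
#' @param partition a [coexpression_partition()].
#' @param k 2 or 3.
#' @return Integer count.
#' @export
count_comodules <- function(partition, k) {
  k <- check_k(k)
  as.integer(sum(choose(lengths(partition$groups), k)))
}

# conserved-pair/triplet count for aligned integer group-id vectors
conserved_count_ids <- function(a, b, k) {
  if (!length(a)) return(0L)
  key <- (a - 1) * (max(b) + 1) + b
  as.integer(sum(choose(tabulate(match(key, unique(key))), k)))
}

#' Count comodules conserved between two stages
#'
#' A k-subset of genes is conserved iff its members share a group in the
#' earlier partition AND share a group in the later one; equivalently the
#' sum of `choose(cell, k)` over the cells of the partition intersection,
#' restricted to genes present (expressed) in both partitions.
#'
#' @param p_s,p_s1 partitions of consecutive stages
#'   (from [coexpression_partition()]).
#' @param k 2 or 3.
#' @return Integer count.
#' @export
conserved_comodules <- function(p_s, p_s1, k) {
  k <- check_k(k)
  common <- intersect(names(p_s$membership), names(p_s1$membership))
  conserved_count_ids(unname(p_s$membership[common]),
                      unname(p_s1$membership[common]), k)
}

#' Permutation Z score for comodule conservation
#'
#' Holds the earlier-stage partition fixed and, in each iteration,
#' reshuffles which gene carries which row of the later-stage pairing
#' matrix (a uniform permutation of gene labels within the set of genes
#' expressed at the later stage), recounting conserved comodules. The
#' observed conserved count is standardized against this null.
#'
#' @param p_s,p_s1 partitions of consecutive stages.
#' @param k 2 or 3.
#' @param n_iter number of reshuffles (default 1000).
#' @param seed optional integer seed.
#' @return One-row data.frame (`module_stats`): `from_stage`, `to_stage`,
#'   `k`, `observed`, `null_mean`, `null_sd`, `z`, `degenerate`,
#'   `n_iterations`.
#' @export
permutation_z <- function(p_s, p_s1, k, n_iter = 1000L, seed = NULL) {
  k <- check_k(k)
  n_iter <- as.integer(n_iter)
  if (n_iter < 2L) stop("n_iter must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  observed <- conserved_comodules(p_s, p_s1, k)
  genes1 <- names(p_s1$membership)
  b_vals <- unname(p_s1$membership)
  common <- intersect(names(p_s$membership), genes1)
  a <- unname(p_s$membership[common])
  pos <- match(common, genes1)
  null_counts <- vapply(seq_len(n_iter), function(i) {
    b_perm <- b_vals[sample.int(length(b_vals))]
    conserved_count_ids(a, b_perm[pos], k)
  }, numeric(1))
  mu <- mean(null_counts); sd <- stats::sd(null_counts)
  degenerate <- !is.finite(sd) || sd == 0
  data.frame(from_stage = p_s$stage, to_stage = p_s1$stage, k = k,
             observed = observed, null_mean = mu, null_sd = sd,
             z = if (degenerate) NA_real_ else (observed - mu) / sd,
             degenerate = degenerate, n_iterations = n_iter)
}

#' Conservation Z scores for all consecutive stage transitions
#'
#' @param m a `stage_tissue_matrix`.
#' @param genes optional gene subset (e.g. the TFs).
#' @param k 2 or 3.
#' @param n_iter reshuffles per transition.
#' @param seed optional integer seed.
#' @return data.frame with one `module_stats` row per transition.
#' @export
conservation_z_all <- function(m, genes = NULL, k = 2L, n_iter = 1000L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(seq_len(N_STAGES), coexpression_partition, m = m,
                  genes = genes)
  do.call(rbind, lapply(seq_len(N_STAGES - 1L), function(s) {
    permutation_z(parts[[s]], parts[[s + 1L]], k, n_iter, seed = NULL)
  }))
}

#' Random-gene-set conservation baseline
#'
#' Repeats the conservation analysis on random gene sets of a fixed size
#' drawn from the annotated universe (TF and non-TF alike), giving the
#' background distribution of conservation Z scores against which the
#' TF-only scores are read.
#'
#' @param m a `stage_tissue_matrix`.
#' @param catalog a `gene_catalog`.
#' @param set_size genes per random set (default 373).
#' @param n_rep number of random sets (default 100).
#' @param k 2 or 3.
#' @param n_iter reshuffles per permutation test.
#' @param seed optional integer seed.
#' @return data.frame with columns `rep`, `from_stage`, `to_stage`, `k`,
#'   `observed`, `z`, ... (one row per rep x transition).
#' @export
random_geneset_baseline <- function(m, catalog, set_size = 373L,
                                    n_rep = 100L, k = 2L, n_iter = 1000L,
                                    seed = NULL) {
  annotated <- unique(m$ann$gene_id)
  if (set_size > length(annotated))
    stop("set_size exceeds number of annotated genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_rep), function(r) {
    genes <- sample(annotated, set_size)
    res <- conservation_z_all(m, genes = genes, k = k, n_iter = n_iter)
    res$rep <- r
    res
  })
  do.call(rbind, out)
}

#' Pairwise TF co-occurrence across stages
#'
#' For every pair of TFs with expression information, the fraction of the
#' six stage ranges at which their term sets intersect (co-occurrence in at
#' least one tissue). Also reports the potential-pair counts: the exact
#' `choose(n, 2)` and the coarse `n^2/2` approximation.
#'
#' @param m a `stage_tissue_matrix`.
#' @param catalog a `gene_catalog`.
#' @return A list of class `cooccurrence` with `fraction` (symmetric TF x
#'   TF matrix, diagonal set to 1 by convention), `n_tf`,
#'   `potential_pairs_exact`, `potential_pairs_approx`, and
#'   `frac_pairs_cooccurring` (share of distinct pairs with fraction > 0).
#' @export
pairwise_cooccurrence <- function(m, catalog) {
  tfs <- intersect(unique(m$ann$gene_id), catalog$gene_id[catalog$is_tf])
  n <- length(tfs)
  if (n < 2L) stop("need at least two annotated TFs", call. = FALSE)
  tfs <- sort(tfs)
  counts <- matrix(0L, n, n, dimnames = list(tfs, tfs))
  for (s in seq_len(N_STAGES)) {
    rows <- m$ann[m$ann$stage == s & m$ann$gene_id %in% tfs, ]
    if (!nrow(rows)) next
    inc <- table(factor(rows$gene_id, levels = tfs),
                 factor(rows$term, levels = m$anatomy$terms))
    inc <- (unclass(inc) > 0) * 1L
    counts <- counts + ((inc %*% t(inc)) > 0)
  }
  fraction <- counts / N_STAGES
  diag(fraction) <- 1
  off <- fraction[upper.tri(fraction)]
  structure(list(fraction = fraction, n_tf = n,
                 potential_pairs_exact = choose(n, 2),
                 potential_pairs_approx = n^2 / 2,
                 frac_pairs_cooccurring = mean(off > 0)),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("cooccurrence:", x$n_tf, "TFs;",
      x$potential_pairs_exact, "pairs (approx", x$potential_pairs_approx,
      ");", sprintf("%.1f%%", 100 * x$frac_pairs_cooccurring),
      "co-occur at >=1 stage\n")
  invisible(x)
}
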