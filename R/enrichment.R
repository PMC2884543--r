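#' Resampling null configuration
#'
#' @param n_iterations number of random draws for sampling-based nulls
#'   (default 10000).
#' @param seed integer seed for the draws (optional; if `NULL` the current
#'   RNG state is used).
#' @return A list of class `sampling_null`.
#' @export
sampling_null <- function(n_iterations = 10000L, seed = NULL) {
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  structure(list(n_iterations = n_iterations, seed = seed),
            class = "sampling_null")
}

universe_counts <- function(universe) {
  if (inherits(universe, "gene_catalog") || is.data.frame(universe)) {
    list(N = nrow(universe), K = sum(universe$is_tf))
  } else if (is.list(universe) && all(c("N", "K") %in% names(universe))) {
    list(N = universe$N, K = universe$K)
  } else stop("universe must be a gene_catalog or list(N=, K=)",
              call. = FALSE)
}

enrichment_result <- function(n_tf, n_nontf, expected, null_sd, z,
                              z_threshold, method,
                              stage = NA_integer_, term = NA_character_) {
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else z
  data.frame(stage = stage, term = term,
             n_tf = n_tf, n_nontf = n_nontf,
             expected_tf = expected, null_sd = null_sd, z = z,
             significant = !degenerate && is.finite(z) && z >= z_threshold,
             degenerate = degenerate, method = method,
             stringsAsFactors = FALSE)
}

#' Analytic (hypergeometric) TF over-representation Z score
#'
#' Exact closed form for the null distribution of the number of TFs in a
#' draw of `n_tf + n_nontf` genes without replacement from the universe:
#' hypergeometric with mean `d*K/N` and variance
#' `d*(K/N)*(1-K/N)*(N-d)/(N-1)` (`d` = draw size, `K` = number of TFs,
#' `N` = universe size). Serves as the independent oracle for the
#' sampling-based score.
#'
#' @param n_tf observed number of TFs expressed in the tissue.
#' @param n_nontf observed number of non-TFs expressed in the tissue.
#' @param universe a `gene_catalog` (or `list(N=, K=)` of universe size and
#'   TF count).
#' @param z_threshold significance cut (default 3; a tissue is called
#'   over-represented iff z >= 3).
#' @return One-row data.frame with `n_tf`, `n_nontf`, `expected_tf`,
#'   `null_sd`, `z`, `significant`, `degenerate`.
#' @export
#' @examples
#' enrichment_z_analytic(20, 100, list(N = 1000, K = 50))  # z = 6.248
enrichment_z_analytic <- function(n_tf, n_nontf, universe, z_threshold = 3) {
  u <- universe_counts(universe)
  N <- u$N; K <- u$K; d <- n_tf + n_nontf
  if (N <= 1) stop("universe must contain more than one gene", call. = FALSE)
  if (d > N) stop("draw size exceeds universe size", call. = FALSE)
  p <- K / N
  mu <- d * p
  sd <- sqrt(d * p * (1 - p) * (N - d) / (N - 1))
  z <- if (sd > 0) (n_tf - mu) / sd else NA_real_
  enrichment_result(n_tf, n_nontf, mu, sd, z, z_threshold, "analytic")
}

#' Sampling-based TF over-representation Z score
#'
#' Monte-Carlo version of the over-representation test: repeatedly draw
#' `n_tf + n_nontf` genes without replacement from the universe, count the
#' TFs among them, and standardize the observed TF count against the
#' empirical null mean and sd. The count of TFs in one such draw is a
#' hypergeometric variate, so the draws are generated with
#' [stats::rhyper()]; this is distribution-identical to materializing the
#' gene samples and counting, at a fraction of the cost.
#'
#' @inheritParams enrichment_z_analytic
#' @param null a [sampling_null()].
#' @return One-row data.frame as for [enrichment_z_analytic()].
#' @export
enrichment_z_sampled <- function(n_tf, n_nontf, universe,
                                 null = sampling_null(), z_threshold = 3) {
  u <- universe_counts(universe)
  N <- u$N; K <- u$K; d <- n_tf + n_nontf
  if (N <= 1) stop("universe must contain more than one gene", call. = FALSE)
  if (d > N) stop("draw size exceeds universe size", call. = FALSE)
  if (!is.null(null$seed)) set.seed(null$seed)
  draws <- stats::rhyper(null$n_iterations, m = K, n = N - K, k = d)
  mu <- mean(draws); sd <- stats::sd(draws)
  z <- if (is.finite(sd) && sd > 0) (n_tf - mu) / sd else NA_real_
  enrichment_result(n_tf, n_nontf, mu, sd, z, z_threshold, "sampled")
}

#' TF over-representation for every (stage range, slim term) cell
#'
#' For every stage range and anatomy term with at least one expressed gene,
#' counts the non-redundant sets of expressed TFs (n) and non-TFs (m) and
#' scores TF over-representation against random draws of n + m genes from
#' the universe. Cells whose null is degenerate (sd = 0) are flagged, not
#' dropped silently.
#'
#' @param m a `stage_tissue_matrix`.
#' @param catalog a `gene_catalog`.
#' @param null a [sampling_null()] (used when `method = "sampled"`).
#' @param method `"sampled"` (default, the resampling procedure) or
#'   `"analytic"` (exact hypergeometric oracle, zero-cost).
#' @param z_threshold significance cut (default 3).
#' @param universe `"annotated"` (default: all genes in the matrix
#'   universe, i.e. genes with expression information) or `"catalog"` (all
#'   catalog genes).
#' @return data.frame with one row per nonempty cell: `stage`,
#'   `stage_label`, `term`, `n_tf`, `n_nontf`, `expected_tf`, `null_sd`,
#'   `z`, `significant`, `degenerate`, `method`.
#' @export
enrich_all <- function(m, catalog, null = sampling_null(),
                       method = c("sampled", "analytic"), z_threshold = 3,
                       universe = c("annotated", "catalog")) {
  method <- match.arg(method)
  universe <- match.arg(universe)
  validate_stm(m)
  is_tf <- stats::setNames(catalog$is_tf, catalog$gene_id)
  if (!all(m$genes %in% catalog$gene_id))
    stop("matrix universe contains genes absent from the catalog",
         call. = FALSE)
  uni_genes <- if (universe == "annotated") m$genes else catalog$gene_id
  u <- list(N = length(uni_genes), K = sum(is_tf[uni_genes]))
  if (!is.null(null$seed)) set.seed(null$seed)
  mc_null <- sampling_null(null$n_iterations, seed = NULL)
  rows <- list()
  for (s in seq_len(N_STAGES)) {
    cells <- m$ann[m$ann$stage == s, ]
    if (!nrow(cells)) next
    for (tm in unique(cells$term)) {
      genes <- unique(cells$gene_id[cells$term == tm])
      ntf <- sum(is_tf[genes]); nnon <- length(genes) - ntf
      res <- if (u$N <= 1L) {
        # degenerate universe: no resampling variance, flag instead of fail
        enrichment_result(ntf, nnon, ntf + nnon, 0, NA_real_, z_threshold,
                          method)
      } else switch(method,
        analytic = enrichment_z_analytic(ntf, nnon, u, z_threshold),
        sampled = enrichment_z_sampled(ntf, nnon, u, mc_null, z_threshold))
      res$stage <- s; res$term <- tm
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) {
    out <- enrichment_result(0L, 0L, 0, 0, NA_real_, z_threshold,
                             method)[0, ]
    out$stage_label <- character()
    return(out[c("stage", "stage_label", "term", "n_tf", "n_nontf",
                 "expected_tf", "null_sd", "z", "significant",
                 "degenerate", "method")])
  }
  out <- do.call(rbind, rows)
  out$stage_label <- stage_labels()[out$stage]
  out[order(out$stage, out$term),
      c("stage", "stage_label", "term", "n_tf", "n_nontf", "expected_tf",
        "null_sd", "z", "significant", "degenerate", "method")]
}

#' Repertoire-overlap Z score between two tissues
#'
#' Tests whether the TF repertoires of two tissues overlap more (or less)
#' than expected for independently drawn repertoires of the same sizes:
#' the observed `|A intersect B|` is standardized against the overlap of
#' random sets of sizes `|A|` and `|B|` drawn from the family universe.
#' Negative z is meaningful and reads as avoidance of overlap.
#'
#' @param set_a,set_b character vectors of gene ids (nonempty subsets of
#'   `family_universe`).
#' @param family_universe character vector: all genes of the relevant
#'   family with expression information.
#' @param null a [sampling_null()].
#' @return One-row data.frame with `observed`, `expected`, `null_sd`, `z`,
#'   `degenerate`.
#' @export
tissue_overlap_z <- function(set_a, set_b, family_universe,
                             null = sampling_null()) {
  if (!length(set_a) || !length(set_b))
    stop("both gene sets must be nonempty", call. = FALSE)
  if (length(bad <- setdiff(c(set_a, set_b), family_universe)))
    stop("set members outside the family universe: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  N <- length(family_universe)
  a <- length(unique(set_a)); b <- length(unique(set_b))
  obs <- length(intersect(set_a, set_b))
  if (!is.null(null$seed)) set.seed(null$seed)
  # overlap of two independent uniform subsets of sizes a and b of N genes
  draws <- stats::rhyper(null$n_iterations, m = a, n = N - a, k = b)
  mu <- mean(draws); sd <- stats::sd(draws)
  degenerate <- !is.finite(sd) || sd == 0
  data.frame(observed = obs, expected = mu, null_sd = sd,
             z = if (degenerate) NA_real_ else (obs - mu) / sd,
             degenerate = degenerate)
}
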