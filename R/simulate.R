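#' Default DBD family weights for simulated TFs
#'
#' Family frequencies roughly proportional to the fly TF repertoire (zinc
#' fingers dominant, then Homeobox and HLH; 14 named families cover ~70% of
#' TFs, the rest labelled "other").
#'
#' @return Named numeric vector summing to 1.
#' @export
default_family_weights <- function() {
  w <- c(`zf-C2H2` = 200, `zf-C2H2+zf-AD` = 49, Homeobox = 99, HLH = 55,
         `zf-C4` = 22, BESS = 20, Forkhead = 19, bZIP1 = 10, bZIP2 = 9,
         Ets = 8, `T-box` = 8, GATA = 6, HMG = 6, HTH = 6, other = 200,
         none = 36)
  w / sum(w)
}

#' Default temporal class mixture
#'
#' Class proportions echoing the observed distribution over an in situ TF
#' repertoire of 373 genes: 46 early, 55 late, 64 zygotic-continuous, 113
#' maternal-continuous, 22 never detected, 73 diverse.
#'
#' @return Named numeric vector over the six classes, summing to 1.
#' @export
default_class_mixture <- function() {
  w <- c(no_expression = 22, early_only = 46, late_only = 55,
         continuous_zygotic = 64, maternal_continuous = 113, diverse = 73)
  w / sum(w)
}

#' Default adult tissue panel for simulated call tables
#' @return Character vector of 15 tissue names.
#' @export
default_adult_tissues <- function() {
  c("brain", "thoracic ganglion", "head", "eye", "crop", "midgut",
    "hindgut", "malpighian tubule", "ovary", "testis", "accessory gland",
    "salivary gland", "fat body", "heart", "carcass")
}

#' Default ChIP occupancy-state transition matrix
#'
#' Emulates the dynamics of an early mesodermal factor (A) being joined by
#' a later myogenic partner (B): double-occupied sites keep their state,
#' one third of A-only sites gain a partner site, and a share of
#' previously empty sites becomes occupied as B expression rises.
#'
#' @return 4x4 row-stochastic matrix over
#'   `{"A_only","B_only","double","none"}`.
#' @export
default_chip_transitions <- function() {
  tr <- rbind(
    A_only = c(A_only = 2 / 3, B_only = 0, double = 1 / 3, none = 0),
    B_only = c(A_only = 0, B_only = 0.8, double = 0.2, none = 0),
    double = c(A_only = 0, B_only = 0, double = 1, none = 0),
    none   = c(A_only = 0.1, B_only = 0.2, double = 0.2, none = 0.5))
  tr
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must be probabilities in [0, 1]", call. = FALSE)
  x
}

check_dist <- function(x, what) {
  check_prob(x, what)
  if (abs(sum(x) - 1) > 1e-8)
    stop(what, " must sum to 1", call. = FALSE)
  x
}

#' Simulation configuration
#'
#' All parameters of the synthetic-data generators, with a mandatory
#' integer seed (no generator reads system entropy). Defaults define the
#' reference study conditions: 2000 genes with 5% TFs, half the genes
#' maternally contributed, a class mixture echoing an in situ TF survey,
#' one planted 6x TF tissue enrichment, and ChIP occupancy transitions
#' with a planted 1/3 partner-gain rate.
#'
#' @param n_genes number of genes (default 2000).
#' @param tf_fraction TF share of the catalog (default 0.05).
#' @param family_weights distribution over DBD families for TFs.
#' @param maternal_fraction share of genes (within TFs and non-TFs alike)
#'   planted with maternal expression, i.e. expression at stage range 1-3
#'   (default 0.5). Planted exactly per stratum: `round(frac * n)` genes.
#'   Honored only insofar as `class_mixture` puts mass on both maternal and
#'   non-maternal classes.
#' @param class_mixture distribution over the six temporal classes.
#' @param enrichment_spec data.frame `term`, `stage` (label or index),
#'   `multiplier`: planted multiplicative TF-inclusion odds per (term,
#'   stage). Default: 6x for ("ventral nerve cord", "13-16").
#' @param conservation probability that a gene expressed at two consecutive
#'   stages carries its term set over unchanged (plants conserved
#'   comodules; default 0.5).
#' @param term_prob baseline per-term inclusion probability for restricted
#'   expression (default 0.10).
#' @param ubiq_prob_tf,ubiq_prob_nontf probability that an expressed
#'   gene-stage is annotated `{ubiquitous}` (TFs restricted more often:
#'   defaults 0.15 / 0.30).
#' @param mu_expressed,mu_unexpressed time-course log-ratio centers for
#'   expressed / unexpressed gene-timepoints (defaults 0.72 / 0.14, the
#'   observed medians for in-situ-positive and -negative genes).
#' @param noise_sd Gaussian noise sd for time-course values (default 0.3).
#' @param tissues adult tissue panel for the call table.
#' @param n_replicates present/absent replicates per tissue (default 4).
#' @param present_prob per-replicate present-call probability (default
#'   0.8).
#' @param n_up_clusters planted adult specificity clusters among TFs
#'   (default 7).
#' @param up_prob_in,up_prob_out up-call probability inside / outside a
#'   cluster signature tissues (defaults 0.9 / 0.02).
#' @param down_prob probability of a "down" call where there is no up call.
#' @param chip_n_sites number of disjoint genomic sites (default 3000).
#' @param chip_site_width,chip_site_gap site geometry in bp.
#' @param chip_initial initial occupancy-state distribution at t1.
#' @param chip_transitions row-stochastic 4x4 transition matrix t1 -> t2.
#' @param seed mandatory integer master seed, expanded into per-generator
#'   substreams (see [derive_substreams()]).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 2000L, tf_fraction = 0.05,
    family_weights = default_family_weights(),
    maternal_fraction = 0.5,
    class_mixture = default_class_mixture(),
    enrichment_spec = data.frame(term = "ventral nerve cord",
                                 stage = "13-16", multiplier = 6),
    conservation = 0.5,
    term_prob = 0.10, ubiq_prob_tf = 0.15, ubiq_prob_nontf = 0.30,
    mu_expressed = 0.72, mu_unexpressed = 0.14, noise_sd = 0.3,
    tissues = default_adult_tissues(), n_replicates = 4L,
    present_prob = 0.8, n_up_clusters = 7L,
    up_prob_in = 0.9, up_prob_out = 0.02, down_prob = 0.05,
    chip_n_sites = 3000L, chip_site_width = 500L, chip_site_gap = 1500L,
    chip_initial = c(A_only = 0.43, B_only = 0.06, double = 0.08,
                     none = 0.43),
    chip_transitions = default_chip_transitions(),
    seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory: generators take no implicit entropy",
         call. = FALSE)
  check_prob(tf_fraction, "tf_fraction")
  check_prob(maternal_fraction, "maternal_fraction")
  check_prob(conservation, "conservation")
  check_prob(c(term_prob, ubiq_prob_tf, ubiq_prob_nontf),
             "term/ubiquitous probabilities")
  check_prob(c(present_prob, up_prob_in, up_prob_out, down_prob),
             "call probabilities")
  check_dist(family_weights, "family_weights")
  if (!all(names(class_mixture) %in% temporal_classes()) ||
      length(class_mixture) != 6L)
    stop("class_mixture must be a distribution over the six temporal ",
         "classes", call. = FALSE)
  check_dist(class_mixture, "class_mixture")
  if (nrow(enrichment_spec)) {
    if (any(enrichment_spec$multiplier <= 0))
      stop("enrichment multiplier must be > 0", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  check_dist(chip_initial[OCC_STATES], "chip_initial")
  tr <- chip_transitions[OCC_STATES, OCC_STATES]
  for (s in OCC_STATES) check_dist(tr[s, ], paste0("chip_transitions[",
                                                   s, ",]"))
  structure(list(
    n_genes = as.integer(n_genes), tf_fraction = tf_fraction,
    family_weights = family_weights,
    maternal_fraction = maternal_fraction,
    class_mixture = class_mixture[temporal_classes()],
    enrichment_spec = enrichment_spec, conservation = conservation,
    term_prob = term_prob, ubiq_prob_tf = ubiq_prob_tf,
    ubiq_prob_nontf = ubiq_prob_nontf,
    mu_expressed = mu_expressed, mu_unexpressed = mu_unexpressed,
    noise_sd = noise_sd,
    tissues = tissues, n_replicates = as.integer(n_replicates),
    present_prob = present_prob, n_up_clusters = as.integer(n_up_clusters),
    up_prob_in = up_prob_in, up_prob_out = up_prob_out,
    down_prob = down_prob,
    chip_n_sites = as.integer(chip_n_sites),
    chip_site_width = as.integer(chip_site_width),
    chip_site_gap = as.integer(chip_site_gap),
    chip_initial = chip_initial[OCC_STATES], chip_transitions = tr,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Expand the master seed into per-generator substreams
#'
#' Fixed scheme: seed the base RNG with the master seed and draw one
#' 31-bit integer per generator, in the documented order `catalog`,
#' `annotations`, `timecourse`, `calls`, `chip`, `aux`. New generators are
#' appended at the end of the order, so adding one never perturbs the
#' streams of the existing ones.
#'
#' @param seed integer master seed.
#' @return Named integer vector of substream seeds.
#' @export
derive_substreams <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  stats::setNames(sample.int(2147483646L, 6L),
                  c("catalog", "annotations", "timecourse", "calls",
                    "chip", "aux"))
}

#' Generate a synthetic gene catalog
#'
#' Exactly `round(n_genes * tf_fraction)` genes are TFs, with DBD families
#' drawn from `family_weights`; all other genes get family `"none"`.
#' Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return A `gene_catalog`.
#' @export
generate_catalog <- function(config) {
  set.seed(derive_substreams(config$seed)[["catalog"]])
  n <- config$n_genes
  n_tf <- round(n * config$tf_fraction)
  if (n_tf < 1) stop("tf_fraction * n_genes < 1: no TFs to analyze",
                     call. = FALSE)
  ids <- sprintf("G%05d", seq_len(n))
  is_tf <- rep(FALSE, n)
  is_tf[sample.int(n, n_tf)] <- TRUE
  fam <- rep("none", n)
  fam[is_tf] <- sample(names(config$family_weights), n_tf, replace = TRUE,
                       prob = config$family_weights)
  gene_catalog(ids, ids, is_tf, fam)
}

# all 64 supports and their class labels, used as per-class sampling pools
support_pools <- function(early_cutoff = 3L) {
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N_STAGES)))
  cls <- apply(grid, 1, classify_temporal_class,
               early_cutoff = early_cutoff)
  list(supports = grid, classes = cls)
}

#' Generate synthetic embryo annotations with planted ground truth
#'
#' Per gene: a maternal flag (planted exactly, `round(frac * n)` genes per
#' TF/non-TF stratum), a temporal class drawn from the class mixture
#' restricted to the maternal arm, a stage support sampled uniformly from
#' the supports of that class, and per-stage term sets. Term sets carry
#' over between consecutive expressed stages with probability
#' `conservation` (planting conserved comodules) and otherwise are
#' resampled: `{ubiquitous}` with the stratum's ubiquity probability, else
#' a random restricted term set. For every planted enrichment cell, TF
#' genes with restricted expression at that stage additionally include the
#' planted term with the probability given by the multiplied odds.
#'
#' @param catalog a `gene_catalog`.
#' @param anatomy a [slim_anatomy()].
#' @param config a [simulation_config()].
#' @return A list with `matrix` (a `stage_tissue_matrix`) and `truth`
#'   (list: `classes` data.frame with `gene_id`, `class`, `maternal`;
#'   `enrichment` the planted cells with stage indices; `carryover`
#'   data.frame of carried gene-stage pairs).
#' @export
generate_embryo_annotations <- function(catalog, anatomy, config) {
  set.seed(derive_substreams(config$seed)[["annotations"]])
  pools <- support_pools()
  mix <- config$class_mixture
  espec <- config$enrichment_spec
  if (nrow(espec)) {
    if (any(espec$multiplier <= 0))
      stop("enrichment multiplier must be > 0", call. = FALSE)
    if (is.character(espec$stage)) espec$stage <- stage_index(espec$stage)
    bad <- setdiff(espec$term, setdiff(anatomy$terms, "ubiquitous"))
    if (length(bad))
      stop("planted enrichment term(s) not in anatomy (or 'ubiquitous'): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  maternal_ok <- pools$supports[, 1]
  arm_classes <- list(
    maternal = c("maternal_continuous", "early_only", "diverse"),
    nonmaternal = c("no_expression", "continuous_zygotic", "late_only",
                    "diverse"))
  genes <- catalog$gene_id
  n <- length(genes)
  maternal <- logical(n); cls <- character(n)
  support <- matrix(FALSE, n, N_STAGES)
  w_mat <- sum(mix[arm_classes$maternal])
  w_non <- sum(mix[arm_classes$nonmaternal])
  for (stratum in list(which(catalog$is_tf), which(!catalog$is_tf))) {
    ns <- length(stratum)
    if (!ns) next
    n_mat <- if (w_mat <= 0) 0L
             else if (w_non <= 0) ns
             else round(config$maternal_fraction * ns)
    mat_idx <- stratum[sample.int(ns, n_mat)]
    maternal[mat_idx] <- TRUE
    for (g in stratum) {
      arm <- if (maternal[g]) "maternal" else "nonmaternal"
      w <- mix[arm_classes[[arm]]]
      cls[g] <- sample(names(w), 1L, prob = w)
      pool <- which(pools$classes == cls[g] &
                      (if (arm == "maternal") maternal_ok else !maternal_ok))
      if (!length(pool))
        pool <- which(pools$classes == cls[g])
      support[g, ] <- pools$supports[pool[sample.int(length(pool), 1L)], ]
    }
  }
  # term sets, stage by stage, with carry-over and planted enrichment
  restricted <- setdiff(anatomy$terms, "ubiquitous")
  ubiq_p <- ifelse(catalog$is_tf, config$ubiq_prob_tf,
                   config$ubiq_prob_nontf)
  sets_prev <- vector("list", n)
  ann_gene <- list(); ann_stage <- list(); ann_term <- list()
  carry_log <- list()
  for (s in seq_len(N_STAGES)) {
    sets_now <- vector("list", n)
    planted <- espec[nrow(espec) > 0 & espec$stage == s, , drop = FALSE]
    for (g in which(support[, s])) {
      carried <- s > 1L && support[g, s - 1L] &&
        stats::runif(1) < config$conservation
      if (carried) {
        set <- sets_prev[[g]]
      } else if (stats::runif(1) < ubiq_p[g]) {
        set <- "ubiquitous"
      } else {
        set <- restricted[stats::runif(length(restricted)) <
                            config$term_prob]
        if (!length(set)) set <- sample(restricted, 1L)
      }
      if (nrow(planted) && catalog$is_tf[g] &&
          !identical(set, "ubiquitous")) {
        for (j in seq_len(nrow(planted))) {
          odds <- config$term_prob / (1 - config$term_prob) *
            planted$multiplier[j]
          if (stats::runif(1) < odds / (1 + odds))
            set <- union(set, planted$term[j])
        }
      }
      sets_now[[g]] <- set
      if (carried)
        carry_log[[length(carry_log) + 1L]] <- c(g, s)
      ann_gene[[length(ann_gene) + 1L]] <- rep(genes[g], length(set))
      ann_stage[[length(ann_stage) + 1L]] <- rep(s, length(set))
      ann_term[[length(ann_term) + 1L]] <- set
    }
    sets_prev <- sets_now
  }
  ann <- data.frame(gene_id = unlist(ann_gene),
                    stage = as.integer(unlist(ann_stage)),
                    term = unlist(ann_term), stringsAsFactors = FALSE)
  if (!nrow(ann))
    ann <- data.frame(gene_id = character(), stage = integer(),
                      term = character(), stringsAsFactors = FALSE)
  m <- stage_tissue_matrix(genes, ann, anatomy)
  carry <- if (length(carry_log)) {
    cl <- do.call(rbind, carry_log)
    data.frame(gene_id = genes[cl[, 1]], stage = cl[, 2],
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), stage = integer(),
                    stringsAsFactors = FALSE)
  list(matrix = m,
       truth = list(
         classes = data.frame(gene_id = genes, class = cls,
                              maternal = maternal,
                              stringsAsFactors = FALSE),
         enrichment = espec, carryover = carry))
}

#' Generate a synthetic expression time-course
#'
#' Gene-timepoint values are Gaussian around `mu_expressed` where the
#' stage-support of the annotation matrix flags the gene expressed (each
#' timepoint is assigned to the stage range containing it) and around
#' `mu_unexpressed` elsewhere.
#'
#' @param catalog a `gene_catalog`.
#' @param m the `stage_tissue_matrix` from
#'   [generate_embryo_annotations()].
#' @param config a [simulation_config()].
#' @param hours timepoints in hours AEL (default: stage-range midpoints).
#' @return A list with `timecourse` (a [timecourse()]) and `expressed`
#'   (logical gene x timepoint matrix, the planted truth).
#' @export
generate_timecourse <- function(catalog, m, config,
                                hours = NULL) {
  set.seed(derive_substreams(config$seed)[["timecourse"]])
  sr <- stage_ranges()
  if (is.null(hours)) hours <- (sr$hours_start + sr$hours_end) / 2
  if (!length(hours)) stop("empty timepoint list", call. = FALSE)
  stage_of <- vapply(hours, function(h) {
    i <- which(h >= sr$hours_start & h < sr$hours_end)
    if (!length(i)) N_STAGES else i[1]
  }, integer(1))
  supp <- stm_support(m)[catalog$gene_id, , drop = FALSE]
  expressed <- supp[, stage_of, drop = FALSE]
  vals <- matrix(stats::rnorm(length(expressed),
                              mean = ifelse(expressed, config$mu_expressed,
                                            config$mu_unexpressed),
                              sd = config$noise_sd),
                 nrow(expressed), ncol(expressed))
  colnames(expressed) <- paste0("h", hours)
  list(timecourse = timecourse(catalog$gene_id, hours, vals),
       expressed = expressed)
}

#' Generate a synthetic adult call table with planted clusters
#'
#' Present calls are i.i.d. Bernoulli per gene/tissue/replicate. Up calls
#' carry the planted structure: TFs are split evenly over
#' `n_up_clusters` clusters, each cluster owning a disjoint signature set
#' of tissues; up-call probability is `up_prob_in` inside the signature
#' and `up_prob_out` elsewhere (and everywhere for non-TFs).
#'
#' @param catalog a `gene_catalog`.
#' @param config a [simulation_config()].
#' @return A list with `calls` (a [call_table()]) and `truth` (data.frame
#'   `gene_id`, `cluster`, plus the signature tissue list as attribute
#'   `"signatures"`).
#' @export
generate_call_table <- function(catalog, config) {
  set.seed(derive_substreams(config$seed)[["calls"]])
  check_prob(config$present_prob, "present_prob")
  tissues <- config$tissues
  nt <- length(tissues)
  if (config$n_replicates < 1L)
    stop("replicate count must be >= 1", call. = FALSE)
  if (config$n_up_clusters > nt)
    stop("more planted clusters than tissues", call. = FALSE)
  genes <- catalog$gene_id
  n <- length(genes)
  present <- array(stats::runif(n * nt * config$n_replicates) <
                     config$present_prob,
                   c(n, nt, config$n_replicates))
  sig <- split(tissues, rep_len(seq_len(config$n_up_clusters), nt))
  names(sig) <- as.character(seq_len(config$n_up_clusters))
  tf_idx <- which(catalog$is_tf)
  cluster <- integer(0)
  up_p <- matrix(config$up_prob_out, n, nt)
  if (length(tf_idx)) {
    cluster <- rep_len(seq_len(config$n_up_clusters),
                       length(tf_idx))[sample.int(length(tf_idx))]
    for (k in seq_len(config$n_up_clusters)) {
      rows <- tf_idx[cluster == k]
      up_p[rows, match(sig[[as.character(k)]], tissues)] <- config$up_prob_in
    }
  }
  up <- matrix(stats::runif(n * nt) < up_p, n, nt)
  direction <- matrix(ifelse(up, "up",
                             ifelse(stats::runif(n * nt) < config$down_prob,
                                    "down", "none")), n, nt)
  truth <- data.frame(gene_id = genes[tf_idx], cluster = cluster,
                      stringsAsFactors = FALSE)
  attr(truth, "signatures") <- sig
  list(calls = call_table(genes, tissues, present, direction),
       truth = truth)
}

#' Generate a synthetic two-factor, two-timepoint ChIP experiment
#'
#' Lays out `chip_n_sites` disjoint anchor regions on one contig, draws an
#' occupancy state per site at t1 from `chip_initial` and at t2 from
#' `chip_transitions`, and emits one jittered peak per occupying factor
#' and timepoint (peaks always overlap their site and never a neighboring
#' one). The per-site state sequence is the recorded ground truth.
#'
#' @param config a [simulation_config()].
#' @return A list with `peaks` (list `A_t1`, `B_t1`, `A_t2`, `B_t2` of
#'   `GRanges`), `sites` (`GRanges`), and `truth` (data.frame `site`,
#'   `state_t1`, `state_t2`).
#' @export
generate_chip_experiment <- function(config) {
  set.seed(derive_substreams(config$seed)[["chip"]])
  ns <- config$chip_n_sites
  if (ns == 0L) {
    empty <- GenomicRanges::GRanges()
    return(list(peaks = list(A_t1 = empty, B_t1 = empty,
                             A_t2 = empty, B_t2 = empty),
                sites = empty,
                truth = data.frame(site = integer(),
                                   state_t1 = character(),
                                   state_t2 = character())))
  }
  w <- config$chip_site_width; gap <- config$chip_site_gap
  jitter_max <- min(200L, gap %/% 4L)
  starts <- (seq_len(ns) - 1L) * (w + gap) + 1L
  sites <- GenomicRanges::GRanges("chrS",
                                  IRanges::IRanges(starts, width = w))
  s1 <- sample(OCC_STATES, ns, replace = TRUE, prob = config$chip_initial)
  s2 <- vapply(s1, function(st) {
    sample(OCC_STATES, 1L, prob = config$chip_transitions[st, ])
  }, character(1), USE.NAMES = FALSE)
  emit <- function(occupied) {
    idx <- which(occupied)
    if (!length(idx)) return(GenomicRanges::GRanges())
    off <- sample(seq(-jitter_max, jitter_max), length(idx),
                  replace = TRUE)
    GenomicRanges::GRanges("chrS",
                           IRanges::IRanges(starts[idx] + off, width = w))
  }
  list(peaks = list(A_t1 = emit(s1 %in% c("A_only", "double")),
                    B_t1 = emit(s1 %in% c("B_only", "double")),
                    A_t2 = emit(s2 %in% c("A_only", "double")),
                    B_t2 = emit(s2 %in% c("B_only", "double"))),
       sites = sites,
       truth = data.frame(site = seq_len(ns), state_t1 = s1,
                          state_t2 = s2, stringsAsFactors = FALSE))
}

#' Generate all five synthetic modalities, optionally writing files
#'
#' Runs every generator under the config's master seed and, if `outdir` is
#' given, writes `catalog.tsv`, `annotations.tsv`, `timecourse.tsv`,
#' `calls.tsv`, `peaks_{A,B}_{t1,t2}.bed` and the ground-truth tables.
#'
#' @param config a [simulation_config()].
#' @param anatomy a [slim_anatomy()] (default [default_slim_anatomy()]).
#' @param outdir optional output directory (created if missing).
#' @return Invisibly, a list with `catalog`, `matrix`, `timecourse`,
#'   `calls`, `chip`, and `truth` (merged ground truth).
#' @export
simulate_all <- function(config, anatomy = default_slim_anatomy(),
                         outdir = NULL) {
  catalog <- generate_catalog(config)
  emb <- generate_embryo_annotations(catalog, anatomy, config)
  tc <- generate_timecourse(catalog, emb$matrix, config)
  ct <- generate_call_table(catalog, config)
  chip <- generate_chip_experiment(config)
  truth <- c(emb$truth,
             list(timecourse_expressed = tc$expressed,
                  adult_clusters = ct$truth, chip = chip$truth))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_gene_catalog(catalog, file.path(outdir, "catalog.tsv"))
    write_annotations(emb$matrix, file.path(outdir, "annotations.tsv"))
    write_timecourse(tc$timecourse, file.path(outdir, "timecourse.tsv"))
    write_call_table(ct$calls, file.path(outdir, "calls.tsv"))
    for (nm in names(chip$peaks))
      write_peaks(chip$peaks[[nm]],
                  file.path(outdir, paste0("peaks_", nm, ".bed")))
    utils::write.table(emb$truth$classes,
                       file.path(outdir, "ground_truth_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(chip$truth,
                       file.path(outdir, "ground_truth_chip.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ct$truth,
                       file.path(outdir, "ground_truth_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(catalog = catalog, matrix = emb$matrix,
                 timecourse = tc$timecourse, calls = ct$calls,
                 chip = chip, truth = truth))
}
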