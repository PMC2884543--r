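test_that("config validation rejects malformed distributions and seeds", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(tf_fraction = 1.5, seed = 1), "\\[0, 1\\]")
  expect_error(simulation_config(class_mixture = c(a = 1), seed = 1),
               "six temporal classes")
  bad_mix <- default_class_mixture(); bad_mix[1] <- bad_mix[1] + 0.5
  expect_error(simulation_config(class_mixture = bad_mix, seed = 1),
               "sum to 1")
  tr <- default_chip_transitions(); tr["A_only", "double"] <- 0.9
  expect_error(simulation_config(chip_transitions = tr, seed = 1),
               "sum to 1")
  expect_error(simulation_config(noise_sd = 0, seed = 1), "noise_sd")
  expect_error(
    generate_embryo_annotations(
      generate_catalog(simulation_config(n_genes = 100, seed = 1)),
      default_slim_anatomy(),
      simulation_config(n_genes = 100, seed = 1,
                        enrichment_spec = data.frame(
                          term = "brain", stage = "1-3", multiplier = -2))),
    "multiplier")
})

test_that("catalog generation plants exact TF counts and families", {
  cfg <- simulation_config(n_genes = 1000, tf_fraction = 0.05, seed = 1)
  cat0 <- generate_catalog(cfg)
  expect_equal(sum(cat0$is_tf), 50)
  expect_equal(sum(!cat0$is_tf), 950)
  expect_true(all(cat0$dbd_family[!cat0$is_tf] == "none"))
  # determinism: same config, same seed, identical output
  expect_identical(cat0, generate_catalog(cfg))
  # all family mass on one family
  w <- stats::setNames(rep(0, length(default_family_weights())),
                       names(default_family_weights()))
  w["Homeobox"] <- 1
  cfg2 <- simulation_config(n_genes = 200, family_weights = w, seed = 2)
  cat2 <- generate_catalog(cfg2)
  expect_true(all(cat2$dbd_family[cat2$is_tf] == "Homeobox"))
  expect_error(generate_catalog(simulation_config(
    n_genes = 10, tf_fraction = 0.01, seed = 3)), "no TFs")
})

test_that("generators are pure functions of config and seed", {
  cfg <- simulation_config(n_genes = 200, chip_n_sites = 50, seed = 11)
  s1 <- simulate_all(cfg)
  s2 <- simulate_all(cfg)
  expect_identical(s1$matrix$ann, s2$matrix$ann)
  expect_identical(s1$timecourse$values, s2$timecourse$values)
  expect_identical(s1$calls$present, s2$calls$present)
  expect_identical(s1$chip$truth, s2$chip$truth)
  expect_identical(s1$truth$classes, s2$truth$classes)
})

test_that("substreams are independent: one generator does not perturb another", {
  cfg <- simulation_config(n_genes = 200, seed = 31)
  ann_alone <- generate_embryo_annotations(generate_catalog(cfg),
                                           default_slim_anatomy(), cfg)
  # running other generators in between must not change the outcome
  invisible(generate_chip_experiment(cfg))
  invisible(generate_call_table(generate_catalog(cfg), cfg))
  ann_again <- generate_embryo_annotations(generate_catalog(cfg),
                                           default_slim_anatomy(), cfg)
  expect_identical(ann_alone$matrix$ann, ann_again$matrix$ann)
})

test_that("degenerate class mixtures force the planted patterns", {
  one_class <- function(cls) {
    w <- stats::setNames(rep(0, 6), temporal_classes()); w[cls] <- 1
    w
  }
  cfg <- simulation_config(n_genes = 100, seed = 4,
                           class_mixture = one_class("maternal_continuous"))
  emb <- generate_embryo_annotations(generate_catalog(cfg),
                                     default_slim_anatomy(), cfg)
  expect_true(all(stm_support(emb$matrix)))  # everyone expressed everywhere
  cfg0 <- simulation_config(n_genes = 50, seed = 5,
                            class_mixture = one_class("no_expression"))
  emb0 <- generate_embryo_annotations(generate_catalog(cfg0),
                                      default_slim_anatomy(), cfg0)
  expect_equal(nrow(emb0$matrix$ann), 0)
  expect_false(any(stm_support(emb0$matrix)))
})

test_that("the classifier recovers every planted temporal class", {
  cfg <- simulation_config(n_genes = 500, seed = 6)
  emb <- generate_embryo_annotations(generate_catalog(cfg),
                                     default_slim_anatomy(), cfg)
  got <- temporal_class_table(emb$matrix)
  expect_identical(got$class, emb$truth$classes$class)
})

test_that("the maternal fraction is planted exactly per stratum", {
  for (seed in c(7, 8)) {
    cfg <- simulation_config(n_genes = 400, seed = seed)
    cat0 <- generate_catalog(cfg)
    emb <- generate_embryo_annotations(cat0, default_slim_anatomy(), cfg)
    expect_equal(maternal_fraction(emb$matrix, cat0), 0.5)
    expect_equal(mean(emb$truth$classes$maternal), 0.5)
  }
})

test_that("time-course values are centered on the planted medians", {
  cfg <- simulation_config(n_genes = 1000, seed = 9)
  cat0 <- generate_catalog(cfg)
  emb <- generate_embryo_annotations(cat0, default_slim_anatomy(), cfg)
  tc <- generate_timecourse(cat0, emb$matrix, cfg)
  expect_equal(stats::median(tc$timecourse$values[tc$expressed]), 0.72,
               tolerance = 0.05 / 0.72)
  expect_equal(stats::median(tc$timecourse$values[!tc$expressed]), 0.14,
               tolerance = 0.05 / 0.14)
  # near-zero noise: the +-0.5 reclassification separates the two groups
  cfg0 <- simulation_config(n_genes = 300, seed = 10, noise_sd = 1e-6)
  emb0 <- generate_embryo_annotations(generate_catalog(cfg0),
                                      default_slim_anatomy(), cfg0)
  tc0 <- generate_timecourse(generate_catalog(cfg0), emb0$matrix, cfg0)
  cls <- classify_timecourse_value(tc0$timecourse$values)
  expect_true(all(cls[tc0$expressed] == "high"))
  expect_true(all(cls[!tc0$expressed] == "average"))
  expect_error(generate_timecourse(cat0, emb$matrix, cfg, hours = numeric()),
               "empty")
})

test_that("present-call extremes behave as planted", {
  cfg1 <- simulation_config(n_genes = 50, present_prob = 1, seed = 12)
  ct1 <- generate_call_table(generate_catalog(cfg1), cfg1)
  votes <- apply(ct1$calls$present, c(1, 2), sum)
  expect_true(all(votes == 4))
  cfg0 <- simulation_config(n_genes = 50, present_prob = 0,
                            up_prob_in = 0, up_prob_out = 0, seed = 13)
  ct0 <- generate_call_table(generate_catalog(cfg0), cfg0)
  expect_false(any(call_table_expressed(ct0$calls)))
})

test_that("an empty ChIP design yields empty sets and empty downstream results", {
  cfg <- simulation_config(chip_n_sites = 0, seed = 14)
  chip <- generate_chip_experiment(cfg)
  expect_true(all(vapply(chip$peaks, length, integer(1)) == 0))
  cc <- chip_cooccupancy(chip$peaks$A_t1, chip$peaks$B_t1,
                         chip$peaks$A_t2, chip$peaks$B_t2)
  expect_length(cc$universe, 0)
  expect_equal(cc$transitions$n_ever_occupied, 0)
})

test_that("simulate_all writes the full plain-text file set that reads back", {
  outdir <- withr::local_tempdir()
  cfg <- simulation_config(n_genes = 120, chip_n_sites = 30, seed = 15)
  sim <- simulate_all(cfg, outdir = outdir)
  files <- c("catalog.tsv", "annotations.tsv", "timecourse.tsv",
             "calls.tsv", "peaks_A_t1.bed", "peaks_B_t1.bed",
             "peaks_A_t2.bed", "peaks_B_t2.bed",
             "ground_truth_classes.tsv", "ground_truth_chip.tsv",
             "ground_truth_clusters.tsv")
  expect_true(all(file.exists(file.path(outdir, files))))
  cat_back <- read_gene_catalog(file.path(outdir, "catalog.tsv"))
  expect_equal(as.data.frame(cat_back), as.data.frame(sim$catalog))
  m_back <- read_annotations(file.path(outdir, "annotations.tsv"),
                             default_slim_anatomy(),
                             genes = cat_back$gene_id)
  expect_equal(m_back$ann, sim$matrix$ann)
  p_back <- read_peaks(file.path(outdir, "peaks_A_t1.bed"))
  expect_equal(GenomicRanges::start(p_back),
               GenomicRanges::start(GenomicRanges::sort(sim$chip$peaks$A_t1)))
})
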