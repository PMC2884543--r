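test_that("partitions group genes by exact term-set identity", {
  an <- toy_anatomy()
  m <- make_stm(list(
    g1 = list(`1` = "brain"), g2 = list(`1` = "brain"),
    g3 = list(`1` = c("brain", "midgut")), g4 = list()), an)
  p <- coexpression_partition(m, 1)
  expect_length(p$groups, 2)
  expect_setequal(names(p$membership), c("g1", "g2", "g3"))  # g4 excluded
  expect_equal(p$membership[["g1"]], p$membership[["g2"]])
  expect_false(p$membership[["g1"]] == p$membership[["g3"]])
  # sizes sum to the number of expressed genes
  expect_equal(sum(lengths(p$groups)), 3)
  # all genes sharing one vector: a single group
  m2 <- make_stm(list(a = list(`1` = "yolk"), b = list(`1` = "yolk")), an)
  expect_length(coexpression_partition(m2, 1)$groups, 1)
})

test_that("comodule counts are sums of binomial coefficients", {
  p <- make_partition(stats::setNames(c(1, 1, 2, 2, 2), letters[1:5]))
  expect_equal(count_comodules(p, 2), 1 + 3)
  expect_equal(count_comodules(p, 3), 0 + 1)
  expect_error(count_comodules(p, 4), "2 or 3")
})

test_that("conserved counts follow the partition-intersection definition", {
  p_s <- make_partition(stats::setNames(c(1, 1, 2, 2), c("g1", "g2", "g3", "g4")))
  p_s1 <- make_partition(stats::setNames(c(1, 1, 2, 3), c("g1", "g2", "g3", "g4")),
                         stage = 2L)
  expect_equal(conserved_comodules(p_s, p_s1, 2), 1)  # only (g1,g2) survives
  # identity case
  expect_equal(conserved_comodules(p_s, p_s, 2), count_comodules(p_s, 2))
  expect_equal(conserved_comodules(p_s, p_s, 3), count_comodules(p_s, 3))
})

test_that("counting operations match exhaustive subset enumeration (n <= 12)", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    genes <- sprintf("g%02d", 1:n)
    m1 <- stats::setNames(sample.int(sample(2:5, 1), n, replace = TRUE), genes)
    # later stage may lack some genes (not expressed there)
    keep <- sort(sample(n, sample(3:n, 1)))
    m2 <- stats::setNames(sample.int(sample(2:5, 1), length(keep),
                                     replace = TRUE), genes[keep])
    p1 <- make_partition(m1); p2 <- make_partition(m2, stage = 2L)
    for (k in 2:3) {
      expect_equal(conserved_comodules(p1, p2, k), brute_conserved(m1, m2, k))
      expect_equal(count_comodules(p1, k), brute_conserved(m1, m1, k))
    }
    # upper bound invariant
    expect_lte(conserved_comodules(p1, p2, 2),
               min(count_comodules(p1, 2), count_comodules(p2, 2)))
  }
})

test_that("permutation test standardizes the conserved count correctly", {
  set.seed(77)
  # planted full conservation: identical nontrivial partitions
  memb <- stats::setNames(sample.int(8, 40, replace = TRUE),
                          sprintf("g%02d", 1:40))
  p <- make_partition(memb)
  res <- permutation_z(p, make_partition(memb, stage = 2L), 2,
                       n_iter = 500, seed = 1)
  expect_gt(res$z, 3)
  expect_equal(res$observed, count_comodules(p, 2))
  expect_equal(res$n_iterations, 500)
  # degenerate null: every gene in one group, permutation cannot change it
  m1 <- stats::setNames(rep(1L, 5), letters[1:5])
  resd <- permutation_z(make_partition(m1),
                        make_partition(m1, stage = 2L), 2,
                        n_iter = 50, seed = 2)
  expect_true(resd$degenerate)
  expect_true(is.na(resd$z))
  expect_error(permutation_z(p, p, 2, n_iter = 1), "n_iter")
})

test_that("permutation null is centered for independent partitions", {
  set.seed(99)
  zs <- vapply(1:30, function(i) {
    g <- sprintf("g%02d", 1:50)
    p1 <- make_partition(stats::setNames(sample.int(10, 50, TRUE), g))
    p2 <- make_partition(stats::setNames(sample.int(10, 50, TRUE), g), 2L)
    permutation_z(p1, p2, 2, n_iter = 300)$z
  }, numeric(1))
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.6)  # tighter check in acceptance
})

test_that("permutation null distribution is exchangeable under pre-shuffling", {
  set.seed(13)
  g <- sprintf("g%02d", 1:30)
  m1 <- stats::setNames(sample.int(6, 30, TRUE), g)
  m2 <- stats::setNames(sample.int(6, 30, TRUE), g)
  # pre-permuting the later stage's labels leaves the null law unchanged
  m2b <- stats::setNames(unname(m2)[sample.int(30)], g)
  z_a <- replicate(20, permutation_z(make_partition(m1),
                                     make_partition(m2, 2L), 2,
                                     n_iter = 200)$null_mean)
  z_b <- replicate(20, permutation_z(make_partition(m1),
                                     make_partition(m2b, 2L), 2,
                                     n_iter = 200)$null_mean)
  expect_equal(mean(z_a), mean(z_b), tolerance = 0.15 * mean(z_a))
})

test_that("random gene-set baseline returns one z per replicate and transition", {
  cfg <- simulation_config(n_genes = 150, seed = 10)
  sim <- simulate_all(cfg)
  base <- random_geneset_baseline(sim$matrix, sim$catalog, set_size = 60,
                                  n_rep = 3, k = 2, n_iter = 100, seed = 4)
  expect_equal(nrow(base), 3 * 5)
  expect_setequal(unique(base$rep), 1:3)
  expect_true(all(base$from_stage == base$to_stage - 1))
  expect_error(random_geneset_baseline(sim$matrix, sim$catalog,
                                       set_size = 1e6), "set_size")
})

test_that("pairwise co-occurrence fractions span the planted extremes", {
  an <- toy_anatomy()
  spec <- list(
    t1 = lapply(stats::setNames(1:6, 1:6), function(i) "brain"),
    t2 = lapply(stats::setNames(1:6, 1:6), function(i) "brain"),
    t3 = list(`1` = "yolk"),
    n1 = list(`1` = "brain"))
  m <- make_stm(spec, an)
  cat0 <- gene_catalog(names(spec), is_tf = c(TRUE, TRUE, TRUE, FALSE))
  co <- pairwise_cooccurrence(m, cat0)
  expect_equal(co$n_tf, 3)
  expect_equal(co$fraction["t1", "t2"], 1)  # identical sets at all 6 stages
  expect_equal(co$fraction["t1", "t3"], 0)  # disjoint everywhere
  expect_equal(diag(co$fraction), stats::setNames(rep(1, 3), rownames(co$fraction)))
  expect_equal(co$potential_pairs_exact, 3)
  expect_equal(co$potential_pairs_approx, 4.5)
  # symmetry
  expect_equal(co$fraction, t(co$fraction))
})

test_that("potential-pair bookkeeping reproduces the closed forms", {
  # for a 373-TF repertoire: coarse approximation vs exact pair count
  expect_equal(round(373^2 / 2 / 500) * 500, 69500)
  expect_equal(choose(373, 2), 69378)
})
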