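test_that("ubiquity chi-square matches the hand-computed Pearson statistic", {
  an <- toy_anatomy()
  # stage 1: 20/100 TFs ubiquitous, 50/100 non-TFs ubiquitous
  spec <- c(
    lapply(1:20, function(i) list(`1` = "ubiquitous")),
    lapply(1:80, function(i) list(`1` = "brain")),
    lapply(1:50, function(i) list(`1` = "ubiquitous")),
    lapply(1:50, function(i) list(`1` = "midgut")))
  names(spec) <- sprintf("g%03d", seq_along(spec))
  m <- make_stm(spec, an)
  cat0 <- gene_catalog(names(spec), is_tf = seq_along(spec) <= 100)
  res <- ubiquity_by_stage(m, cat0)
  r1 <- res[res$stage == 1, ]
  expect_equal(c(r1$tf_ubiq, r1$tf_restricted, r1$nontf_ubiq,
                 r1$nontf_restricted), c(20, 80, 50, 50))
  # Pearson: n(ad-bc)^2 / row/col products = 200*9e6/91e6 = 19.78
  expect_equal(r1$chisq, 200 * (20 * 50 - 80 * 50)^2 /
                 (100 * 100 * 70 * 130), tolerance = 1e-10)
  expect_equal(r1$chisq, 19.78, tolerance = 1e-2)
  expect_equal(r1$p, stats::pchisq(r1$chisq, 1, lower.tail = FALSE))
  expect_lt(r1$p, 1e-5)
  # stages with nobody expressed: degenerate, missing p
  expect_true(all(res$degenerate[res$stage > 1]))
})

test_that("ubiquity chi-square is null on identical proportions and pools stages", {
  an <- toy_anatomy()
  spec <- c(
    lapply(1:10, function(i) list(`2` = "ubiquitous", `3` = "ubiquitous")),
    lapply(1:10, function(i) list(`2` = "brain", `3` = "brain")),
    lapply(1:20, function(i) list(`2` = "ubiquitous", `3` = "ubiquitous")),
    lapply(1:20, function(i) list(`2` = "midgut", `3` = "midgut")))
  names(spec) <- sprintf("g%03d", seq_along(spec))
  m <- make_stm(spec, an)
  cat0 <- gene_catalog(names(spec), is_tf = seq_along(spec) <= 20)
  res <- ubiquity_by_stage(m, cat0)
  expect_equal(res$chisq[res$stage == 2], 0)
  expect_equal(res$p[res$stage == 2], 1)
  pooled <- ubiquity_by_stage(m, cat0, pool = 2:3)
  expect_equal(pooled$tf_ubiq, 20)  # gene-stage observations accumulate
  expect_equal(pooled$chisq, 0)
})

test_that("chi-square agrees with a label permutation test on random tables", {
  set.seed(5)
  for (rep in 1:3) {
    n_tf <- 200; n_non <- 300
    p_tf <- stats::runif(1, 0.3, 0.7); p_non <- stats::runif(1, 0.3, 0.7)
    ubiq <- c(stats::runif(n_tf) < p_tf, stats::runif(n_non) < p_non)
    tf <- rep(c(TRUE, FALSE), c(n_tf, n_non))
    tab <- table(tf, ubiq)
    if (any(tab == 0)) next
    chisq <- unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic))
    # permutation null of the same statistic
    perm <- replicate(2000, {
      t2 <- table(sample(tf), ubiq)
      unname(suppressWarnings(
        stats::chisq.test(t2, correct = FALSE)$statistic))
    })
    p_perm <- mean(perm >= chisq - 1e-9)
    p_chi <- stats::pchisq(chisq, 1, lower.tail = FALSE)
    expect_lt(abs(p_perm - p_chi), 0.05)
  }
})

test_that("narrow never-ubiquitous TF selection applies both filters strictly", {
  an <- toy_anatomy()
  m <- make_stm(list(
    a = list(`2` = "ubiquitous", `3` = "brain"),           # ubiq at stage 2
    b = list(`1` = "brain", `4` = "ventral nerve cord"),   # breadth 2
    c = list(`1` = "brain", `2` = "midgut", `3` = "yolk"), # breadth 3
    d = list(`5` = "midgut"),                              # breadth 1
    n = list(`1` = "brain")), an)
  cat0 <- gene_catalog(c("a", "b", "c", "d", "n"),
                       is_tf = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(never_ubiquitous_narrow_tfs(m, cat0), c("b", "d"))
  expect_equal(never_ubiquitous_narrow_tfs(m, cat0, max_breadth = 4),
               c("b", "c", "d"))
})

test_that("exclusively ubiquitous genes never show a restricted pattern", {
  an <- toy_anatomy()
  m <- make_stm(list(
    pure = list(`1` = "ubiquitous", `2` = "ubiquitous"),
    mixed = list(`1` = "ubiquitous", `2` = "brain"),
    mixed2 = list(`3` = c("ubiquitous", "brain")),
    restricted = list(`1` = "brain")), an)
  expect_equal(exclusively_ubiquitous(m), "pure")
  # subset invariant: exclusively ubiquitous genes are ubiquitous somewhere
  ubiq_any <- unique(m$ann$gene_id[m$ann$term == "ubiquitous"])
  expect_true(all(exclusively_ubiquitous(m) %in% ubiq_any))
})

test_that("adult clustering separates planted blocks and names clusters", {
  tissues <- default_adult_tissues()
  up <- matrix(FALSE, 8, 15, dimnames = list(sprintf("g%02d", 1:8), tissues))
  up[1:4, 1:2] <- TRUE    # block 1: brain + thoracic ganglion
  up[5:8, 9:10] <- TRUE   # block 2: ovary + testis
  cl <- adult_specificity_clusters(up, linkage_cut = 0.5)
  expect_equal(cl$n_clusters, 2)
  sizes <- table(cl$membership$cluster)
  expect_equal(sort(as.integer(sizes)), c(4, 4))
  expect_setequal(unlist(cl$defining_tissues),
                  c("brain", "thoracic ganglion", "ovary", "testis"))
  # all-zero vectors excluded with a record
  up0 <- rbind(up, g99 = rep(FALSE, 15))
  cl0 <- adult_specificity_clusters(up0, linkage_cut = 0.5)
  expect_equal(cl0$excluded, "g99")
  expect_error(adult_specificity_clusters(up, ), "linkage_cut")
})

test_that("cluster output is invariant to gene input order", {
  set.seed(8)
  up <- matrix(stats::runif(200) < 0.3, 20, 10,
               dimnames = list(sprintf("g%02d", 1:20), letters[1:10]))
  up[rowSums(up) == 0, 1] <- TRUE
  c1 <- adult_specificity_clusters(up, linkage_cut = 0.6)
  c2 <- adult_specificity_clusters(up[sample(20), ], linkage_cut = 0.6)
  m1 <- c1$membership[order(c1$membership$gene_id), ]
  m2 <- c2$membership[order(c2$membership$gene_id), ]
  expect_equal(c1$n_clusters, c2$n_clusters)
  # identical partitions: co-membership relations coincide
  expect_equal(outer(m1$cluster, m1$cluster, "=="),
               outer(m2$cluster, m2$cluster, "=="))
})

test_that("embryo-adult crosstab reports annotated fractions and top terms", {
  an <- toy_anatomy()
  # 23 annotated members, 8 of them midgut at stage 6 -> 35%
  spec <- c(lapply(1:8, function(i) list(`6` = "midgut")),
            lapply(1:15, function(i) list(`6` = "brain")))
  names(spec) <- sprintf("m%02d", 1:23)
  m <- make_stm(spec, an, genes = c(names(spec), sprintf("u%02d", 1:17)))
  membership <- data.frame(
    gene_id = c(names(spec), sprintf("u%02d", 1:17)), cluster = 1L)
  clusters <- structure(list(membership = membership), class = "adult_clusters")
  ct <- embryo_adult_crosstab(clusters, m)
  expect_equal(unique(ct$n_members), 40)
  expect_equal(unique(ct$n_annotated), 23)
  expect_equal(ct$pct[ct$term == "midgut"], 35)  # 34.8 printed as 35
  # a fully unannotated cluster is flagged empty
  clusters2 <- structure(list(membership = data.frame(
    gene_id = "u01", cluster = 1L)), class = "adult_clusters")
  ct2 <- embryo_adult_crosstab(clusters2, m)
  expect_equal(ct2$n_annotated, 0)
  expect_true(is.na(ct2$term))
})
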