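# shared fixture builders -- everything is generated in code, no data files

toy_anatomy <- function() {
  terms <- c("ubiquitous", "mesoderm", "brain", "ventral nerve cord",
             "midgut", "yolk")
  slim_anatomy(terms, stats::setNames(
    c("ubiquitous", "mesoderm", "neural", "mesectoderm", "endoderm",
      "extraembryonic"), terms))
}

# build a stage_tissue_matrix from a list gene -> list(stage = terms)
make_stm <- function(spec, anatomy = toy_anatomy(), genes = names(spec)) {
  rows <- do.call(rbind, lapply(names(spec), function(g) {
    st <- spec[[g]]
    do.call(rbind, lapply(seq_along(st), function(i) {
      if (!length(st[[i]])) return(NULL)
      data.frame(gene_id = g, stage = as.integer(names(st)[i] %||0% i),
                 term = st[[i]], stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(rows))
    rows <- data.frame(gene_id = character(), stage = integer(),
                       term = character())
  stage_tissue_matrix(genes, rows, anatomy)
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

make_catalog <- function(n, n_tf, families = NULL) {
  ids <- sprintf("g%03d", seq_len(n))
  is_tf <- seq_len(n) <= n_tf
  fam <- if (is.null(families)) ifelse(is_tf, "other", "none")
         else c(families, rep("none", n - n_tf))
  gene_catalog(ids, ids, is_tf, fam)
}

make_partition <- function(membership, stage = 1L) {
  structure(list(stage = stage, membership = membership,
                 groups = split(names(membership), membership)),
            class = "coexpression_partition")
}

gr <- function(starts, ends, contig = "chr2L") {
  if (!length(starts)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(contig,
                         IRanges::IRanges(start = starts + 1L, end = ends))
}

# brute-force conserved k-subset count by subset enumeration
brute_conserved <- function(m1, m2, k) {
  genes <- intersect(names(m1), names(m2))
  if (length(genes) < k) return(0)
  combos <- utils::combn(genes, k)
  sum(apply(combos, 2, function(g)
    length(unique(m1[g])) == 1L && length(unique(m2[g])) == 1L))
}

# greedy one-to-one cluster matching agreement
cluster_agreement <- function(membership, truth) {
  m <- merge(membership, truth, by = "gene_id")
  tab <- as.matrix(table(m$cluster, m$truth_cluster))
  tot <- 0
  while (nrow(tab) && ncol(tab)) {
    i <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    tot <- tot + tab[i[1], i[2]]
    tab <- tab[-i[1], -i[2], drop = FALSE]
  }
  tot / nrow(m)
}
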