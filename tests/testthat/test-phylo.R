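# Gap stripping, distances, neighbor joining, rooting, RF incongruence

test_that("strip_gap_columns removes exactly the gapped columns", {
  aln <- c(a = "AC-G", b = "ACTG")
  out <- strip_gap_columns(aln)
  expect_equal(unname(out), c("ACG", "ACG"))
  clean <- c(a = "ACGT", b = "ACGT")
  expect_equal(strip_gap_columns(clean), clean)
  expect_error(strip_gap_columns(c(a = "-C", b = "A-")), "all columns")
})

test_that("p-distances and corrections are computed as defined", {
  aln <- c(a = "AAAA", b = "AAAT")
  d <- pdistance_matrix(aln, "none")
  expect_equal(d["a", "b"], 0.25)
  expect_equal(diag(d), c(a = 0, b = 0))
  djc <- pdistance_matrix(aln, "jc")
  expect_equal(djc["a", "b"], -0.75 * log(1 - 4 * 0.25 / 3))
  # pairwise deletion of residual gaps
  d2 <- pdistance_matrix(c(a = "A-AT", b = "AGAA"), "none")
  expect_equal(d2["a", "b"], 1 / 3)
  # amino-acid Poisson correction and saturation cap
  dp <- pdistance_matrix(c(a = "AAAA", b = "AAAC"), "poisson")
  expect_equal(dp["a", "b"], -log(1 - 0.25))
  expect_warning(ds <- pdistance_matrix(c(a = "ACGT", b = "CGTA"), "jc", cap = 3),
                 "saturated")
  expect_equal(ds["a", "b"], 3)
})

test_that("neighbor joining recovers an additive 4-taxon tree exactly", {
  # tree ((A:2,B:3):1,(C:4,D:5)) -> additive distances
  dm <- matrix(c(0, 5, 7, 8,
                 5, 0, 8, 9,
                 7, 8, 0, 9,
                 8, 9, 9, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  expect_true(clade_test(tr, c("A", "B")))
  expect_true(clade_test(tr, c("C", "D")))
  # additive matrix: path lengths reproduce the input distances
  pd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(pd, dm, tolerance = 1e-10, ignore_attr = TRUE)
  # taxon-order permutation leaves the unrooted topology unchanged
  perm <- c("C", "A", "D", "B")
  tr2 <- nj_tree(dm[perm, perm])
  expect_equal(rf_distance(tr, tr2)$rf, 0L)
})

test_that("three taxa give the closed-form star lengths", {
  dm <- matrix(c(0, 3, 5,
                 3, 0, 4,
                 5, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                  tr$tip.label)
  expect_equal(len[["A"]], (3 + 5 - 4) / 2)
  expect_equal(len[["B"]], (3 + 4 - 5) / 2)
  expect_equal(len[["C"]], (5 + 4 - 3) / 2)
  expect_error(nj_tree(dm[1:2, 1:2]), "3 taxa")
})

test_that("midpoint rooting centers the longest leaf-to-leaf path", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):0,D:10);")
  rooted <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(rooted)
  tipd <- setNames(depths[seq_along(rooted$tip.label)], rooted$tip.label)
  # root-to-tip distance of the long-branch leaf equals half the diameter
  diam <- max(ape::cophenetic.phylo(tr))
  expect_equal(unname(tipd[["D"]]), diam / 2)
  # re-rooting preserves pairwise path lengths
  expect_equal(ape::cophenetic.phylo(rooted)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-10)
})

test_that("RF distance is 0 for identical and 2 for NNI-adjacent trees", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1)$rf, 0L)
  r <- rf_distance(t1, t2)
  expect_equal(r$rf, 2L)
  expect_equal(r$normalized, 1.0)
  # single NNI on a 5-taxon tree also gives 2
  t5a <- ape::read.tree(text = "(((A,B),C),(D,E));")
  t5b <- ape::read.tree(text = "(((A,C),B),(D,E));")
  expect_equal(rf_distance(t5a, t5b)$rf, 2L)
  # fewer than 4 shared taxa: not evaluated
  expect_true(is.na(rf_distance(ape::read.tree(text = "((A,B),C);"),
                                ape::read.tree(text = "((A,B),C);"))$rf))
})

test_that("RF behaves as a metric on all 5-taxon topologies", {
  topos <- phangorn::allTrees(5, rooted = FALSE, tip.label = LETTERS[1:5])
  n <- length(topos)
  rf <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    rf[i, j] <- rf_distance(topos[[i]], topos[[j]])$rf
  expect_true(all(diag(rf) == 0L))
  expect_true(all(rf[upper.tri(rf)] > 0L))
  expect_identical(rf, t(rf))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(rf[i, k], rf[i, j] + rf[j, k])
})

test_that("clade_test evaluates bipartitions in the unrooted sense", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(clade_test(tr, c("A", "B")))
  expect_false(clade_test(ape::read.tree(text = "((A,C),(B,D));"), c("A", "B")))
  expect_message(res <- clade_test(tr, "A"), "convention")
  expect_true(res)
  expect_error(clade_test(tr, c("A", "Z")), "not all present")
})

test_that("NJ recovers the true 4-taxon topology in nearly all replicates", {
  empty_genes <- data.frame(gene_id = character(), contig_id = character(),
                            start = integer(), end = integer(),
                            strand = character())
  good <- 0L
  for (r in 1:100) {
    set.seed(r)
    root <- list(genome_vec = sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
                 genes = empty_genes)
    ab <- evolve(root, 0.02)
    tips <- list(A = evolve(ab, 0.03), B = evolve(ab, 0.03),
                 C = evolve(root, 0.05), O = evolve(root, 0.15))
    aln <- vapply(tips, function(t) paste(t$genome_vec, collapse = ""),
                  character(1))
    tr <- gene_tree(aln, "nt")
    if (clade_test(tr, c("A", "B"))) good <- good + 1L
  }
  expect_gte(good, 95L)
})

test_that("planted xenolog gene trees are incongruent with the species tree", {
  trio <- trio_small()
  sp <- trio_species_tree(trio$config)
  tx <- trio$truth
  incong <- vapply(seq_len(nrow(tx)), function(i) {
    aln <- trio_gene_alignment(trio, tx$gene_id[i])
    gt <- suppressWarnings(gene_tree(aln, "nt"))
    isTRUE(rf_distance(gt, sp)$rf > 0L)
  }, logical(1))
  expect_gt(mean(incong), 0.5)
  # a long vertically inherited gene agrees with the species tree
  ga <- trio$genomes$A$genes
  cand <- ga[!ga$gene_id %in% tx$gene_id, ]
  normal <- cand$gene_id[which.max(cand$end - cand$start)]
  gt0 <- gene_tree(trio_gene_alignment(trio, normal), "nt")
  expect_equal(rf_distance(gt0, sp)$rf, 0L)
})
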