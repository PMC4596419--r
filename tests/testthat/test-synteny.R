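# Anchors, collinearity, contig ordering, clusters, evidence integration

test_that("a genome anchors perfectly onto itself", {
  g <- trio_plain()$genomes$A
  an <- find_anchors(g$proteins, g$genes, g$proteins, g$genes)
  expect_equal(nrow(an), nrow(g$genes))
  expect_true(all(an$orientation == "same"))
  expect_true(all(an$query_mid == an$ref_mid))
  expect_equal(collinearity_chain(an)$fraction, 1.0)
})

test_that("sister genomes anchor near-completely and reciprocally", {
  trio <- trio_plain()
  a <- trio$genomes$A; b <- trio$genomes$B
  an <- find_anchors(a$proteins, a$genes, b$proteins, b$genes)
  expect_gte(nrow(an) / nrow(a$genes), 0.95)
  an_rev <- find_anchors(b$proteins, b$genes, a$proteins, a$genes)
  expect_setequal(paste(an$query_gene, an$ref_gene),
                  paste(an_rev$ref_gene, an_rev$query_gene))
  expect_equal(collinearity_chain(an)$fraction, 1.0, tolerance = 0.02)
})

test_that("an in-silico block swap breaks collinearity by the block size", {
  trio <- trio_plain()
  a <- trio$genomes$A; b <- trio$genomes$B
  an <- find_anchors(a$proteins, a$genes, b$proteins, b$genes)
  an <- an[order(an$ref_mid), ]
  n <- nrow(an)
  swapped <- an
  i1 <- 1:10; i2 <- (n - 9):n
  swapped$query_mid[c(i1, i2)] <- swapped$query_mid[c(i2, i1)]
  cc <- collinearity_chain(swapped)
  expect_lte(cc$chain_length, n - 10)
  expect_lt(cc$fraction, 1.0)
})

test_that("LIS chain matches the quadratic oracle and Ulam scaling", {
  set.seed(77)
  x <- sample(100)
  an <- data.frame(ref_mid = seq_along(x), query_mid = x)
  expect_equal(collinearity_chain(an)$chain_length,
               max(lis_oracle(x), lis_oracle(-x)))
  # fully reversed anchors are fully collinear via the decreasing chain
  an_rev <- data.frame(ref_mid = 1:50, query_mid = 50:1)
  expect_equal(collinearity_chain(an_rev)$fraction, 1.0)
  # random permutations of n = 400: chain near 2 sqrt(n)
  chains <- vapply(1:5, function(s) {
    set.seed(s)
    p <- sample(400)
    collinearity_chain(data.frame(ref_mid = seq_along(p), query_mid = p))$chain_length
  }, numeric(1))
  expect_true(all(abs(chains - 2 * sqrt(400)) <= 3 * 400^(1/6) + 3))
})

test_that("collinearity is invariant to shifts and contig relabeling", {
  trio <- trio_plain()
  a <- trio$genomes$A; b <- trio$genomes$B
  an <- find_anchors(a$proteins, a$genes, b$proteins, b$genes)
  base <- collinearity_chain(an)
  shifted <- an
  shifted$query_mid <- shifted$query_mid + 1e6
  shifted$ref_mid <- shifted$ref_mid + 5e5
  expect_equal(collinearity_chain(shifted), base)
  relabeled <- an
  relabeled$query_contig <- "renamed"
  expect_equal(collinearity_chain(relabeled), base)
})

test_that("contig ordering recovers the true fragmentation order", {
  cfg <- trio_config(seed = 5, genome_length = 1.2e5, n_genes = 120,
                     n_contigs = c(A = 8, B = 1, C = 1), xenolog_plan = NULL)
  trio <- simulate_trio(cfg)
  a <- trio$genomes$A; b <- trio$genomes$B
  an <- find_anchors(a$proteins, a$genes, b$proteins, b$genes)
  oc <- order_contigs(an, names(a$contigs$contigs))
  off <- a$contig_offsets
  expect_equal(oc$contig_id[oc$anchored],
               off$contig_id[order(off$offset)][seq_len(sum(oc$anchored))])
  expect_true(all(oc$orientation[oc$anchored] == "same"))
  # single-contig query: identity ordering; anchorless contig appended+flagged
  oc1 <- order_contigs(an[an$query_contig == "c01", ], c("c01", "cEmpty"))
  expect_equal(oc1$contig_id, c("c01", "cEmpty"))
  expect_false(oc1$anchored[2])
})

test_that("extract_cluster returns contiguous genes in genomic order", {
  g <- trio_plain()$genomes$A$genes
  g <- g[order(g$start), ]
  cl <- extract_cluster(g, g$gene_id[3], g$gene_id[9])
  expect_equal(nrow(cl), 7L)
  expect_equal(cl$gene_id, g$gene_id[3:9])
  expect_equal(extract_cluster(g, g$gene_id[5], g$gene_id[5])$gene_id,
               g$gene_id[5])
  # reversed bounds are normalized
  expect_equal(extract_cluster(g, g$gene_id[9], g$gene_id[3])$gene_id,
               g$gene_id[3:9])
  g2 <- g
  g2$contig_id[1] <- "other"
  expect_error(extract_cluster(g2, g2$gene_id[1], g2$gene_id[5]), "contig")
})

test_that("cluster comparison maps homologs and carries evidence flags", {
  trio <- trio_small()
  tx <- trio$truth[trio$truth$cluster, ]
  ids <- tx$gene_id
  gC <- trio$genomes$C
  ordC <- gC$genes[order(gC$genes$start), ]
  cl_C <- extract_cluster(gC$genes, ids[1], ids[length(ids)])
  cl_A <- trio$genomes$A$genes[trio$genomes$A$genes$gene_id %in% cl_C$gene_id, ]
  comp <- list(C = composition_report(gC$cds),
               A = composition_report(trio$genomes$A$cds))
  cc <- compare_clusters(list(A = cl_A, C = cl_C),
                         list(A = trio$genomes$A$proteins, C = gC$proteins),
                         composition = comp)
  # reference cluster maps to itself
  expect_true(all(cc$ref_match[cc$genome == "A"] == cc$gene_id[cc$genome == "A"]))
  # planted genes in C: no homology to A (donor-model replacement), flagged
  planted_rows <- cc[cc$genome == "C" & cc$gene_id %in% ids, ]
  expect_true(all(is.na(planted_rows$ref_match)))
  flagged <- planted_rows$tetra == "yes" | planted_rows$codon == "yes" |
    planted_rows$gc == "yes"
  # the weak-donor cluster (GC 0.49 vs 0.377 background) flags most but not
  # necessarily every member gene
  expect_gte(mean(flagged), 0.7)
  expect_true(any(flagged))
  # non-planted flanking genes in the C cluster match their A orthologs
  flank <- cc[cc$genome == "C" & !cc$gene_id %in% ids, ]
  if (nrow(flank)) expect_true(all(!is.na(flank$ref_match)))
  lines <- cluster_diagram(cc)
  expect_length(lines, 2L)
  expect_true(any(grepl("\\*", lines)))
})

test_that("evidence classes follow the parametric-then-support rule", {
  comp <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    length = c(900, 900, 900, 900, 150),
    gc = 0.4, gc_flag = c(FALSE, TRUE, FALSE, TRUE, FALSE),
    tetra_score = 0.1, tetra_flag = c(FALSE, TRUE, TRUE, FALSE, NA),
    codon_score = 0.1, codon_flag = c(FALSE, FALSE, FALSE, FALSE, NA)
  )
  ev <- hgt_evidence_table(comp, tree_incongruent = c(g3 = TRUE))
  expect_equal(ev$class,
               c("none", "supported", "supported",
                 "none", "not evaluated"))
  s <- attr(ev, "summary")
  expect_equal(sum(s$count), 5L)
  expect_equal(s$percent[s$class == "supported"], 40)
  # gc alone (g4) is not parametric evidence
  expect_equal(ev$class[4], "none")
})
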