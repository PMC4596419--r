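# Simulator contracts: determinism, composition targets, the Jukes-Cantor
# substitution process, and planted-xenolog bookkeeping.

test_that("identical config and seed give byte-identical trios", {
  cfg <- trio_config(seed = 21, genome_length = 4e4, n_genes = 40)
  t1 <- simulate_trio(cfg)
  t2 <- simulate_trio(cfg)
  for (nm in names(t1$genomes)) {
    expect_identical(as.character(t1$genomes[[nm]]$contigs$contigs),
                     as.character(t2$genomes[[nm]]$contigs$contigs))
  }
  expect_identical(t1$truth, t2$truth)
  expect_identical(t1$branch_subs, t2$branch_subs)
})

test_that("ancestral genome GC matches the configured background", {
  cfg <- trio_config(seed = 5, genome_length = 1e6, n_genes = 800,
                     gc_background = 0.5, xenolog_plan = NULL)
  anc <- simulate_ancestor(cfg)
  expect_lt(abs(gc_content(anc$contigs) - 0.5), 0.005)
})

test_that("every simulated CDS is a valid gene and translates cleanly", {
  trio <- trio_plain()
  for (nm in c("A", "B", "C")) {
    cds <- trio$genomes[[nm]]$cds
    expect_true(all(substr(cds, 1, 3) == "ATG"))
    expect_true(all(substr(cds, nchar(cds) - 2, nchar(cds)) == "TAA"))
    prots <- vapply(cds, translate_cds, character(1))  # would warn on '*'
    expect_false(any(grepl("\\*", prots)))
    # stored proteome equals extract + translate
    expect_identical(unname(prots),
                     unname(as.character(trio$genomes[[nm]]$proteins$proteins)))
  }
})

test_that("evolve applies Jukes-Cantor substitutions at the expected rate", {
  set.seed(99)
  parent <- list(genome_vec = sample(c("A", "C", "G", "T"), 1e6, replace = TRUE),
                 genes = data.frame(gene_id = character(), contig_id = character(),
                                    start = integer(), end = integer(),
                                    strand = character()))
  same <- evolve(parent, 0)
  expect_identical(same$genome_vec, parent$genome_vec)
  expect_error(evolve(parent, -0.1), ">= 0")

  child <- evolve(parent, 0.012, seed = 7)
  p <- pdist_vec(parent$genome_vec, child$genome_vec)
  p_expect <- 0.75 * (1 - exp(-4 * 0.012 / 3))
  expect_lt(abs(p - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / 1e6))
  # reproducible under fixed seed
  child2 <- evolve(parent, 0.012, seed = 7)
  expect_identical(child$genome_vec, child2$genome_vec)
})

test_that("measured sister p-distance matches the JC expectation", {
  trio <- trio_plain()
  cfg <- trio$config
  p <- pdist_vec(trio$genomes$A$genome_vec, trio$genomes$B$genome_vec)
  d_tot <- 2 * cfg$d_sister
  p_expect <- 0.75 * (1 - exp(-4 * d_tot / 3))
  n <- cfg$genome_length
  expect_lt(abs(p - p_expect), 3 * sqrt(p_expect * (1 - p_expect) / n))
})

test_that("planted xenologs take the donor GC and are recorded in truth", {
  trio <- trio_small()
  tx <- trio$truth
  expect_true(all(tx$gene_id %in% unlist(lapply(trio$genomes, function(g)
    g$genes$gene_id))))
  # realized GC near the donor model's stationary GC
  for (i in seq_len(nrow(tx))) {
    g <- trio$genomes[[tx$genome[i]]]
    gc <- gc_content(g$cds[[tx$gene_id[i]]])
    tol <- max(0.03, 3 * sqrt(tx$donor_gc[i] * (1 - tx$donor_gc[i]) /
                                nchar(g$cds[[tx$gene_id[i]]])))
    expect_lt(abs(gc - tx$donor_gc[i]), tol)
  }
  # default plan: 4 singleton events + one 7-gene cluster
  expect_equal(sum(!tx$cluster), 4L)
  expect_equal(sum(tx$cluster), 7L)
  expect_error(plant_xenolog(trio$genomes$A, "nope", 0.6), "unknown gene_id")
})

test_that("a background-matched order-0 donor is GC-indistinguishable", {
  cfg <- trio_config(seed = 17, genome_length = 3e4, n_genes = 30,
                     xenolog_plan = NULL)
  anc <- simulate_ancestor(cfg)
  genome <- list(genome_vec = anc$genome_vec, genes = anc$genes)
  cds0 <- extract_all_cds(anc$contigs, anc$genes)
  gcs <- gc_content_each(cds0)
  m <- mean(gcs); s <- sd(gcs)
  hits <- 0L
  for (sd_i in 1:100) {
    g2 <- plant_xenolog(genome, "g0005", cfg$gc_background, markov_order = 0,
                        seed = sd_i)
    cs <- contig_set("x", c(chr = paste(g2$genome_vec, collapse = "")))
    gc <- gc_content(extract_cds(cs, anc$genes[anc$genes$gene_id == "g0005", ]))
    if (abs(gc - m) < 2 * s) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("fragmentation preserves gene content and contig invariants", {
  cfg <- trio_config(seed = 9, genome_length = 5e4, n_genes = 50,
                     n_contigs = c(A = 6, B = 1, C = 1), xenolog_plan = NULL)
  trio <- simulate_trio(cfg)
  a <- trio$genomes$A
  expect_equal(length(a$contigs$contigs), 6L)
  expect_equal(sum(Biostrings::width(a$contigs$contigs)), cfg$genome_length)
  # fragmented CDS set identical to the unfragmented sister layout
  expect_true(all(substr(a$cds, 1, 3) == "ATG"))
  expect_equal(sort(a$genes$gene_id), sort(trio$genomes$B$genes$gene_id))
  # genes stay within their contig
  w <- setNames(Biostrings::width(a$contigs$contigs), names(a$contigs$contigs))
  expect_true(all(a$genes$end <= w[a$genes$contig_id]))
})
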