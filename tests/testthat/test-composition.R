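# Tetranucleotide, codon-usage (RSCU) and GC screens

test_that("tetra_profile counts overlapping 4-mers correctly", {
  p <- tetra_profile("AAAA")
  expect_equal(unname(p[["AAAA"]]), 1)
  expect_equal(attr(p, "n_windows"), 1L)
  p2 <- tetra_profile("AAAAA")
  expect_equal(unname(p2[["AAAA"]]), 1)
  expect_equal(attr(p2, "n_windows"), 2L)
  # copy-number invariance (junction windows vanish for long sequences)
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  expect_lt(max(abs(tetra_profile(s) - tetra_profile(strrep(s, 3)))), 0.002)
  # windows containing N are skipped
  pn <- tetra_profile("AAAANAAAA")
  expect_equal(attr(pn, "n_windows"), 2L)
  expect_equal(unname(pn[["AAAA"]]), 1)
  expect_error(tetra_profile("ACG"), "window")
  expect_error(tetra_profile("AAANAAA"), "window")
})

test_that("the GC filter flags exactly the constructed high-GC genes", {
  genes <- c(setNames(replicate(98, seq_with_gc(300, 0.38)),
                      sprintf("n%02d", 1:98)),
             hi1 = seq_with_gc(300, 0.61), hi2 = seq_with_gc(300, 0.57))
  out <- gc_outliers(genes)
  expect_setequal(out$gene_id[out$gc_flag], c("hi1", "hi2"))
  # thresholds recomputed independently
  gcs <- c(rep(0.38, 98), 0.61, 0.57)
  expect_equal(mean(out$gc), mean(gcs), tolerance = 1e-6)
  expect_true(abs(0.61 - mean(gcs)) > 2 * sd(gcs))
  expect_true(abs(0.38 - mean(gcs)) < 2 * sd(gcs))
})

test_that("degenerate GC inputs behave per the strict rule", {
  same <- setNames(replicate(30, seq_with_gc(300, 0.4)), sprintf("g%d", 1:30))
  out <- gc_outliers(same)
  expect_false(any(out$gc_flag))  # SD 0, strict >
  expect_error(gc_outliers(same[1]), "at least 2")
})

test_that("tetra scores are zero against an identical background", {
  same <- setNames(replicate(25, seq_with_gc(400, 0.4)), sprintf("g%d", 1:25))
  out <- tetra_outliers(same)
  expect_true(all(out$tetra_score < 1e-12))
  expect_false(any(out$tetra_flag))
  expect_error(tetra_outliers(same[1:10]), "20")
})

test_that("genes below min_len are reported not evaluated", {
  set.seed(1)
  cfg <- trio_config(seed = 40, genome_length = 4e4, n_genes = 40,
                     gene_length_mean = 500, gene_length_sd = 200,
                     xenolog_plan = NULL)
  anc <- simulate_ancestor(cfg)
  cds <- extract_all_cds(anc$contigs, anc$genes)
  short <- names(cds)[nchar(cds) < 300]
  rep <- composition_report(cds)
  if (length(short)) {
    expect_true(all(is.na(rep$tetra_flag[rep$gene_id %in% short])))
    expect_true(all(is.na(rep$codon_flag[rep$gene_id %in% short])))
    expect_false(any(is.na(rep$gc_flag)))
  }
})

test_that("rscu matches a hand computation and flags biased usage", {
  # two-codon family example: 3x TTT vs 1x TTC -> RSCU 1.5 / 0.5
  s <- "TTTTTTTTTTTC"
  r <- rscu(s)
  expect_equal(unname(r[["TTT"]]), 1.5)
  expect_equal(unname(r[["TTC"]]), 0.5)
  expect_equal(length(r), 59L)
  # balanced usage gives RSCU 1 everywhere it is defined
  r2 <- rscu("TTTTTCGGAGGT")
  expect_equal(unname(r2[["TTT"]]), 1)
  expect_equal(unname(r2[["GGA"]]), unname(r2[["GGT"]]))
})

test_that("a uniform-synonymous gene stands out against a GC3-biased background", {
  set.seed(12)
  fams <- list(c("GCC", "GCA"), c("CGC", "CGT"), c("ACC", "ACA"), c("GGC", "GGA"))
  biased_gene <- function() {
    cods <- unlist(lapply(fams, function(f)
      sample(f, 75, replace = TRUE, prob = c(0.95, 0.05))))
    paste(c("ATG", sample(cods), "TAA"), collapse = "")
  }
  uniform_gene <- paste(c("ATG",
                          sample(unlist(lapply(fams, rep, times = 75))),
                          "TAA"), collapse = "")
  genes <- c(setNames(replicate(40, biased_gene()), sprintf("b%02d", 1:40)),
             u1 = uniform_gene)
  out <- codon_usage_outliers(genes)
  expect_true(out$codon_flag[out$gene_id == "u1"])
  expect_lt(mean(out$codon_flag[out$gene_id != "u1"]), 0.15)
  # length not divisible by 3 is excluded with a warning
  genes2 <- c(genes, bad = paste0(uniform_gene, "A"))
  expect_warning(out2 <- codon_usage_outliers(genes2), "multiple of 3")
  expect_true(is.na(out2$codon_flag[out2$gene_id == "bad"]))
})

test_that("planted donor-model genes are flagged by the tetra screen", {
  trio <- trio_small()
  g <- trio$genomes$C
  rep <- composition_report(g$cds)
  planted <- trio$truth$gene_id[trio$truth$genome == "C" &
                                  trio$truth$donor_gc >= 0.49]
  flags <- rep$tetra_flag[rep$gene_id %in% planted] |
    rep$codon_flag[rep$gene_id %in% planted] |
    rep$gc_flag[rep$gene_id %in% planted]
  expect_gte(mean(flags, na.rm = TRUE), 0.7)
})

test_that("tetra sensitivity rises with donor GC distance", {
  cfg0 <- trio_config(seed = 33, genome_length = 8e4, n_genes = 80,
                      xenolog_plan = NULL)
  base <- simulate_ancestor(cfg0)
  genome <- list(genome_vec = base$genome_vec, genes = base$genes)
  cs_of <- function(g) contig_set("x", c(chr = paste(g$genome_vec, collapse = "")))
  sens <- vapply(c(0.42, 0.50, 0.62), function(dgc) {
    g2 <- genome
    targets <- sprintf("g%04d", seq(5, 50, by = 5))
    for (k in seq_along(targets))
      g2 <- plant_xenolog(g2, targets[k], dgc, markov_order = 2,
                          seed = 100 + k)
    cds <- extract_all_cds(cs_of(g2), base$genes)
    out <- tetra_outliers(cds)
    mean(out$tetra_flag[out$gene_id %in% targets], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})
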