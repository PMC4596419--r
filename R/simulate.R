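# Seeded genome-trio simulator with planted xenologs. The trio topology is
# fixed at ((A,B),C); an optional outgroup O splits off first. Sequences are
# stored as plain character vectors of bases internally for fast vectorized
# mutation; no indels are introduced, so gene coordinates are shared across
# the trio and per-gene alignments are gap-free by construction.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the genome-trio simulator
#'
#' Defaults emulate the study system: three ~98-99% ANI subspecies genomes
#' of low GC (0.377) carrying a handful of recently acquired high-GC genes
#' (cooS/cooF-like singletons) and one transferred gene cluster (mbx-like).
#' Divergences are Jukes-Cantor branch lengths (expected substitutions per
#' site): the sister distance `2 * d_sister` is tuned so that A-B ANI is
#' ~98.8% and the A-C / B-C distance gives ~98.0%.
#'
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @param genome_length Genome length in nt (single linear contig before
#'   optional fragmentation).
#' @param n_genes Number of CDSs to place.
#' @param gene_length_mean,gene_length_sd Gene length distribution in nt
#'   (normal, rounded to codons, clamped to `[150, 3000]`).
#' @param gc_background Background GC fraction.
#' @param d_sister Branch length from the A-B ancestor to each of A and B.
#' @param d_internal Branch length from the root to the A-B ancestor.
#' @param d_c Branch length from the root to C.
#' @param d_outgroup Branch length from the root to an outgroup genome `O`,
#'   or `NULL` for no outgroup.
#' @param xenolog_plan `data.frame` with columns `recipient` (`"A"`, `"B"`,
#'   `"C"`), `n_genes` (genes per event), `cluster` (logical: one contiguous
#'   run sharing a donor model vs independent singletons), `donor_gc`,
#'   `markov_order` (0-3). `NULL` plants nothing.
#' @param donor_jitter Concentration of the Beta jitter applied to donor
#'   Markov transition rows (smaller = stronger compositional signature).
#' @param n_contigs Fragment emitted genomes into this many contigs at
#'   uniform intergenic breakpoints (1 = single contig). Either a single
#'   count applied to every genome or a named vector per genome, e.g.
#'   `c(A = 20, B = 1, C = 1)` for a draft assembly against complete
#'   sisters.
#' @return A `TrioConfig` list.
#' @export
trio_config <- function(seed = 1L,
                        genome_length = 2.4e6,
                        n_genes = 2500L,
                        gene_length_mean = 850,
                        gene_length_sd = 250,
                        gc_background = 0.377,
                        d_sister = 0.00605,
                        d_internal = 0.00409,
                        d_c = 0.01013,
                        d_outgroup = NULL,
                        xenolog_plan = default_xenolog_plan(),
                        donor_jitter = 8,
                        n_contigs = 1L) {
  stopifnot(gc_background > 0, gc_background < 1,
            d_sister >= 0, d_internal >= 0, d_c >= 0,
            n_genes * gene_length_mean < genome_length)
  if (!is.null(xenolog_plan)) {
    stopifnot(all(c("recipient", "n_genes", "cluster", "donor_gc",
                    "markov_order") %in% names(xenolog_plan)),
              all(xenolog_plan$donor_gc > 0), all(xenolog_plan$donor_gc < 1),
              all(xenolog_plan$markov_order %in% 0:3))
  }
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 gene_length_mean = gene_length_mean, gene_length_sd = gene_length_sd,
                 gc_background = gc_background, d_sister = d_sister,
                 d_internal = d_internal, d_c = d_c, d_outgroup = d_outgroup,
                 xenolog_plan = xenolog_plan, donor_jitter = donor_jitter,
                 n_contigs = setNames(as.integer(n_contigs), names(n_contigs))),
            class = "TrioConfig")
}

#' Default xenolog plan: high-GC singletons in B and C plus a cluster in C
#'
#' Mirrors the motivating system: two recently replaced high-GC genes in each
#' of the two carboxydotroph-like recipients (donor GC 0.57/0.61 and
#' 0.49/0.51) and one seven-gene cluster transfer (donor GC 0.49) in C.
#'
#' @return A `data.frame` usable as `xenolog_plan` in [trio_config()].
#' @export
default_xenolog_plan <- function() {
  data.frame(
    recipient    = c("B", "B", "C", "C", "C"),
    n_genes      = c(1L, 1L, 1L, 1L, 7L),
    cluster      = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    donor_gc     = c(0.61, 0.57, 0.49, 0.51, 0.49),
    markov_order = c(2L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

## ---- internal sequence helpers (character-vector representation) ----

rand_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

codons_of <- function(v) {
  # v: character vector of bases, length divisible by 3
  paste0(v[c(TRUE, FALSE, FALSE)], v[c(FALSE, TRUE, FALSE)], v[c(FALSE, FALSE, TRUE)])
}

revcomp_vec <- function(v) rev(chartr("ACGT", "TGCA", v))

# Stop-codon exclusion skews coding sequence away from the raw base
# distribution: stop codons (TAA/TAG/TGA) are AT-rich, so removing them
# raises realized GC. This solves for the generation-time GC g such that the
# conditional mean GC per codon, given no in-frame stop, equals gc_target.
gc_nonstop_adjust <- function(gc_target) {
  f <- function(g) {
    at <- (1 - g) / 2; gcb <- g / 2
    p_taa <- at^3
    p_tag <- at^2 * gcb
    p_tga <- at^2 * gcb
    p_stop <- p_taa + p_tag + p_tga
    (3 * g - (p_tag + p_tga)) / (3 * (1 - p_stop)) - gc_target
  }
  uniroot(f, c(1e-4, 1 - 1e-4), tol = 1e-10)$root
}

# Resample in-frame internal stop codons from an i.i.d. background model
# until none remain. v covers the full CDS in coding orientation.
purge_internal_stops <- function(v, gc) {
  repeat {
    cod <- codons_of(v)
    bad <- which(cod %in% STOP_CODONS)
    bad <- bad[bad < length(cod)]          # terminal stop is legitimate
    if (!length(bad)) return(v)
    for (j in bad) v[(3L * j - 2L):(3L * j)] <- rand_bases(3L, gc)
  }
}

#' Simulate an ancestral genome with placed genes
#'
#' Draws an i.i.d. genome at the background GC, then places `n_genes`
#' non-overlapping CDSs uniformly at random (both strands, probability 1/2
#' each). Every CDS starts `ATG`, ends `TAA`, and contains no internal
#' in-frame stop codon (offending codons are resampled).
#'
#' @param config A `TrioConfig`.
#' @return List with `contigs` (a `ContigSet` with one contig `chr`) and
#'   `genes` (gene-model `data.frame`).
#' @export
simulate_ancestor <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  gc <- config$gc_background
  n <- config$n_genes
  lens <- round(rnorm(n, config$gene_length_mean, config$gene_length_sd))
  lens <- pmin(pmax(lens, 150L), 3000L)
  lens <- as.integer(3L * round(lens / 3L))
  total <- sum(lens)
  slack <- L - total
  if (slack < n) stop("cannot place ", n, " genes in ", L,
                      " nt without overlap; lower n_genes")
  # uniform non-overlapping placement: n sorted points in the slack space
  offsets <- sort(sample.int(slack, n))
  starts <- offsets + c(0L, cumsum(lens)[-n])
  ends <- starts + lens - 1L
  genome <- rand_bases(L, gc)
  gadj <- gc_nonstop_adjust(gc)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  for (i in seq_len(n)) {
    # gene bodies are generated at the stop-adjusted GC so the realized
    # (stop-free) coding GC matches gc_background
    v <- c("A", "T", "G", rand_bases(lens[i] - 6L, gadj), "T", "A", "A")
    v <- purge_internal_stops(v, gadj)
    if (strand[i] == "-") v <- revcomp_vec(v)
    genome[starts[i]:ends[i]] <- v
  }
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    contig_id = "chr",
    start = starts, end = ends, strand = strand,
    product = "hypothetical protein",
    stringsAsFactors = FALSE
  )
  list(
    contigs = contig_set("ancestor", c(chr = paste(genome, collapse = ""))),
    genes = genes,
    genome_vec = genome
  )
}

# Apply Jukes-Cantor substitutions to a base vector; genes (coding-strand
# intervals) are kept free of internal stops and keep their ATG/TAA termini
# by redrawing the offending codon's substitutions. Returns list(vec, n_sub).
jc_mutate <- function(genome, genes, d) {
  if (d < 0) stop("divergence must be >= 0")
  if (d == 0) return(list(vec = genome, n_sub = 0L))
  p <- 0.75 * (1 - exp(-4 * d / 3))
  L <- length(genome)
  hit <- which(runif(L) < p)
  mutated <- genome
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    mutated[hit] <- BASES[(match(genome[hit], BASES) - 1L + shift) %% 4L + 1L]
  }
  # repair genes: no internal stop, termini fixed
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]; e <- genes$end[i]
    v <- mutated[s:e]
    if (genes$strand[i] == "-") v <- revcomp_vec(v)
    len <- length(v)
    v[1:3] <- c("A", "T", "G")
    v[(len - 2L):len] <- c("T", "A", "A")
    orig <- genome[s:e]
    if (genes$strand[i] == "-") orig <- revcomp_vec(orig)
    repeat {
      cod <- codons_of(v)
      bad <- which(cod %in% STOP_CODONS)
      bad <- bad[bad < len / 3L]
      if (!length(bad)) break
      for (j in bad) {
        idx <- (3L * j - 2L):(3L * j)
        # redraw this codon's substitutions from the JC process
        v[idx] <- orig[idx]
        redo <- which(runif(3L) < p)
        if (length(redo)) {
          shift <- sample.int(3L, length(redo), replace = TRUE)
          pos <- idx[redo]
          v[pos] <- BASES[(match(orig[pos], BASES) - 1L + shift) %% 4L + 1L]
        }
      }
      if (!any(codons_of(v)[seq_len(len / 3L - 1L)] %in% STOP_CODONS)) break
    }
    if (genes$strand[i] == "-") v <- revcomp_vec(v)
    mutated[s:e] <- v
  }
  list(vec = mutated, n_sub = sum(mutated != genome))
}

#' Evolve a genome along a branch under the Jukes-Cantor model
#'
#' Each site substitutes with probability `3/4 * (1 - exp(-4 d / 3))` to a
#' uniformly chosen different base. Gene coordinates are preserved; CDSs are
#' kept biologically valid (ATG...TAA, no internal in-frame stop) by
#' redrawing substitutions in offending codons.
#'
#' @param parent List with `genome_vec` (character base vector) and `genes`
#'   (gene-model `data.frame`), e.g. from [simulate_ancestor()].
#' @param d Expected substitutions per site along the branch (>= 0).
#' @param seed Optional integer seed for this branch.
#' @return List like `parent` with mutated `genome_vec` and the realized
#'   substitution count in `n_sub`.
#' @export
evolve <- function(parent, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- jc_mutate(parent$genome_vec, parent$genes, d)
  list(genome_vec = res$vec, genes = parent$genes, n_sub = res$n_sub)
}

## ---- donor compositional models ----

# Order-k Markov donor model with stationary GC fixed exactly at donor_gc per
# context. The G-vs-C and A-vs-T splits of every context row are jittered
# (Beta(c, c)) to give each donor a distinct, seeded oligonucleotide
# signature without moving its GC.
donor_model <- function(donor_gc, order, jitter_conc) {
  g <- gc_nonstop_adjust(donor_gc)   # stop purging pulls realized GC back up
  n_ctx <- 4L^order
  gsplit <- rbeta(n_ctx, jitter_conc, jitter_conc)
  asplit <- rbeta(n_ctx, jitter_conc, jitter_conc)
  rows <- cbind(
    A = (1 - g) * asplit,
    C = g * (1 - gsplit),
    G = g * gsplit,
    T = (1 - g) * (1 - asplit)
  )
  list(gc = donor_gc, order = order, rows = rows)
}

ctx_index <- function(v) {
  # v: character vector of length `order`; lexicographic index, 1-based
  sum((match(v, BASES) - 1L) * 4L^(rev(seq_along(v)) - 1L)) + 1L
}

# Generate n bases from the donor model (order-0 rows all identical in GC;
# order >= 1 uses the preceding k emitted bases as context).
donor_generate <- function(model, n) {
  if (model$order == 0L) {
    p <- colMeans(model$rows)
    return(sample(BASES, n, replace = TRUE, prob = p))
  }
  k <- model$order
  out <- character(n)
  # burn-in context drawn from the marginal
  ctx <- sample(BASES, k, replace = TRUE, prob = colMeans(model$rows))
  for (i in seq_len(n)) {
    row <- model$rows[ctx_index(ctx), ]
    b <- sample(BASES, 1L, prob = row)
    out[i] <- b
    ctx <- c(ctx[-1L], b)
  }
  out
}

#' Replace a gene's CDS with a xenolog drawn from a donor model
#'
#' The gene body between the preserved `ATG` start and terminal `TAA` stop is
#' regenerated from an order-`markov_order` Markov model whose stationary GC
#' equals `donor_gc`; in-frame stop codons are resampled from the donor
#' model. Reading frame, coordinates and strand are untouched.
#'
#' @param genome List with `genome_vec` and `genes`.
#' @param gene_id Gene to replace.
#' @param donor_gc Donor GC fraction (0-1).
#' @param markov_order Donor Markov order (0-3).
#' @param seed Optional seed.
#' @param model Optional pre-built donor model (shared across a cluster).
#' @param jitter_conc Beta concentration for row jitter.
#' @return The genome list with the gene replaced.
#' @export
plant_xenolog <- function(genome, gene_id, donor_gc, markov_order = 2L,
                          seed = NULL, model = NULL, jitter_conc = 8) {
  if (!is.null(seed)) set.seed(seed)
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", gene_id)
  if (is.null(model)) model <- donor_model(donor_gc, markov_order, jitter_conc)
  g <- genome$genes[i, ]
  v <- genome$genome_vec[g$start:g$end]
  if (g$strand == "-") v <- revcomp_vec(v)
  len <- length(v)
  body <- donor_generate(model, len - 6L)
  v <- c("A", "T", "G", body, "T", "A", "A")
  repeat {
    cod <- codons_of(v)
    bad <- which(cod %in% STOP_CODONS)
    bad <- bad[bad < len / 3L]
    if (!length(bad)) break
    for (j in bad) v[(3L * j - 2L):(3L * j)] <- donor_generate(model, 3L)
  }
  if (g$strand == "-") v <- revcomp_vec(v)
  genome$genome_vec[g$start:g$end] <- v
  genome
}

# split a base vector into n contigs at sorted uniform breakpoints, keeping
# every gene inside a single contig (breakpoints are drawn in intergenic
# space). Returns ContigSet plus remapped gene table.
fragment_genome <- function(genome_vec, genes, genome_id, n_contigs) {
  L <- length(genome_vec)
  if (n_contigs <= 1L) {
    return(list(contigs = contig_set(genome_id,
                                     setNames(paste(genome_vec, collapse = ""), "c01")),
                genes = transform(genes, contig_id = "c01"),
                offsets = data.frame(contig_id = "c01", offset = 0L, length = L)))
  }
  occupied <- logical(L)
  for (i in seq_len(nrow(genes))) occupied[genes$start[i]:genes$end[i]] <- TRUE
  free <- which(!occupied)
  free <- free[free > 1L]
  bp <- sort(sample(free, n_contigs - 1L))
  bounds <- c(1L, bp, L + 1L)
  ids <- sprintf("c%02d", seq_len(n_contigs))
  seqs <- character(n_contigs)
  offs <- integer(n_contigs)
  for (k in seq_len(n_contigs)) {
    s <- bounds[k]; e <- bounds[k + 1L] - 1L
    seqs[k] <- paste(genome_vec[s:e], collapse = "")
    offs[k] <- s - 1L
  }
  gidx <- findInterval(genes$start, bounds)
  genes$contig_id <- ids[gidx]
  genes$start <- genes$start - offs[gidx]
  genes$end <- genes$end - offs[gidx]
  list(contigs = contig_set(genome_id, setNames(seqs, ids)), genes = genes,
       offsets = data.frame(contig_id = ids, offset = offs,
                            length = nchar(seqs)))
}

#' Simulate a genome trio with planted xenologs
#'
#' Evolves one simulated ancestor along the fixed topology `((A,B),C)`
#' (optionally with an outgroup `O` splitting off at the root), then applies
#' the xenolog plan to the extant recipients. Proteomes are derived by
#' translation of every CDS.
#'
#' @param config A [trio_config()].
#' @return A `TrioSim` list with elements `genomes` (named list per genome:
#'   `contigs`, `genes`, `proteins`, `genome_vec`, `cds`), `truth` (a
#'   `data.frame` of planted xenologs: `genome`, `gene_id`, `event`,
#'   `cluster`, `donor_gc`, `markov_order`), `branch_subs` (realized
#'   substitution counts per branch), and `config`.
#' @export
simulate_trio <- function(config) {
  stopifnot(inherits(config, "TrioConfig"))
  anc <- simulate_ancestor(config)
  root <- list(genome_vec = anc$genome_vec, genes = anc$genes)
  # derive independent branch seeds from the root seed (kept below 2^31)
  set.seed(config$seed)
  bseed <- sample.int(2^31 - 1L, 8L)
  ab <- evolve(root, config$d_internal, seed = bseed[1L])
  A <- evolve(ab, config$d_sister, seed = bseed[2L])
  B <- evolve(ab, config$d_sister, seed = bseed[3L])
  C <- evolve(root, config$d_c, seed = bseed[4L])
  genomes <- list(A = A, B = B, C = C)
  branch_subs <- c(internal = ab$n_sub, A = A$n_sub, B = B$n_sub, C = C$n_sub)
  if (!is.null(config$d_outgroup)) {
    O <- evolve(root, config$d_outgroup, seed = bseed[5L])
    genomes$O <- O
    branch_subs <- c(branch_subs, O = O$n_sub)
  }
  # plant xenologs post-speciation
  truth <- data.frame(genome = character(), gene_id = character(),
                      event = integer(), cluster = logical(),
                      donor_gc = numeric(), markov_order = integer(),
                      stringsAsFactors = FALSE)
  plan <- config$xenolog_plan
  if (!is.null(plan) && nrow(plan)) {
    set.seed(bseed[6L])
    for (e in seq_len(nrow(plan))) {
      rec <- plan$recipient[e]
      if (!rec %in% names(genomes)) stop("unknown recipient genome: ", rec)
      gn <- genomes[[rec]]
      avail <- setdiff(gn$genes$gene_id, truth$gene_id[truth$genome == rec])
      k <- plan$n_genes[e]
      if (plan$cluster[e]) {
        ord <- gn$genes[order(gn$genes$start), ]
        ord <- ord[ord$gene_id %in% avail, ]
        if (nrow(ord) < k) stop("not enough genes for cluster transfer")
        s0 <- sample.int(nrow(ord) - k + 1L, 1L)
        ids <- ord$gene_id[s0:(s0 + k - 1L)]
        model <- donor_model(plan$donor_gc[e], plan$markov_order[e],
                             config$donor_jitter)
        for (id in ids)
          gn <- plant_xenolog(gn, id, plan$donor_gc[e], plan$markov_order[e],
                              model = model)
      } else {
        ids <- sample(avail, k)
        for (id in ids)
          gn <- plant_xenolog(gn, id, plan$donor_gc[e], plan$markov_order[e],
                              jitter_conc = config$donor_jitter)
      }
      genomes[[rec]] <- gn
      truth <- rbind(truth, data.frame(
        genome = rec, gene_id = ids, event = e, cluster = plan$cluster[e],
        donor_gc = plan$donor_gc[e], markov_order = plan$markov_order[e],
        stringsAsFactors = FALSE))
    }
  }
  # package each genome: optional fragmentation, ContigSet, CDS, proteome
  set.seed(bseed[7L])
  out <- list()
  for (nm in names(genomes)) {
    g <- genomes[[nm]]
    nc <- if (length(config$n_contigs) > 1L) {
      if (nm %in% names(config$n_contigs)) config$n_contigs[[nm]] else 1L
    } else config$n_contigs
    frag <- fragment_genome(g$genome_vec, g$genes, nm, nc)
    cds <- extract_all_cds(frag$contigs, frag$genes)
    out[[nm]] <- list(contigs = frag$contigs, genes = frag$genes,
                      proteins = protein_set(nm, translate_many(cds)),
                      genome_vec = g$genome_vec, cds = cds,
                      contig_offsets = frag$offsets)
  }
  structure(list(genomes = out, truth = truth, branch_subs = branch_subs,
                 config = config),
            class = "TrioSim")
}

#' Gap-free alignment of one gene across the simulated genomes
#'
#' Because the simulator introduces no indels, orthologous CDSs share
#' coordinates; the alignment is simply the stack of CDS sequences.
#'
#' @param trio A `TrioSim`.
#' @param gene_id Gene id shared by all genomes.
#' @param genomes Which genomes to include (default all).
#' @return Named character vector of equal-length CDS sequences.
#' @export
trio_gene_alignment <- function(trio, gene_id, genomes = names(trio$genomes)) {
  out <- vapply(genomes, function(nm) {
    g <- trio$genomes[[nm]]
    i <- match(gene_id, g$genes$gene_id)
    if (is.na(i)) stop("unknown gene_id: ", gene_id)
    g$cds[[i]]
  }, character(1L))
  setNames(out, genomes)
}

#' Write a simulated trio to disk
#'
#' Emits, per genome, `<id>.fna` (genome FASTA), `<id>.gff3` (CDS models) and
#' `<id>.faa` (proteome FASTA), plus `truth.tsv` (planted xenologs) and
#' `branch_subs.tsv`.
#'
#' @param trio A `TrioSim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trio <- function(trio, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(trio$genomes)) {
    g <- trio$genomes[[nm]]
    write_fasta(g$contigs, file.path(dir, paste0(nm, ".fna")))
    write_gff_genes(g$genes, file.path(dir, paste0(nm, ".gff3")))
    write_fasta(g$proteins, file.path(dir, paste0(nm, ".faa")))
  }
  write.table(trio$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bs <- data.frame(branch = names(trio$branch_subs),
                   n_substitutions = as.integer(trio$branch_subs))
  write.table(bs, file.path(dir, "branch_subs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Species tree of the simulated trio
#'
#' @param config A `TrioConfig`.
#' @return An [ape::phylo] tree `((A,B),C)` (plus `O` when configured) with
#'   the configured branch lengths.
#' @export
trio_species_tree <- function(config) {
  if (is.null(config$d_outgroup)) {
    txt <- sprintf("((A:%g,B:%g):%g,C:%g);",
                   config$d_sister, config$d_sister, config$d_internal,
                   config$d_c)
  } else {
    txt <- sprintf("(((A:%g,B:%g):%g,C:%g):0,O:%g);",
                   config$d_sister, config$d_sister, config$d_internal,
                   config$d_c, config$d_outgroup)
  }
  ape::read.tree(text = txt)
}
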