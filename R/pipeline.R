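# End-to-end orchestration: simulate (or load) genomes, run relatedness,
# conservation, composition, gene trees for flagged genes, synteny, and the
# merged per-gene evidence tables. All randomness flows from the single run
# seed; every output header records it.

write_stage_table <- function(df, path, seed, params = NULL) {
  partial <- paste0(path, ".partial")
  con <- file(partial, "w")
  header <- sprintf("# hgtrio %s | seed %s%s",
                    as.character(utils::packageVersion("hgtrio")), seed,
                    if (is.null(params)) "" else paste0(" | ", params))
  writeLines(header, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  file.rename(partial, path)
  invisible(path)
}

#' Read a pipeline TSV table (skipping the run header)
#'
#' @param path Path to a table written by [run_pipeline()].
#' @return `data.frame`.
#' @export
read_stage_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

load_genome_inputs <- function(inputs) {
  out <- list()
  for (nm in names(inputs)) {
    spec <- inputs[[nm]]
    if (!file.exists(spec$fasta)) stop("missing input path: ", spec$fasta)
    if (!file.exists(spec$gff)) stop("missing input path: ", spec$gff)
    contigs <- read_fasta(spec$fasta, "nt", genome_id = nm)
    genes <- read_gff_genes(spec$gff)
    cds <- extract_all_cds(contigs, genes)
    out[[nm]] <- list(contigs = contigs, genes = genes, cds = cds,
                      proteins = protein_set(nm, translate_many(cds)))
  }
  out
}

#' Run the full comparative/HGT pipeline
#'
#' In simulate mode (`config` is a [trio_config()]) the trio is generated
#' and written alongside its ground truth; in file mode `config` is a named
#' list of `list(fasta =, gff =)` genome inputs. Stages: relatedness (ANI +
#' d2/DDH for every genome pair), conservation (best-hit H-values per pair),
#' composition (per-CDS tetra/codon/GC screens), gene trees for
#' parametrically flagged genes (simulate mode with an outgroup only),
#' synteny anchors + collinearity per pair, and a merged per-gene evidence
#' table per genome. A manifest records versions, seed, parameters and input
#' checksums.
#'
#' @param config A `TrioConfig`, or a named list of genome input paths.
#' @param out_dir Output directory.
#' @param seed Run seed (defaults to the TrioConfig seed, or 1).
#' @param h_threshold,evalue_max,sd_mult,min_len Analysis thresholds.
#' @param ani_parameters See [ani_params()].
#' @param ddh_calibration `NULL` or `c(a, b)` for the DDH mapping.
#' @param run_synteny,run_trees Stage switches.
#' @return Invisibly, a list with the in-memory stage results
#'   (`genomes`, `relatedness`, `conservation`, `composition`, `evidence`,
#'   `synteny`, `truth` when simulated).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         h_threshold = 0.64, evalue_max = 1e-10,
                         sd_mult = 2, min_len = 300L,
                         ani_parameters = ani_params(),
                         ddh_calibration = ddh_default_calibration(),
                         run_synteny = TRUE, run_trees = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulate_mode <- inherits(config, "TrioConfig")
  if (is.null(seed)) seed <- if (simulate_mode) config$seed else 1L
  set.seed(seed)

  manifest <- c(
    sprintf("hgtrio_version\t%s", as.character(utils::packageVersion("hgtrio"))),
    sprintf("seed\t%d", as.integer(seed)),
    sprintf("mode\t%s", if (simulate_mode) "simulate" else "files"),
    sprintf("h_threshold\t%g", h_threshold),
    sprintf("evalue_max\t%g", evalue_max),
    sprintf("sd_mult\t%g", sd_mult),
    sprintf("min_len\t%d", as.integer(min_len)),
    sprintf("ani_frag_len\t%d", ani_parameters$frag_len),
    sprintf("ani_seed_k\t%d", ani_parameters$k)
  )
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))

  truth <- NULL
  trio <- NULL
  if (simulate_mode) {
    trio <- run_stage("simulate", simulate_trio(config))
    input_dir <- file.path(out_dir, "inputs")
    write_trio(trio, input_dir)
    genomes <- trio$genomes
    truth <- trio$truth
    sums <- tools::md5sum(list.files(input_dir, full.names = TRUE))
    manifest <- c(manifest, sprintf("md5\t%s\t%s", basename(names(sums)), sums))
    writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  } else {
    paths <- unlist(lapply(config, function(s) c(s$fasta, s$gff)))
    genomes <- run_stage("load", load_genome_inputs(config))
    sums <- tools::md5sum(paths)
    manifest <- c(manifest, sprintf("md5\t%s\t%s", basename(names(sums)), sums))
    writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  }
  nms <- names(genomes)
  pairs <- if (length(nms) >= 2L) utils::combn(nms, 2L, simplify = FALSE) else list()

  # relatedness: ANI + d2 (+ DDH) for every pair
  rel <- run_stage("relatedness", {
    rows <- lapply(pairs, function(p) {
      gd <- ggdc_distance(genomes[[p[1L]]]$contigs, genomes[[p[2L]]]$contigs,
                          params = ani_parameters, calibration = ddh_calibration)
      data.frame(genome_a = p[1L], genome_b = p[2L],
                 ani = gd$ani, d2 = gd$d2,
                 ddh = if (is.character(gd$ddh_estimate)) NA_real_ else gd$ddh_estimate,
                 n_fragments_kept = gd$n_fragments_kept,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  if (length(pairs))
    write_stage_table(rel, file.path(out_dir, "relatedness.tsv"), seed)

  # conservation: best-hit H-values for every ordered pair
  cons <- run_stage("conservation", {
    out <- list()
    for (p in pairs) {
      for (dir in list(p, rev(p))) {
        hv <- proteome_hvalues(genomes[[dir[1L]]]$proteins,
                               genomes[[dir[2L]]]$proteins)
        key <- paste0(dir[1L], "_vs_", dir[2L])
        out[[key]] <- hv
        write_stage_table(hv, file.path(out_dir, paste0("hvalues_", key, ".tsv")),
                          seed)
      }
    }
    out
  })

  # composition screens per genome
  comp <- run_stage("composition", {
    out <- list()
    for (nm in nms) {
      out[[nm]] <- composition_report(genomes[[nm]]$cds, min_len = min_len,
                                      sd_mult = sd_mult)
      write_stage_table(out[[nm]],
                        file.path(out_dir, paste0("composition_", nm, ".tsv")),
                        seed)
    }
    out
  })

  # gene trees for parametrically flagged genes (needs >= 4 genomes, i.e.
  # a simulated outgroup); incongruence = RF > 0 against the species tree
  tree_flags <- NULL
  if (run_trees && simulate_mode && length(nms) >= 4L) {
    tree_flags <- run_stage("trees", {
      sp <- trio_species_tree(config)
      out <- list()
      for (nm in setdiff(nms, "O")) {
        flagged <- comp[[nm]]$gene_id[(comp[[nm]]$tetra_flag %in% TRUE) |
                                        (comp[[nm]]$codon_flag %in% TRUE)]
        fl <- setNames(rep(NA, nrow(comp[[nm]])), comp[[nm]]$gene_id)
        for (gid in flagged) {
          aln <- trio_gene_alignment(trio, gid)
          gt <- gene_tree(aln, "nt")
          rf <- rf_distance(gt, sp)
          fl[gid] <- if (is.na(rf$rf)) NA else rf$rf > 0L
        }
        out[[nm]] <- fl
      }
      out
    })
  }

  # merged evidence tables
  evid <- run_stage("evidence", {
    out <- list()
    for (nm in nms) {
      out[[nm]] <- hgt_evidence_table(comp[[nm]], tree_flags[[nm]])
      write_stage_table(out[[nm]],
                        file.path(out_dir, paste0("evidence_", nm, ".tsv")),
                        seed)
    }
    out
  })

  # synteny anchors + collinearity per pair
  synt <- NULL
  if (run_synteny && length(pairs)) {
    synt <- run_stage("synteny", {
      out <- list()
      rows <- list()
      for (p in pairs) {
        key <- paste0(p[1L], "_vs_", p[2L])
        anch <- find_anchors(genomes[[p[1L]]]$proteins, genomes[[p[1L]]]$genes,
                             genomes[[p[2L]]]$proteins, genomes[[p[2L]]]$genes)
        chain <- collinearity_chain(anch)
        out[[key]] <- anch
        write_stage_table(anch, file.path(out_dir, paste0("anchors_", key, ".tsv")),
                          seed)
        rows[[key]] <- data.frame(pair = key, n_anchors = chain$n_anchors,
                                  chain_length = chain$chain_length,
                                  collinear_fraction = chain$fraction,
                                  stringsAsFactors = FALSE)
      }
      write_stage_table(do.call(rbind, rows),
                        file.path(out_dir, "synteny_summary.tsv"), seed)
      out
    })
  }

  invisible(list(genomes = genomes, relatedness = rel, conservation = cons,
                 composition = comp, evidence = evid, synteny = synt,
                 truth = truth, trio = trio, out_dir = out_dir, seed = seed))
}
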