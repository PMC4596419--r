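# Ortholog-anchor synteny: reciprocal-best-hit anchors, LIS collinearity,
# contig ordering against a reference, gene-cluster extraction/comparison,
# and per-gene HGT evidence integration.

gene_midpoints <- function(genes) {
  data.frame(gene_id = genes$gene_id, contig_id = genes$contig_id,
             midpoint = (genes$start + genes$end) / 2,
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Reciprocal best-hit synteny anchors between two annotated genomes
#'
#' Anchors are reciprocal best hits by local alignment score whose H-value
#' exceeds `h_threshold` in both directions. Anchor coordinates are gene
#' midpoints; orientation is `"same"` when the two genes lie on the same
#' strand.
#'
#' @param query_proteins,ref_proteins `ProteinSet`s.
#' @param query_genes,ref_genes Gene-model `data.frame`s.
#' @param h_threshold Strict H-value threshold for both directions.
#' @param ... Passed to [proteome_hvalues()] (e.g. `exhaustive`).
#' @return `data.frame` of anchors: `query_gene`, `query_contig`,
#'   `query_mid`, `ref_gene`, `ref_contig`, `ref_mid`, `orientation`,
#'   `h_value`.
#' @export
find_anchors <- function(query_proteins, query_genes, ref_proteins, ref_genes,
                         h_threshold = 0.64, ...) {
  fwd <- proteome_hvalues(query_proteins, ref_proteins, ...)
  rev_ <- proteome_hvalues(ref_proteins, query_proteins, ...)
  back <- setNames(rev_$subject_id, rev_$query_id)
  keep <- fwd$subject_id != "." &
    !is.na(back[fwd$subject_id]) & back[fwd$subject_id] == fwd$query_id &
    fwd$h_value > h_threshold &
    rev_$h_value[match(fwd$subject_id, rev_$query_id)] > h_threshold
  keep[is.na(keep)] <- FALSE
  fwd <- fwd[keep, , drop = FALSE]
  qm <- gene_midpoints(query_genes)
  rm_ <- gene_midpoints(ref_genes)
  qi <- match(fwd$query_id, qm$gene_id)
  ri <- match(fwd$subject_id, rm_$gene_id)
  out <- data.frame(
    query_gene = fwd$query_id, query_contig = qm$contig_id[qi],
    query_mid = qm$midpoint[qi],
    ref_gene = fwd$subject_id, ref_contig = rm_$contig_id[ri],
    ref_mid = rm_$midpoint[ri],
    orientation = ifelse(qm$strand[qi] == rm_$strand[ri], "same", "opposite"),
    h_value = fwd$h_value,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Collinearity of an anchor set
#'
#' Anchors are sorted by reference position; the chain is the longer of the
#' longest strictly increasing and longest strictly decreasing subsequence
#' of query positions (the decreasing chain captures a fully inverted
#' genome). The collinear fraction is `chain / n_anchors`.
#'
#' @param anchors `data.frame` from [find_anchors()] (columns `ref_mid`,
#'   `query_mid` used).
#' @return List with `chain_length`, `fraction`, `n_anchors`.
#' @export
collinearity_chain <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0L) return(list(chain_length = 0L, fraction = NA_real_, n_anchors = 0L))
  q <- anchors$query_mid[order(anchors$ref_mid, anchors$query_mid)]
  fwd <- .lis_length_cpp(q)
  rev_ <- .lis_length_cpp(-q)
  chain <- max(fwd, rev_)
  list(chain_length = chain, fraction = chain / n, n_anchors = n)
}

#' Order and orient query contigs against a reference genome
#'
#' Contigs are sorted by the median reference position of their anchors;
#' orientation is the majority anchor orientation (ties break to `"same"`).
#' Contigs without anchors are appended last in input order and flagged.
#'
#' @param anchors `data.frame` from [find_anchors()].
#' @param query_contig_ids All query contig ids in input order.
#' @return `data.frame` with `contig_id`, `median_ref_pos`, `orientation`,
#'   `n_anchors`, `anchored`, in the recovered order.
#' @export
order_contigs <- function(anchors, query_contig_ids) {
  rows <- lapply(query_contig_ids, function(cid) {
    a <- anchors[anchors$query_contig == cid, , drop = FALSE]
    if (nrow(a) == 0L)
      return(data.frame(contig_id = cid, median_ref_pos = NA_real_,
                        orientation = "same", n_anchors = 0L,
                        anchored = FALSE, stringsAsFactors = FALSE))
    n_same <- sum(a$orientation == "same")
    data.frame(contig_id = cid, median_ref_pos = median(a$ref_mid),
               orientation = if (n_same * 2L >= nrow(a)) "same" else "opposite",
               n_anchors = nrow(a), anchored = TRUE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  anchored <- tab[tab$anchored, , drop = FALSE]
  anchored <- anchored[order(anchored$median_ref_pos), , drop = FALSE]
  out <- rbind(anchored, tab[!tab$anchored, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Extract a contiguous gene cluster between two gene ids
#'
#' Returns the genes between the two ids (inclusive) on their common contig,
#' in genomic order. The two ids may be given in either order.
#'
#' @param genes Gene-model `data.frame`.
#' @param from_gene_id,to_gene_id Bounding gene ids.
#' @return Gene-model `data.frame` subset ordered by `start`.
#' @export
extract_cluster <- function(genes, from_gene_id, to_gene_id) {
  i <- match(from_gene_id, genes$gene_id)
  j <- match(to_gene_id, genes$gene_id)
  if (is.na(i) || is.na(j)) stop("unknown gene id")
  if (genes$contig_id[i] != genes$contig_id[j])
    stop("cluster bounds lie on different contigs")
  lo <- min(genes$start[i], genes$start[j])
  hi <- max(genes$end[i], genes$end[j])
  sel <- genes$contig_id == genes$contig_id[i] &
    genes$start >= lo & genes$end <= hi
  out <- genes[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare a gene cluster across genomes with per-gene HGT evidence
#'
#' Pairwise homology between the first (reference) cluster and every other
#' cluster is established by best H-value within the clusters (strictly
#' above `h_threshold`, injective: hits assigned greedily by descending H).
#' Each gene carries its tri-state evidence vector (`"yes"`, `"no"`,
#' `"not evaluated"`) from the composition reports and optional tree flags.
#'
#' @param clusters Named list (one element per genome) of gene-model
#'   `data.frame`s, e.g. from [extract_cluster()].
#' @param proteomes Named list of `ProteinSet`s (same names).
#' @param composition Named list of [composition_report()] tables, or `NULL`.
#' @param tree_incongruent Named list of logical vectors indexed by gene id,
#'   or `NULL`.
#' @param h_threshold Strict H-value threshold for homology mapping.
#' @return `data.frame` with one row per gene per genome: `genome`,
#'   `gene_id`, `position`, `strand`, `ref_match` (matched gene of the
#'   reference cluster or `NA`), `tetra`, `codon`, `gc`, `tree` (tri-state).
#' @export
compare_clusters <- function(clusters, proteomes, composition = NULL,
                             tree_incongruent = NULL, h_threshold = 0.64) {
  stopifnot(length(clusters) >= 1L, !is.null(names(clusters)))
  ref_name <- names(clusters)[1L]
  tri <- function(flag) {
    ifelse(is.na(flag), "not evaluated", ifelse(flag, "yes", "no"))
  }
  evid <- function(genome, ids) {
    co <- composition[[genome]]
    tr <- tree_incongruent[[genome]]
    data.frame(
      tetra = if (is.null(co)) "not evaluated" else tri(co$tetra_flag[match(ids, co$gene_id)]),
      codon = if (is.null(co)) "not evaluated" else tri(co$codon_flag[match(ids, co$gene_id)]),
      gc    = if (is.null(co)) "not evaluated" else tri(co$gc_flag[match(ids, co$gene_id)]),
      tree  = if (is.null(tr)) "not evaluated" else tri(unname(tr[ids])),
      stringsAsFactors = FALSE
    )
  }
  sub_proteins <- function(genome, ids) {
    p <- proteomes[[genome]]$proteins
    protein_set(genome, setNames(as.character(p[ids]), ids))
  }
  ref_genes <- clusters[[ref_name]]
  out <- list()
  for (nm in names(clusters)) {
    cl <- clusters[[nm]]
    match_col <- rep(NA_character_, nrow(cl))
    if (nm == ref_name) {
      match_col <- cl$gene_id
    } else if (nrow(cl) && nrow(ref_genes)) {
      hv <- proteome_hvalues(sub_proteins(nm, cl$gene_id),
                             sub_proteins(ref_name, ref_genes$gene_id),
                             exhaustive = TRUE)
      hv <- hv[hv$subject_id != "." & hv$h_value > h_threshold, , drop = FALSE]
      hv <- hv[order(-hv$h_value, hv$query_id), , drop = FALSE]
      used <- character(0)
      for (r in seq_len(nrow(hv))) {
        if (hv$subject_id[r] %in% used) next
        if (!is.na(match_col[match(hv$query_id[r], cl$gene_id)])) next
        match_col[match(hv$query_id[r], cl$gene_id)] <- hv$subject_id[r]
        used <- c(used, hv$subject_id[r])
      }
    }
    out[[nm]] <- cbind(
      data.frame(genome = nm, gene_id = cl$gene_id,
                 position = seq_len(nrow(cl)), strand = cl$strand,
                 ref_match = match_col, stringsAsFactors = FALSE),
      evid(nm, cl$gene_id)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Text diagram of a cluster comparison
#'
#' One line per genome; genes drawn as `>name` / `<name` arrows, an asterisk
#' marking genes with any `"yes"` evidence flag, in the style of published
#' cluster figures.
#'
#' @param comparison Output of [compare_clusters()].
#' @return Character vector of lines (also printed).
#' @export
cluster_diagram <- function(comparison) {
  lines <- vapply(split(comparison, comparison$genome), function(d) {
    d <- d[order(d$position), ]
    star <- ifelse(d$tetra == "yes" | d$codon == "yes" |
                     d$gc == "yes" | d$tree == "yes", "*", "")
    paste0(unique(d$genome), ": ",
           paste0(ifelse(d$strand == "+", ">", "<"), d$gene_id, star,
                  collapse = " "))
  }, character(1L))
  cat(lines, sep = "\n")
  invisible(unname(lines))
}

#' Integrate per-gene HGT evidence into summary classes
#'
#' Composite class per gene: `"putative HGT (parametric)"` when the tetra or
#' codon screen flags it; `"supported"` when additionally the GC filter or
#' gene-tree incongruence agrees; `"none"` otherwise; `"not evaluated"` when
#' neither parametric screen could run (short genes).
#'
#' @param composition A [composition_report()] table.
#' @param tree_incongruent Optional logical vector indexed by gene id
#'   (`TRUE` = gene tree incongruent with the species tree).
#' @return The composition table with columns `tree_incongruent` and
#'   `class`, plus a `"summary"` attribute of class counts and percentages.
#' @export
hgt_evidence_table <- function(composition, tree_incongruent = NULL) {
  tr <- if (is.null(tree_incongruent)) rep(NA, nrow(composition))
        else unname(tree_incongruent[composition$gene_id])
  parametric <- (composition$tetra_flag %in% TRUE) |
    (composition$codon_flag %in% TRUE)
  not_eval <- is.na(composition$tetra_flag) & is.na(composition$codon_flag)
  supported <- parametric &
    ((composition$gc_flag %in% TRUE) | (tr %in% TRUE))
  cls <- ifelse(not_eval, "not evaluated",
                ifelse(supported, "supported",
                       ifelse(parametric, "putative HGT (parametric)", "none")))
  out <- composition
  out$tree_incongruent <- tr
  out$class <- cls
  counts <- table(factor(cls, levels = c("none", "putative HGT (parametric)",
                                         "supported", "not evaluated")))
  attr(out, "summary") <- data.frame(
    class = names(counts),
    count = as.integer(counts),
    percent = 100 * as.integer(counts) / nrow(out)
  )
  out
}
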