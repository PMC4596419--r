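# Distance-based gene/species trees and incongruence testing. Maximum
# likelihood inference is deliberately out of scope; neighbor-joining over
# corrected distances is the desk-scale substitute, so published tree
# details obtained with ML may differ.

as_char_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  nms <- names(aln)
  seqs <- setNames(as.character(aln), nms)
  if (is.null(names(seqs))) stop("alignment rows must be named by taxon")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Remove every alignment column containing a gap
#'
#' @param aln Named character vector of equal-length gapped sequences (gap
#'   symbol `-`), or a character matrix (rows = taxa).
#' @return The alignment as a named character vector without gapped columns.
#' @export
strip_gap_columns <- function(aln) {
  m <- as_char_matrix(aln)
  keep <- colSums(m == "-") == 0L
  if (!any(keep)) stop("all columns contain gaps; empty alignment")
  m <- m[, keep, drop = FALSE]
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance with pairwise deletion of residual gap positions, optionally
#' corrected: Jukes-Cantor `-3/4 log(1 - 4p/3)` for nucleotides or Poisson
#' `-log(1 - p)` for amino acids. Saturated pairs (p at or beyond the
#' correction domain) are set to `cap` with a warning.
#'
#' @param aln Named character vector or matrix (see [strip_gap_columns()]).
#' @param correction `"none"`, `"jc"`, or `"poisson"`.
#' @param cap Distance assigned to saturated pairs.
#' @return Symmetric numeric matrix with taxa as dimnames.
#' @export
pdistance_matrix <- function(aln, correction = c("none", "jc", "poisson"),
                             cap = 3) {
  correction <- match.arg(correction)
  m <- as_char_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  saturated <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      nc <- sum(ok)
      if (nc == 0L) stop("no shared ungapped column between ",
                         rownames(m)[i], " and ", rownames(m)[j])
      p <- sum(m[i, ok] != m[j, ok]) / nc
      dd <- switch(correction,
        none = p,
        jc = if (p >= 0.75) { saturated <- TRUE; cap }
             else -0.75 * log(1 - 4 * p / 3),
        poisson = if (p >= 1) { saturated <- TRUE; cap } else -log(1 - p)
      )
      d[i, j] <- d[j, i] <- dd
    }
  }
  if (saturated) warning("saturated pair(s) set to cap = ", cap)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch at the same
#' node, preserving pairwise path lengths where possible.
#'
#' @param dm Symmetric distance matrix with taxa dimnames.
#' @return Unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sibs)) {
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (via [phangorn::midpoint()]).
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Rooted tree.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Robinson-Foulds distance between two trees
#'
#' Both trees are restricted to their shared taxa and unrooted; the RF
#' distance is the size of the symmetric difference of their non-trivial
#' bipartition sets, normalized by `2 (n - 3)`.
#'
#' @param t1,t2 [ape::phylo] trees.
#' @return List with `rf` (integer), `normalized` (fraction), `n_shared`
#'   (shared taxa). Fewer than 4 shared taxa yields `rf = NA` ("not
#'   evaluated").
#' @export
rf_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  n <- length(shared)
  if (n < 4L)
    return(list(rf = NA_integer_, normalized = NA_real_, n_shared = n))
  t1 <- ape::unroot(ape::keep.tip(t1, shared))
  t2 <- ape::unroot(ape::keep.tip(t2, shared))
  rf <- as.integer(phangorn::RF.dist(t1, t2, normalize = FALSE))
  list(rf = rf, normalized = rf / (2 * (n - 3)), n_shared = n)
}

#' Do the focal taxa form a clade (unrooted sense)?
#'
#' `TRUE` iff some bipartition of the unrooted tree separates exactly the
#' focal taxa from the rest. Singletons (and the full taxon set) are clades
#' by convention.
#'
#' @param tree An [ape::phylo] tree.
#' @param focal_taxa Character vector of tip labels.
#' @return Logical.
#' @export
clade_test <- function(tree, focal_taxa) {
  tips <- tree$tip.label
  if (!all(focal_taxa %in% tips)) stop("focal taxa not all present in tree")
  if (length(focal_taxa) <= 1L || length(focal_taxa) >= length(tips) - 1L) {
    # singleton, complement-singleton and full set are trivially bipartitions
    if (length(focal_taxa) == length(tips)) return(TRUE)
    if (length(focal_taxa) <= 1L) {
      message("singleton clade test: TRUE by convention")
      return(TRUE)
    }
    if (length(focal_taxa) == length(tips) - 1L) return(TRUE)
  }
  out <- setdiff(tips, focal_taxa)[1L]
  tr <- ape::root(ape::unroot(tree), outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(tr, focal_taxa)
}

#' NJ gene tree from a gap-free alignment
#'
#' Convenience wrapper: strip gapped columns, compute corrected distances,
#' run neighbor joining.
#'
#' @param aln Named character vector of aligned sequences.
#' @param alphabet `"nt"` (Jukes-Cantor correction) or `"aa"` (Poisson).
#' @return Unrooted [ape::phylo] tree.
#' @export
gene_tree <- function(aln, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  aln <- strip_gap_columns(aln)
  dm <- pdistance_matrix(aln, correction = if (alphabet == "nt") "jc" else "poisson")
  nj_tree(dm)
}
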