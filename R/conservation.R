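# Proteome conservation via the H-value homology score: Smith-Waterman local
# alignment (BLOSUM62, affine gaps open 11 / extend 1), identity over aligned
# columns (gap columns included in the denominator), and
# H = identity * match_length / query_length, capped at 1.

# Karlin-Altschul constants for gapped BLOSUM62 (comparative device, not a
# claim of BLAST equivalence)
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Local protein alignment statistics
#'
#' Smith-Waterman alignment with BLOSUM62 and affine gap penalties (open 11,
#' extend 1). Identity counts identical columns over all aligned columns,
#' including gap columns; `match_length` is the number of aligned columns.
#' The e-value is `K * m * n * exp(-lambda * S)` with the classical gapped
#' BLOSUM62 constants.
#'
#' @param query,subject Amino-acid strings.
#' @return List with `hit` (logical: a positive-scoring local alignment
#'   exists), `score`, `identity`, `match_length`, `evalue`.
#' @export
align_local <- function(query, subject) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  s <- Biostrings::score(aln)
  len <- Biostrings::nchar(aln)
  if (s <= 0 || len == 0L) {
    return(list(hit = FALSE, score = s, identity = NA_real_,
                match_length = 0L, evalue = NA_real_))
  }
  list(
    hit = TRUE,
    score = s,
    identity = Biostrings::nmatch(aln) / len,
    match_length = len,
    evalue = KA_K * nchar(query) * nchar(subject) * exp(-KA_LAMBDA * s)
  )
}

#' H-value homology score
#'
#' `H = identity * match_length / query_length`, capped at 1. Identity is a
#' fraction in `[0, 1]`; a protein conserved over its full length at full
#' identity scores 1.
#'
#' @param identity Identity fraction of the local alignment.
#' @param match_length Aligned columns of the local alignment.
#' @param query_length Length of the query protein in residues.
#' @return H-value in `[0, 1]`.
#' @export
h_value <- function(identity, match_length, query_length) {
  if (any(query_length < 1)) stop("query_length must be >= 1")
  if (any(identity < 0 | identity > 1)) stop("identity must be in [0, 1]")
  pmin(1, identity * match_length / query_length)
}

# shared-5-mer candidate prefilter: for each query id, subject ids ranked by
# number of shared distinct 5-mers
kmer_candidates <- function(qseqs, sseqs, k = 5L, top = 20L) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0L))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  skm <- lapply(sseqs, kmers_of)
  idx <- split(rep(names(sseqs), lengths(skm)), unlist(skm, use.names = FALSE))
  lapply(qseqs, function(q) {
    km <- kmers_of(q)
    hits <- unlist(idx[intersect(km, names(idx))], use.names = FALSE)
    if (!length(hits)) return(character(0L))
    tab <- sort(table(hits), decreasing = TRUE)
    names(tab)[seq_len(min(top, length(tab)))]
  })
}

#' Best-hit H-values of a query proteome against a subject proteome
#'
#' For each query protein, the subject protein with the maximal local
#' alignment score is reported (score ties break to the lexicographically
#' smallest subject id). Queries with no positive-scoring alignment are
#' reported with `h_value` 0 and subject `"."`. Candidate subjects are
#' preselected by shared-5-mer counting (`top_candidates` per query) unless
#' `exhaustive = TRUE`.
#'
#' @param query,subject `ProteinSet`s.
#' @param exhaustive Align every query against every subject.
#' @param top_candidates Candidates retained by the 5-mer prefilter.
#' @return `data.frame` of `HValueHit` rows: `query_id`, `subject_id`,
#'   `identity`, `match_length`, `query_length`, `h_value`, `score`,
#'   `evalue`.
#' @export
proteome_hvalues <- function(query, subject, exhaustive = FALSE,
                             top_candidates = 20L) {
  stopifnot(inherits(query, "ProteinSet"), inherits(subject, "ProteinSet"))
  qseqs <- setNames(as.character(query$proteins), names(query$proteins))
  sseqs <- setNames(as.character(subject$proteins), names(subject$proteins))
  if (!length(qseqs) || !length(sseqs)) stop("empty proteome")
  cands <- if (exhaustive) {
    setNames(rep(list(names(sseqs)), length(qseqs)), names(qseqs))
  } else {
    kmer_candidates(qseqs, sseqs, top = top_candidates)
  }
  sset <- Biostrings::AAStringSet(sseqs)
  rows <- vector("list", length(qseqs))
  for (i in seq_along(qseqs)) {
    qid <- names(qseqs)[i]
    qlen <- nchar(qseqs[[i]])
    cand <- sort(cands[[qid]])
    if (!length(cand)) {
      rows[[i]] <- data.frame(query_id = qid, subject_id = ".",
                              identity = NA_real_, match_length = 0L,
                              query_length = qlen, h_value = 0,
                              score = NA_real_, evalue = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = sset[cand], subject = Biostrings::AAString(qseqs[[i]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1
    )
    sc <- Biostrings::score(aln)
    if (max(sc) <= 0) {
      rows[[i]] <- data.frame(query_id = qid, subject_id = ".",
                              identity = NA_real_, match_length = 0L,
                              query_length = qlen, h_value = 0,
                              score = NA_real_, evalue = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    best <- which(sc == max(sc))[1L]  # cand sorted: lexicographic tie-break
    len <- Biostrings::nchar(aln)[best]
    ident <- Biostrings::nmatch(aln)[best] / len
    rows[[i]] <- data.frame(
      query_id = qid, subject_id = cand[best],
      identity = ident, match_length = len, query_length = qlen,
      h_value = h_value(ident, len, qlen),
      score = sc[best],
      evalue = KA_K * qlen * nchar(sseqs[[cand[best]]]) * exp(-KA_LAMBDA * sc[best]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conserved proteins by the H-value threshold
#'
#' A protein is conserved iff its H-value is strictly above the threshold
#' (an H of exactly 0.64 is excluded).
#'
#' @param hits `data.frame` from [proteome_hvalues()].
#' @param threshold H-value threshold (strict).
#' @return Character vector of conserved query ids.
#' @export
conserved_set <- function(hits, threshold = 0.64) {
  hits$query_id[hits$h_value > threshold]
}

#' Histogram bins of H-values
#'
#' @param hits `data.frame` from [proteome_hvalues()].
#' @param width Bin width.
#' @return `data.frame` with `bin_low`, `bin_high`, `count`.
#' @export
hvalue_histogram <- function(hits, width = 0.05) {
  breaks <- seq(0, 1, by = width)
  ct <- table(cut(hits$h_value, breaks = breaks, include.lowest = TRUE,
                  right = FALSE))
  data.frame(bin_low = head(breaks, -1L), bin_high = breaks[-1L],
             count = as.integer(ct))
}

#' Annotate query proteins against a labelled reference set
#'
#' For each query protein the reference hit with the lowest e-value is
#' assigned, provided the e-value is strictly below `evalue_max` (default
#' 1e-10). E-value ties break to the smaller reference id (logged via a
#' message). `mode = "hvalue"` instead assigns the best-scoring reference
#' with H strictly above `h_threshold`.
#'
#' @param query A `ProteinSet`.
#' @param reference A `ProteinSet` of reference proteins.
#' @param families Named character vector mapping reference ids to family
#'   labels; required.
#' @param evalue_max Strict e-value cutoff for `mode = "evalue"`.
#' @param h_threshold Strict H-value cutoff for `mode = "hvalue"`.
#' @param mode Assignment rule.
#' @param exhaustive,top_candidates Passed to the alignment stage.
#' @return `data.frame` with `query_id`, `family` (`NA` when unassigned),
#'   `reference_id`, `evalue`, `h_value`.
#' @export
annotate_with_reference <- function(query, reference, families,
                                    evalue_max = 1e-10, h_threshold = 0.64,
                                    mode = c("evalue", "hvalue"),
                                    exhaustive = FALSE, top_candidates = 20L) {
  mode <- match.arg(mode)
  if (missing(families) || is.null(families))
    stop("reference family labels are required")
  if (!all(names(reference$proteins) %in% names(families)))
    stop("family label missing for some reference proteins")
  qseqs <- setNames(as.character(query$proteins), names(query$proteins))
  sseqs <- setNames(as.character(reference$proteins), names(reference$proteins))
  cands <- if (exhaustive) {
    setNames(rep(list(names(sseqs)), length(qseqs)), names(qseqs))
  } else {
    kmer_candidates(qseqs, sseqs, top = top_candidates)
  }
  sset <- Biostrings::AAStringSet(sseqs)
  rows <- vector("list", length(qseqs))
  for (i in seq_along(qseqs)) {
    qid <- names(qseqs)[i]
    qlen <- nchar(qseqs[[i]])
    cand <- sort(cands[[qid]])
    row <- data.frame(query_id = qid, family = NA_character_,
                      reference_id = NA_character_, evalue = NA_real_,
                      h_value = NA_real_, stringsAsFactors = FALSE)
    if (length(cand)) {
      aln <- Biostrings::pairwiseAlignment(
        pattern = sset[cand], subject = Biostrings::AAString(qseqs[[i]]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1
      )
      sc <- Biostrings::score(aln)
      ok <- which(sc > 0)
      if (length(ok)) {
        len <- Biostrings::nchar(aln)[ok]
        ident <- Biostrings::nmatch(aln)[ok] / len
        ev <- KA_K * qlen * nchar(sseqs[cand[ok]]) * exp(-KA_LAMBDA * sc[ok])
        hv <- h_value(ident, len, qlen)
        if (mode == "evalue") {
          sel <- which(ev == min(ev))
          if (length(sel) > 1L) message("e-value tie for ", qid,
                                        "; smaller reference id assigned")
          sel <- sel[order(cand[ok][sel])][1L]
          if (ev[sel] < evalue_max) {
            rid <- cand[ok][sel]
            row$family <- unname(families[[rid]])
            row$reference_id <- rid
            row$evalue <- ev[sel]
            row$h_value <- hv[sel]
          }
        } else {
          sel <- which(sc[ok] == max(sc[ok]))
          sel <- sel[order(cand[ok][sel])][1L]
          if (hv[sel] > h_threshold) {
            rid <- cand[ok][sel]
            row$family <- unname(families[[rid]])
            row$reference_id <- rid
            row$evalue <- ev[sel]
            row$h_value <- hv[sel]
          }
        }
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
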