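# Parametric per-CDS xenolog screening: tetranucleotide-usage deviation,
# relative synonymous codon usage (RSCU) deviation, and the GC +/- 2 SD
# filter. One coherent rule: a gene is flagged when its deviation score
# exceeds the across-gene mean by more than sd_mult standard deviations
# (one-sided for the distance scores, two-sided for GC).
#
# The raw Manhattan distance of a homogeneous gene scales as 1/sqrt(counted
# units), so over a realistic gene-length distribution it measures length,
# not composition (flags pile up on short genes and the null flag rate
# drifts above the nominal 2-SD tail). Both distance scores are therefore
# standardized by sqrt(counted units), which makes the null score
# approximately length-free and restores the ~2-3% one-sided tail.

#' Tetranucleotide frequency profile of a sequence
#'
#' Overlapping 4-mers counted on the given (coding) strand; windows
#' containing `N` are skipped; counts normalized to frequencies over the 256
#' lexicographically ordered tetranucleotides `AAAA..TTTT`.
#'
#' @param seq Nucleotide string.
#' @return Named numeric vector of 256 frequencies with attribute
#'   `n_windows` (number of counted 4-mers).
#' @export
tetra_profile <- function(seq) {
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = 4L)
  n <- sum(counts)
  if (n < 1) stop("no valid 4-mer window in sequence")
  structure(counts / n, n_windows = n)
}

# count matrix (genes x 256) for a set of CDS sequences
tetra_counts <- function(seqs) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                       width = 4L)
}

#' Tetranucleotide-usage outliers among a genome's CDSs
#'
#' The background profile pools the 4-mer counts of all evaluable CDSs
#' (length >= `min_len`); each gene's score is the Manhattan distance
#' between its own profile and the background, standardized by the square
#' root of the gene's counted 4-mer windows (so the null score does not
#' depend on gene length), and a gene is flagged when its score exceeds
#' `mean + sd_mult * SD` of the per-gene scores.
#'
#' @param cds_seqs Named character vector of CDS sequences (coding
#'   orientation), names = gene ids.
#' @param min_len Minimum CDS length evaluated (shorter genes are reported
#'   `NA` = not evaluated).
#' @param sd_mult SD multiplier of the flag threshold.
#' @return `data.frame` with `gene_id`, `tetra_score`, `tetra_flag` (logical,
#'   `NA` for unevaluated genes).
#' @export
tetra_outliers <- function(cds_seqs, min_len = 300L, sd_mult = 2) {
  stopifnot(!is.null(names(cds_seqs)))
  len <- nchar(cds_seqs)
  eval_idx <- which(len >= min_len)
  if (length(eval_idx) < 20L)
    stop("fewer than 20 evaluable genes; background unstable")
  counts <- tetra_counts(cds_seqs[eval_idx])
  bg <- colSums(counts) / sum(counts)
  freq <- counts / rowSums(counts)
  score <- rowSums(abs(sweep(freq, 2L, bg))) * sqrt(rowSums(counts))
  thr <- mean(score) + sd_mult * sd(score)
  out <- data.frame(gene_id = names(cds_seqs),
                    tetra_score = NA_real_, tetra_flag = NA,
                    stringsAsFactors = FALSE)
  out$tetra_score[eval_idx] <- score
  out$tetra_flag[eval_idx] <- score > thr
  out
}

#' GC-content outliers among a genome's CDSs
#'
#' Flags genes whose GC content lies strictly more than `sd_mult` standard
#' deviations from the mean CDS GC of the genome (two-sided). With zero SD
#' no gene is flagged.
#'
#' @inheritParams tetra_outliers
#' @return `data.frame` with `gene_id`, `gc`, `gc_flag`.
#' @export
gc_outliers <- function(cds_seqs, sd_mult = 2) {
  stopifnot(!is.null(names(cds_seqs)))
  if (length(cds_seqs) < 2L) stop("need at least 2 genes for the GC filter")
  gc <- gc_content_each(cds_seqs)
  m <- mean(gc); s <- sd(gc)
  data.frame(gene_id = names(cds_seqs), gc = unname(gc),
             gc_flag = abs(gc - m) > sd_mult * s,
             stringsAsFactors = FALSE, row.names = NULL)
}

# RSCU machinery ------------------------------------------------------------

# synonymous families of translation table 11, excluding stop codons and
# single-codon families (ATG/Met, TGG/Trp): 59 informative codons
rscu_codon_families <- function() {
  code <- Biostrings::getGeneticCode("11")
  code <- code[code != "*"]
  fam <- split(names(code), unname(code))
  fam[lengths(fam) > 1L]
}

# RSCU vector over the 59 informative codons from a codon count vector;
# families with zero counts get NA
rscu_from_counts <- function(counts, families) {
  out <- numeric(0)
  for (fam in families) {
    tot <- sum(counts[fam])
    vals <- if (tot == 0) rep(NA_real_, length(fam))
            else counts[fam] * length(fam) / tot
    out <- c(out, setNames(vals, fam))
  }
  out
}

#' Relative synonymous codon usage of one or more CDSs
#'
#' RSCU of codon `c` is its observed count divided by the mean count of its
#' synonymous family. Stop codons and the single-codon families (ATG, TGG)
#' are excluded, leaving 59 dimensions. Counts from multiple sequences are
#' pooled.
#'
#' @param seqs Character vector of CDS sequences (lengths divisible by 3).
#' @return Named numeric vector of 59 RSCU values (`NA` for codons of
#'   families absent from the input).
#' @export
rscu <- function(seqs) {
  stopifnot(all(nchar(seqs) %% 3L == 0L))
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 3L, step = 3L))
  rscu_from_counts(counts, rscu_codon_families())
}

#' Codon-usage outliers among a genome's CDSs
#'
#' Per-gene RSCU vectors are compared to the background RSCU pooled over all
#' evaluable CDSs by Manhattan distance, standardized by the square root of
#' the gene's informative codon count (length-free null, as in
#' [tetra_outliers()]); genes are flagged at `mean + sd_mult * SD` of the
#' per-gene scores. Codon families absent from a gene are uninformative for
#' that gene and contribute zero distance. Genes whose length is not a
#' multiple of 3 are excluded with a warning.
#'
#' @inheritParams tetra_outliers
#' @return `data.frame` with `gene_id`, `codon_score`, `codon_flag`.
#' @export
codon_usage_outliers <- function(cds_seqs, min_len = 300L, sd_mult = 2) {
  stopifnot(!is.null(names(cds_seqs)))
  len <- nchar(cds_seqs)
  bad_frame <- len %% 3L != 0L
  if (any(bad_frame))
    warning(sum(bad_frame), " CDS(s) not a multiple of 3 excluded from codon screening")
  eval_idx <- which(len >= min_len & !bad_frame)
  if (length(eval_idx) < 20L)
    stop("fewer than 20 evaluable genes; background unstable")
  families <- rscu_codon_families()
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(cds_seqs[eval_idx]), width = 3L, step = 3L)
  bg <- rscu_from_counts(colSums(counts), families)
  codons <- names(bg)
  score <- vapply(seq_along(eval_idx), function(i) {
    g <- rscu_from_counts(counts[i, ], families)[codons]
    d <- abs(g - bg)
    sum(d, na.rm = TRUE) * sqrt(sum(counts[i, codons]))
  }, numeric(1L))
  thr <- mean(score) + sd_mult * sd(score)
  out <- data.frame(gene_id = names(cds_seqs),
                    codon_score = NA_real_, codon_flag = NA,
                    stringsAsFactors = FALSE)
  out$codon_score[eval_idx] <- score
  out$codon_flag[eval_idx] <- score > thr
  out
}

#' Full per-CDS composition report of a genome
#'
#' Combines [gc_outliers()], [tetra_outliers()] and [codon_usage_outliers()]
#' into one table. Genes below `min_len` carry `NA` ("not evaluated") tetra
#' and codon fields; the GC filter evaluates every CDS.
#'
#' @inheritParams tetra_outliers
#' @param run_codon Set `FALSE` to skip the codon-usage screen.
#' @return `data.frame` with `gene_id`, `length`, `gc`, `gc_flag`,
#'   `tetra_score`, `tetra_flag`, `codon_score`, `codon_flag`.
#' @export
composition_report <- function(cds_seqs, min_len = 300L, sd_mult = 2,
                               run_codon = TRUE) {
  gc <- gc_outliers(cds_seqs, sd_mult = sd_mult)
  tet <- tetra_outliers(cds_seqs, min_len = min_len, sd_mult = sd_mult)
  out <- data.frame(gene_id = names(cds_seqs),
                    length = unname(nchar(cds_seqs)),
                    stringsAsFactors = FALSE)
  out$gc <- gc$gc[match(out$gene_id, gc$gene_id)]
  out$gc_flag <- gc$gc_flag[match(out$gene_id, gc$gene_id)]
  out$tetra_score <- tet$tetra_score[match(out$gene_id, tet$gene_id)]
  out$tetra_flag <- tet$tetra_flag[match(out$gene_id, tet$gene_id)]
  if (run_codon) {
    cod <- codon_usage_outliers(cds_seqs, min_len = min_len, sd_mult = sd_mult)
    out$codon_score <- cod$codon_score[match(out$gene_id, cod$gene_id)]
    out$codon_flag <- cod$codon_flag[match(out$gene_id, cod$gene_id)]
  } else {
    out$codon_score <- NA_real_
    out$codon_flag <- NA
  }
  out
}
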