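# Whole-genome relatedness: fragment-based ANI and an intergenomic distance
# d2 (1 - summed identities / summed alignment length over kept fragments)
# with an optional logistic DDH mapping.

#' Parameters for fragment-based genome comparison
#'
#' The classical ANI recipe: the query is cut into consecutive 1,020-nt
#' fragments (tail discarded), each fragment is located in the subject by
#' shared 15-mer seeding (the most seed-supported subject window; ties break
#' to the leftmost position) and aligned by banded semi-global alignment.
#' Fragments are kept iff identity >= 30% over >= 70% of the fragment
#' length.
#'
#' @param frag_len Fragment length in nt.
#' @param k Seed k-mer length.
#' @param band Band half-width for the fragment alignment; default
#'   `max(32, 0.05 * frag_len)`.
#' @param min_identity,min_coverage Keep thresholds.
#' @param seed_step Stride between seed start positions in a fragment.
#' @return List of parameters.
#' @export
ani_params <- function(frag_len = 1020L, k = 15L, band = NULL,
                       min_identity = 0.30, min_coverage = 0.70,
                       seed_step = 3L) {
  if (is.null(band)) band <- max(32L, as.integer(ceiling(0.05 * frag_len)))
  list(frag_len = as.integer(frag_len), k = as.integer(k),
       band = as.integer(band), min_identity = min_identity,
       min_coverage = min_coverage, seed_step = as.integer(seed_step))
}

# one-way fragment table for query vs subject
fragment_table <- function(query, subject, params) {
  stopifnot(inherits(query, "ContigSet"), inherits(subject, "ContigSet"))
  qc <- as.character(query$contigs)
  # join subject contigs with N spacers so no window spans two contigs
  sub <- paste(as.character(subject$contigs),
               collapse = strrep("N", params$k + 5L))
  ft <- .ani_fragments_cpp(qc, sub, params$frag_len, params$k,
                           params$band, params$seed_step)
  ft$kept <- ft$identity >= params$min_identity &
    ft$coverage >= params$min_coverage
  ft
}

#' Average nucleotide identity between two genomes
#'
#' @param query,subject `ContigSet`s.
#' @param params See [ani_params()].
#' @param symmetric If `TRUE` (default), both directions are computed and
#'   their mean identities averaged (reciprocal ANI).
#' @return An `ANIResult` list: `query_id`, `subject_id`, `ani` (percent; `NA`
#'   with `flag = "no_fragment_kept"` if nothing aligned), `n_fragments_total`,
#'   `n_fragments_kept`, `mean_kept_identity_sd` (percent), and the per-fragment
#'   table(s) in `fragments`.
#' @export
ani <- function(query, subject, params = ani_params(), symmetric = TRUE) {
  ft_q <- fragment_table(query, subject, params)
  fts <- list(forward = ft_q)
  if (symmetric) fts$reverse <- fragment_table(subject, query, params)
  kept_ids <- lapply(fts, function(ft) ft$identity[ft$kept])
  per_dir <- vapply(kept_ids, function(x)
    if (length(x)) mean(x) else NA_real_, numeric(1L))
  n_total <- sum(vapply(fts, nrow, integer(1L)))
  n_kept <- sum(vapply(kept_ids, length, integer(1L)))
  all_kept <- unlist(kept_ids, use.names = FALSE)
  res <- list(
    query_id = query$genome_id,
    subject_id = subject$genome_id,
    ani = if (all(is.na(per_dir))) NA_real_ else 100 * mean(per_dir, na.rm = TRUE),
    n_fragments_total = n_total,
    n_fragments_kept = n_kept,
    mean_kept_identity_sd = if (length(all_kept) > 1L) 100 * sd(all_kept) else NA_real_,
    symmetric = symmetric,
    fragments = fts
  )
  if (n_kept == 0L) res$flag <- "no_fragment_kept"
  class(res) <- "ANIResult"
  res
}

#' @export
print.ANIResult <- function(x, ...) {
  cat(sprintf("ANI %s vs %s: %s (fragments kept %d/%d%s)\n",
              x$query_id, x$subject_id,
              if (is.na(x$ani)) "undefined" else sprintf("%.2f%%", x$ani),
              x$n_fragments_kept, x$n_fragments_total,
              if (x$symmetric) ", reciprocal" else ""))
  invisible(x)
}

#' Approximate logistic DDH calibration
#'
#' Maps the intergenomic distance `d2` to a percent DDH estimate through
#' `100 / (1 + exp(-(a + b * d2)))`. The shipped coefficients are an
#' approximate anchor through two subspecies-level reference points
#' (d2 = 0.012 -> 85%, d2 = 0.020 -> 80%); they are a convenience mapping,
#' not a reproduction of the GGDC regression.
#'
#' @return Named vector `c(a, b)`.
#' @export
ddh_default_calibration <- function() c(a = 2.257, b = -43.54)

#' Intergenomic distance (formula-2 style) with optional DDH mapping
#'
#' Reuses the kept fragment alignments of [ani()] as HSP proxies:
#' `d2 = 1 - sum(identical columns) / sum(aligned columns)`. When a
#' calibration `c(a, b)` is supplied, a percent DDH estimate is added via
#' the logistic map; otherwise `ddh_estimate` is `"uncalibrated"`.
#'
#' @inheritParams ani
#' @param calibration `NULL` (default) or `c(a, b)`; see
#'   [ddh_default_calibration()].
#' @return A `GenomeDistance` list: `query_id`, `subject_id`, `d2`,
#'   `ddh_estimate`, `n_fragments_kept`.
#' @export
ggdc_distance <- function(query, subject, params = ani_params(),
                          symmetric = TRUE, calibration = NULL) {
  a <- ani(query, subject, params = params, symmetric = symmetric)
  kept <- do.call(rbind, lapply(a$fragments, function(ft) ft[ft$kept, ]))
  if (is.null(kept) || nrow(kept) == 0L) {
    d2 <- NA_real_
  } else {
    d2 <- 1 - sum(kept$identical_cols) / sum(kept$aligned_cols)
  }
  ddh <- if (is.null(calibration)) {
    "uncalibrated"
  } else if (is.na(d2)) {
    NA_real_
  } else {
    100 / (1 + exp(-(calibration[["a"]] + calibration[["b"]] * d2)))
  }
  structure(list(query_id = query$genome_id, subject_id = subject$genome_id,
                 d2 = d2, ddh_estimate = ddh,
                 n_fragments_kept = a$n_fragments_kept, ani = a$ani),
            class = "GenomeDistance")
}

#' @export
print.GenomeDistance <- function(x, ...) {
  cat(sprintf("d2 %s vs %s: %.5f (DDH %s)\n", x$query_id, x$subject_id, x$d2,
              if (is.character(x$ddh_estimate)) x$ddh_estimate
              else sprintf("%.1f%%", x$ddh_estimate)))
  invisible(x)
}

#' GC content of sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from numerator and
#' denominator.
#'
#' @param x A nucleotide string, a character vector of sequences (e.g. a CDS
#'   set; counts are pooled), a [Biostrings::DNAStringSet], or a `ContigSet`.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  if (inherits(x, "ContigSet")) x <- x$contigs
  x <- Biostrings::DNAStringSet(x)
  f <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  tot <- colSums(f[, c("A", "C", "G", "T"), drop = FALSE])
  denom <- sum(tot)
  if (denom == 0) stop("no counted A/C/G/T bases")
  unname((tot[["C"]] + tot[["G"]]) / denom)
}

#' Per-sequence GC content
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] of sequences.
#' @return Numeric vector of GC fractions, one per sequence (`NaN` when a
#'   sequence has no counted base).
#' @export
gc_content_each <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  denom <- rowSums(f[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- (f[, "C"] + f[, "G"]) / denom
  setNames(gc, names(x))
}
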