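# Sequence and annotation I/O: FASTA genomes/proteomes, GFF3 CDS tables,
# CDS extraction and translation, Newick trees. All user-facing coordinates
# are GFF3-style 1-based inclusive.

#' Read a FASTA file as a contig set or protein set
#'
#' Nucleotide records are uppercased and any character outside `A,C,G,T,N`
#' is replaced by `N` (the number of replacements is reported via a message).
#' Protein records are uppercased and a single trailing stop symbol `*` is
#' stripped.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` for genomes/CDS, `"aa"` for proteins.
#' @param genome_id Label attached to the returned set; defaults to the file
#'   base name without extension.
#' @return For `alphabet = "nt"` a `ContigSet`: a list with elements
#'   `genome_id` and `contigs` (a [Biostrings::DNAStringSet]). For
#'   `alphabet = "aa"` a `ProteinSet`: a list with `genome_id` and `proteins`
#'   (a [Biostrings::AAStringSet]).
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa"), genome_id = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[[1L]])
  names(raw) <- ids
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in ", path)
  if (alphabet == "nt") {
    cleaned <- gsub("[^ACGTN]", "N", seqs)
    n_rep <- sum(nchar(seqs)) - sum(nchar(gsub("[^ACGTN]", "", seqs)))
    if (n_rep > 0L) message(n_rep, " non-ACGTN characters replaced by N")
    contig_set(genome_id, setNames(cleaned, ids))
  } else {
    seqs <- sub("\\*$", "", seqs)
    if (any(nchar(seqs) == 0L)) stop("empty protein after stop stripping in ", path)
    protein_set(genome_id, setNames(seqs, ids))
  }
}

#' Construct a ContigSet
#'
#' @param genome_id Genome label.
#' @param sequences Named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences over `A,C,G,T,N`.
#' @return A `ContigSet` list with `genome_id` and `contigs` (DNAStringSet).
#' @export
contig_set <- function(genome_id, sequences) {
  x <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("contig ids must be present and unique")
  if (any(Biostrings::width(x) == 0L)) stop("contig sequences must be non-empty")
  structure(list(genome_id = genome_id, contigs = x), class = "ContigSet")
}

#' Construct a ProteinSet
#'
#' @param genome_id Genome label.
#' @param sequences Named character vector or [Biostrings::AAStringSet].
#' @return A `ProteinSet` list with `genome_id` and `proteins` (AAStringSet).
#' @export
protein_set <- function(genome_id, sequences) {
  x <- Biostrings::AAStringSet(sequences)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("protein ids must be present and unique")
  chars <- as.character(x)
  if (any(grepl("\\*", sub("\\*$", "", chars))))
    stop("internal stop symbol in protein sequence")
  structure(list(genome_id = genome_id, proteins = x), class = "ProteinSet")
}

#' Write a ContigSet or ProteinSet to FASTA
#'
#' Sequences are wrapped at 80 columns.
#'
#' @param x A `ContigSet` or `ProteinSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "ContigSet")) x$contigs else x$proteins
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read CDS gene models from a GFF3 file
#'
#' Only rows with feature type `CDS` are consumed; the `ID` attribute (or
#' `locus_tag` when `ID` is absent) becomes the gene id. Coordinates are kept
#' 1-based inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` of gene models with columns `gene_id`, `contig_id`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`), `product`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  g <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(g) == 0L) stop("no CDS rows in ", path)
  id <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  if ("locus_tag" %in% names(g)) {
    lt <- as.character(g$locus_tag)
    id <- ifelse(is.na(id) | id == "", lt, id)
  }
  if (anyNA(id) || any(id == ""))
    stop("CDS row without ID or locus_tag attribute in ", path)
  strand <- as.character(g$strand)
  if (any(!strand %in% c("+", "-")))
    stop("CDS with undefined strand in ", path)
  if (any(g$end < g$start)) stop("CDS with end < start in ", path)
  product <- if ("product" %in% names(g)) as.character(g$product) else NA_character_
  gm <- data.frame(
    gene_id = id,
    contig_id = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = strand,
    product = product,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(gm$gene_id)) stop("duplicate gene_id in ", path)
  rownames(gm) <- NULL
  gm
}

#' Write CDS gene models to a GFF3 file
#'
#' @param genes Gene-model `data.frame` as returned by [read_gff_genes()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path, source = "hgtrio") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$source <- source
  gr$phase <- 0L  # whole-CDS features always start in frame
  gr$ID <- genes$gene_id
  gr$locus_tag <- genes$gene_id
  if (!is.null(genes$product)) gr$product <- genes$product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the CDS sequence of one gene model
#'
#' Returns the genomic subsequence `[start..end]`, reverse-complemented for
#' minus-strand genes, so the result reads in coding orientation.
#'
#' @param contigs A `ContigSet`.
#' @param gene One-row gene-model `data.frame` (or list) with `contig_id`,
#'   `start`, `end`, `strand`.
#' @return Nucleotide string of length `end - start + 1`.
#' @export
extract_cds <- function(contigs, gene) {
  stopifnot(inherits(contigs, "ContigSet"))
  cid <- as.character(gene$contig_id)
  if (!cid %in% names(contigs$contigs)) stop("unknown contig: ", cid)
  ctg <- contigs$contigs[[cid]]
  start <- as.integer(gene$start); end <- as.integer(gene$end)
  if (start < 1L || end > length(ctg) || start > end)
    stop("gene coordinates outside contig ", cid, ": ", start, "..", end)
  s <- Biostrings::subseq(ctg, start, end)
  if (as.character(gene$strand) == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Extract all CDS sequences of a genome
#'
#' @param contigs A `ContigSet`.
#' @param genes Gene-model `data.frame`.
#' @return Named character vector of CDS sequences (coding orientation),
#'   in the row order of `genes`.
#' @export
extract_all_cds <- function(contigs, genes) {
  out <- vapply(seq_len(nrow(genes)), function(i)
    extract_cds(contigs, genes[i, ]), character(1L))
  names(out) <- genes$gene_id
  out
}

#' Translate a CDS with the bacterial genetic code
#'
#' Uses translation table 11. A trailing stop is removed; internal stops are
#' translated as `*` with a warning. Codons containing `N` translate to `X`.
#'
#' @param nt Nucleotide string (coding orientation).
#' @param tolerant If `TRUE`, a length not divisible by 3 truncates the tail
#'   with a warning instead of erroring.
#' @return Amino-acid string.
#' @export
translate_cds <- function(nt, tolerant = FALSE) {
  n <- nchar(nt)
  if (n %% 3L != 0L) {
    if (!tolerant) stop("CDS length ", n, " not divisible by 3")
    warning("CDS length not divisible by 3; tail truncated")
    nt <- substr(nt, 1L, n - n %% 3L)
    if (nchar(nt) == 0L) return("")
  }
  aa <- if (grepl("[^ACGT]", nt)) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(nt),
      genetic.code = Biostrings::getGeneticCode("11"), no.init.codon = TRUE,
      if.fuzzy.codon = "solve"))
  } else {
    as.character(Biostrings::translate(
      Biostrings::DNAString(nt),
      genetic.code = Biostrings::getGeneticCode("11"), no.init.codon = TRUE))
  }
  aa <- sub("\\*$", "", aa)
  if (grepl("\\*", aa)) warning("internal stop codon in CDS")
  aa
}

# Vectorized translation of many CDSs (table 11). The fuzzy-codon machinery
# (N -> X) is only engaged for sequences that need it: building the fuzzy
# code dominates runtime otherwise.
translate_many <- function(nts) {
  stopifnot(all(nchar(nts) %% 3L == 0L))
  out <- character(length(nts))
  code <- Biostrings::getGeneticCode("11")
  clean <- !grepl("[^ACGT]", nts)
  if (any(clean)) {
    out[clean] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nts[clean]), genetic.code = code, no.init.codon = TRUE))
  }
  if (any(!clean)) {
    out[!clean] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nts[!clean]), genetic.code = code, no.init.codon = TRUE,
      if.fuzzy.codon = "solve"))
  }
  out <- sub("\\*$", "", out)
  setNames(out, names(nts))
}

#' Derive the proteome of a genome from its gene models
#'
#' @param contigs A `ContigSet`.
#' @param genes Gene-model `data.frame`.
#' @return A `ProteinSet` with one protein per gene, ids taken from `gene_id`.
#' @export
derive_proteome <- function(contigs, genes) {
  cds <- extract_all_cds(contigs, genes)
  protein_set(contigs$genome_id, translate_many(cds))
}

#' Read or write a phylogenetic tree in Newick format
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()]; round
#' trips preserve topology, labels and branch lengths.
#'
#' @param path File path.
#' @return `read_newick` returns an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param nt Nucleotide string over `A,C,G,T,N`.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}
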