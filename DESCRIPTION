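Package: hgtrio
Title: Comparative Genomics and Horizontal Gene Transfer Screening for
    Closely Related Bacterial Genome Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing trios of closely related bacterial genomes
    and screening their genes for horizontal acquisition. Implements
    fragment-based average nucleotide identity (ANI), an intergenomic
    distance with an optional DNA-DNA hybridization mapping, proteome
    conservation via the H-value homology score, parametric xenolog
    screening (tetranucleotide usage, relative synonymous codon usage,
    and a two-standard-deviation GC filter), distance-based gene trees
    with Robinson-Foulds incongruence testing, ortholog-anchor synteny
    and contig ordering, gene-cluster comparison, and per-gene evidence
    integration. Ships a seeded genome-trio simulator with planted
    xenologous genes and clusters for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    ape,
    phangorn,
    rtracklayer,
    stats,
    utils,
    tools,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
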