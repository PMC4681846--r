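Package: prodege
Title: Automated Decontamination of Draft Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates the contigs of a draft genome assembly (single
    amplified genomes, metagenome-assembled genomes, or isolates) into
    clean (target organism) and contaminant classes without manual
    screening. A homology stage assigns contigs by best nucleotide
    alignment against a lineage-annotated reference database; the
    classified contigs calibrate a distance cutoff in a PCA of canonical
    5-mer frequencies which then classifies the alignment-undecided
    contigs. When the target taxonomy is too shallow or no confident
    target bin emerges from alignment, a taxonomy-free mode bins contigs
    in a PCA of canonical 9-mer frequencies with a pre-calibrated cutoff
    tuned for 80% or better base-weighted specificity, taking the largest
    bin as the target. Includes a deterministic synthetic-mixture
    simulator with truth labels and a mock reference database, and
    base- and contig-weighted evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    GenomicRanges,
    optparse,
    readr,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
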