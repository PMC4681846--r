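#' Read an assembly FASTA into a contig table
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased and any character outside A/C/G/T/N (IUPAC
#' ambiguity codes, gaps, ...) is normalised to N so that downstream
#' handling of ambiguous positions is uniform.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length`, one row per
#'   contig in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("FASTA file '%s' contains no records.", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate contig id '%s' in '%s'.",
                  ids[anyDuplicated(ids)], path))
  }
  seqs <- unname(toupper(as.character(set)))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  tibble(id = unname(ids), seq = seqs, length = nchar(seqs))
}

#' Write contigs to FASTA
#'
#' Sequence lines are wrapped at 60 columns. Writing an empty table
#' produces an empty file. `read_fasta(write_fasta(x))` round-trips.
#'
#' @param contigs Tibble with `id` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  if (nrow(contigs) == 0L) {
    ok <- file.create(path)
    if (!ok) abort(sprintf("Cannot write to '%s'.", path))
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(setNames(contigs$seq, contigs$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a two-column lineage table for a reference database
#'
#' Tab-separated, no header: sequence id, semicolon-delimited lineage.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `subject_id`, `lineage` (string form;
#'   parse on demand with [parse_lineage()]).
#' @export
read_lineage_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    abort(sprintf("Malformed lineage table row at line %d of '%s' (expected 2 tab-separated fields).",
                  bad[1], path))
  }
  tibble(subject_id = vapply(parts, `[[`, character(1), 1L),
         lineage = vapply(parts, `[[`, character(1), 2L))
}

.aln_cols <- c("query_id", "subject_id", "pident", "aln_len", "mismatches",
               "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore")

#' Read a 12-column tabular alignment file
#'
#' The de-facto tabular dialect emitted by standard nucleotide aligners
#' (query id, subject id, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, e-value, bit score). Percent
#' identity is converted to a fraction. Subject lineages are resolved via
#' the reference database lineage table; a subject absent from it is a
#' hard error, as is any malformed row (reported with its line number).
#'
#' @param path Path to the alignment table.
#' @param lineages Lineage table from [read_lineage_table()].
#' @return Tibble of hits with `identity` as a fraction and a
#'   `subject_lineage` string column.
#' @export
read_alignment_table <- function(path, lineages) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  identity = numeric(), aln_len = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(),
                  evalue = numeric(), bitscore = numeric(),
                  subject_lineage = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad)) {
    abort(sprintf("Malformed alignment row at line %d of '%s' (expected 12 tab-separated fields, got %d).",
                  lineno[bad[1]], path, lengths(parts)[bad[1]]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L)
  badnum <- which(apply(is.na(num), 1L, any))
  if (length(badnum)) {
    abort(sprintf("Malformed alignment row at line %d of '%s' (non-numeric score field).",
                  lineno[badnum[1]], path))
  }
  hits <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    identity = num[, 1] / 100, aln_len = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]), gap_opens = as.integer(num[, 4]),
    qstart = as.integer(num[, 5]), qend = as.integer(num[, 6]),
    sstart = as.integer(num[, 7]), send = as.integer(num[, 8]),
    evalue = num[, 9], bitscore = num[, 10]
  )
  miss <- setdiff(hits$subject_id, lineages$subject_id)
  if (length(miss)) {
    abort(sprintf("Subject '%s' in '%s' is absent from the lineage table.",
                  miss[1], path))
  }
  dplyr::left_join(hits, lineages, by = "subject_id") |>
    dplyr::rename(subject_lineage = "lineage")
}

#' Read gene calls from a GFF3 file
#'
#' Intervals are converted to the package-internal 0-based half-open
#' convention. Requires the rtracklayer package.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `contig_id`, `start` (0-based), `end` (exclusive),
#'   `strand`, `gene_id`.
#' @export
read_genes_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading GFF3 requires the 'rtracklayer' package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("%s_g%d", as.character(GenomicRanges::seqnames(gr)), seq_along(gr))
  tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = ids
  )
}

#' Write gene calls to GFF3
#'
#' Internal 0-based half-open intervals are emitted as 1-based inclusive.
#'
#' @param genes Tibble from [call_genes()] or [read_genes_gff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\tprodege\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       genes$contig_id, genes$start + 1L, genes$end,
                       genes$strand, genes$gene_id), con)
  }
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  df[list_cols] <- lapply(df[list_cols], function(col)
    vapply(col, function(x) paste(unlist(x), collapse = ","), character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
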