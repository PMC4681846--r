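# Stage 1: nucleotide-homology classification. One best hit decides each
# contig, under a total tie-break order so labels never depend on input
# row order.

#' Filter alignment hits to the qualifying set
#'
#' @param hits Hit tibble (see [read_alignment_table()] /
#'   [align_shared_kmers()]).
#' @param config A [prodege_config()].
#' @return Hits with `identity >= min_identity` and
#'   `aln_len >= min_aln_len`.
#' @export
qualify_hits <- function(hits, config = prodege_config()) {
  dplyr::filter(hits, .data$identity >= config$min_identity,
                .data$aln_len >= config$min_aln_len)
}

# highest bitscore; ties -> higher identity, longer aln_len, then
# lexicographically smallest subject id
best_hit_per_query <- function(hits) {
  hits |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bitscore),
                   dplyr::desc(.data$identity), dplyr::desc(.data$aln_len),
                   .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}

.agreement_vs_target <- function(lineage_strings, target) {
  uniq <- unique(lineage_strings)
  agree <- vapply(uniq, function(s) {
    r <- agreement_rank(parse_lineage(s), target)
    if (is.null(r)) NA_character_ else r
  }, character(1))
  agree[match(lineage_strings, uniq)]
}

#' Classify contigs by nucleotide homology
#'
#' Each contig's best hit (highest bitscore; ties broken by identity,
#' alignment length, then subject id) decides it: CLEAN when the hit's
#' lineage agrees with the declared target at or deeper than
#' `rank_required_for_homology`, CONTAMINANT when it disagrees at or
#' above that rank. A contig is UNDECIDED when it has no hit or its best
#' hit fails the identity/length thresholds -- weak evidence abstains
#' rather than falling back to a lower-ranked hit.
#'
#' @param contigs Contig tibble.
#' @param hits Hit tibble (will be passed through [qualify_hits()]).
#' @param target Target `lineage`; must reach the required rank.
#' @param config A [prodege_config()].
#' @return Tibble `contig_id`, `label`, `decided_at_rank` (deepest
#'   agreement with the target; NA for UNDECIDED or domain-level
#'   disagreement), `subject_id`, `subject_lineage`, `identity`,
#'   `aln_len`, `bitscore`.
#' @export
classify_by_homology <- function(contigs, hits, target,
                                 config = prodege_config()) {
  req <- config$rank_required_for_homology
  if (!is_taxonomy_deep_enough(target, req)) {
    abort(sprintf(
      "Target lineage depth '%s' is shallower than required rank '%s'; use 9-mer-only mode.",
      lineage_depth(target), req))
  }
  # the single best hit decides; identity/length thresholds veto the
  # decision rather than re-select a weaker hit, so tightening thresholds
  # can only move contigs towards UNDECIDED, never flip CLEAN/CONTAMINANT
  best <- best_hit_per_query(hits)
  qualified <- best$identity >= config$min_identity &
    best$aln_len >= config$min_aln_len
  best <- best[qualified, , drop = FALSE]
  best$agree <- unname(.agreement_vs_target(best$subject_lineage, target))
  req_i <- rank_index(req)
  agree_i <- ifelse(is.na(best$agree), 0L,
                    vapply(best$agree, rank_index, integer(1), USE.NAMES = FALSE))
  best$label <- unname(ifelse(agree_i >= req_i, "CLEAN", "CONTAMINANT"))
  out <- tibble(contig_id = contigs$id) |>
    dplyr::left_join(
      dplyr::select(best, contig_id = "query_id", "label",
                    decided_at_rank = "agree", "subject_id",
                    "subject_lineage", "identity", "aln_len", "bitscore"),
      by = "contig_id")
  out$label[is.na(out$label)] <- "UNDECIDED"
  out$decided_at_rank[out$label == "UNDECIDED"] <- NA_character_
  out
}

#' Flag contigs carrying mostly eukaryotic genes
#'
#' A contig is flagged when a strict majority of its genes that have any
#' qualifying hit have their best (highest-bitscore) hit against a
#' eukaryotic subject (subject lineage domain `Eukaryota`). Contigs with
#' no qualifying gene hit are never flagged; a tie is not a majority.
#'
#' @param genes Gene table from [call_genes()].
#' @param hits_vs_euk Gene-level hit tibble (query ids are gene ids),
#'   typically against a eukaryote-only reference.
#' @param config A [prodege_config()].
#' @return Character vector of flagged contig ids.
#' @export
screen_eukaryotic <- function(genes, hits_vs_euk,
                              config = prodege_config()) {
  if (nrow(genes) == 0L || nrow(hits_vs_euk) == 0L) return(character())
  best <- best_hit_per_query(qualify_hits(hits_vs_euk, config))
  if (nrow(best) == 0L) return(character())
  dom <- vapply(best$subject_lineage,
                function(s) tolower(unclass(parse_lineage(s))[[1]]),
                character(1))
  best$is_euk <- dom == "eukaryota"
  per_contig <- best |>
    dplyr::inner_join(dplyr::select(genes, "gene_id", "contig_id"),
                      by = c(query_id = "gene_id")) |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(n_hit = dplyr::n(), n_euk = sum(.data$is_euk),
                     .groups = "drop")
  per_contig$contig_id[per_contig$n_euk * 2L > per_contig$n_hit]
}

#' Does homology yield a single confident target bin?
#'
#' True when the CLEAN-labelled contigs (i) number at least 3, (ii) cover
#' at least 10% of the assembly bases, and (iii) are not outweighed in
#' bases by any single contaminant phylum. When false the engine falls
#' back to taxonomy-free 9-mer binning.
#'
#' @param labels Output of [classify_by_homology()].
#' @param contigs Contig tibble.
#' @param min_clean_contigs,min_clean_fraction Clause thresholds.
#' @return Logical scalar.
#' @export
confident_target_bin_exists <- function(labels, contigs,
                                        min_clean_contigs = 3L,
                                        min_clean_fraction = 0.10) {
  len <- setNames(contigs$length, contigs$id)
  lab <- labels
  lab$bases <- len[lab$contig_id]
  clean <- dplyr::filter(lab, .data$label == "CLEAN")
  if (nrow(clean) < min_clean_contigs) return(FALSE)
  clean_bases <- sum(clean$bases)
  if (clean_bases < min_clean_fraction * sum(contigs$length)) return(FALSE)
  contam <- dplyr::filter(lab, .data$label == "CONTAMINANT",
                          !is.na(.data$subject_id))
  if (nrow(contam) == 0L) return(TRUE)
  # bases of the largest single conflicting phylum must not exceed clean
  contam$phylum <- vapply(contam$subject_lineage, function(s) {
    lin <- parse_lineage(s)
    if (length(lin) >= 2L) unclass(lin)[[2]] else unclass(lin)[[1]]
  }, character(1))
  biggest <- contam |>
    dplyr::group_by(.data$phylum) |>
    dplyr::summarise(bases = sum(.data$bases), .groups = "drop") |>
    dplyr::pull(.data$bases) |>
    max()
  biggest <= clean_bases
}
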