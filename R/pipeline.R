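# Engine orchestration: eukaryotic screen -> homology -> calibrated 5-mer
# distance classification of the alignment-undecided contigs; or, when
# taxonomy is too shallow / no confident target bin / no reference, the
# taxonomy-free 9-mer mode. Stage precedence is fixed: a contig decided
# by an earlier stage is never re-labelled by a later one.

#' Choose the engine mode
#'
#' The taxonomy-free 9-mer-only mode is used when (a) the target lineage
#' is shallower than the rank required for homology, (b) the homology
#' stage ran but produced no single confident target bin, or (c) no
#' reference database or hit table was supplied. Otherwise the
#' homology-calibrated 5-mer path runs.
#'
#' @param target Target `lineage`.
#' @param labels Homology labels ([classify_by_homology()]) or `NULL` if
#'   the homology stage did not run.
#' @param contigs Contig tibble (needed to weigh the bin-confidence
#'   clauses); may be `NULL` when `labels` is `NULL`.
#' @param config A [prodege_config()].
#' @return `"HOMOLOGY_5MER"` or `"NINEMER_ONLY"`.
#' @export
choose_mode <- function(target, labels = NULL, contigs = NULL,
                        config = prodege_config()) {
  if (!is_taxonomy_deep_enough(target, config$rank_required_for_homology)) {
    return("NINEMER_ONLY")
  }
  if (is.null(labels)) return("NINEMER_ONLY")
  if (!confident_target_bin_exists(labels, contigs)) return("NINEMER_ONLY")
  "HOMOLOGY_5MER"
}

#' Run the full decontamination engine
#'
#' @param contigs Assembly contig tibble from [read_fasta()] or
#'   [generate_mixture()].
#' @param target Target organism `lineage` (string or parsed).
#' @param ref_db Optional reference database: list with `seqs` (contig
#'   tibble) and `lineages` (from [read_lineage_table()]). Used with
#'   `aligner` when `hits` is not supplied.
#' @param hits Optional precomputed contig-level hit table
#'   ([read_alignment_table()]).
#' @param euk_db Optional eukaryote reference database (same shape as
#'   `ref_db`) for the gene-level eukaryote screen.
#' @param euk_hits Optional precomputed gene-level hit table; query ids
#'   must be gene ids of `genes`.
#' @param genes Optional gene calls ([call_genes()] or
#'   [read_genes_gff()]); computed with the built-in caller when needed.
#' @param config A [prodege_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `clean.fna`, `contaminant.fna`, `report.tsv`, `summary.txt` and
#'   `projection.tsv`.
#' @param aligner Function `(query, ref_db) -> hit tibble`; defaults to
#'   the built-in [align_shared_kmers()]. Any external nucleotide aligner
#'   can be dropped in via precomputed `hits` instead.
#' @return A `prodege_report`: `contigs` (per-contig tibble with final
#'   two-class `label`, deciding `stage`, homology columns, PC distance,
#'   flags), `summary` (mode, per-label counts and bases, cutoff, seed),
#'   `config`, plus stage detail (`cutoff`, `points`).
#' @export
run_prodege <- function(contigs, target,
                        ref_db = NULL, hits = NULL,
                        euk_db = NULL, euk_hits = NULL, genes = NULL,
                        config = prodege_config(), out_dir = NULL,
                        aligner = align_shared_kmers) {
  if (is.null(contigs) || nrow(contigs) == 0L) {
    abort("The assembly is empty.")
  }
  if (anyDuplicated(contigs$id)) {
    abort(sprintf("Duplicate contig id '%s' in the assembly.",
                  contigs$id[anyDuplicated(contigs$id)]))
  }
  if (!inherits(target, "lineage")) target <- parse_lineage(target)
  set.seed(config$seed)

  deep_enough <- is_taxonomy_deep_enough(target,
                                         config$rank_required_for_homology)

  # --- eukaryote screen (gene-level homology) ---------------------------
  euk_flagged <- character()
  if (is.null(euk_hits) && !is.null(euk_db)) {
    if (is.null(genes)) genes <- call_genes(contigs, config$min_orf_len)
    if (nrow(genes)) {
      euk_hits <- aligner(gene_sequences(contigs, genes), euk_db)
    }
  }
  if (!is.null(euk_hits) && !is.null(genes)) {
    euk_flagged <- screen_eukaryotic(genes, euk_hits, config)
  }

  # --- prokaryote homology stage ---------------------------------------
  hom <- NULL
  if (deep_enough) {
    if (is.null(hits) && !is.null(ref_db)) {
      hits <- aligner(contigs, ref_db)
    }
    if (!is.null(hits)) {
      hom <- classify_by_homology(contigs, hits, target, config)
      if (length(euk_flagged)) {
        i <- hom$contig_id %in% euk_flagged
        hom$label[i] <- "EUK_CONTAMINANT"
      }
    }
  }
  hom_for_mode <- if (is.null(hom)) NULL else
    dplyr::filter(hom, .data$label != "EUK_CONTAMINANT")
  mode <- choose_mode(target, hom_for_mode, contigs, config)

  res <- tibble(contig_id = contigs$id, length = contigs$length,
                label = NA_character_, stage = NA_character_,
                homology_label = NA_character_,
                subject_id = NA_character_,
                decided_at_rank = NA_character_,
                distance = NA_real_, bin = NA_integer_,
                flag = NA_character_)
  cutoff <- NULL
  points <- NULL
  warnings <- character()

  if (mode == "HOMOLOGY_5MER") {
    res$homology_label <- hom$label
    res$subject_id <- hom$subject_id
    res$decided_at_rank <- hom$decided_at_rank
    decided <- hom$label != "UNDECIDED"
    res$label[decided] <- ifelse(hom$label[decided] == "CLEAN",
                                 "CLEAN", "CONTAMINANT")
    res$stage[decided] <- ifelse(hom$label[decided] == "EUK_CONTAMINANT",
                                 "euk_screen", "homology")
    if (any(!decided)) {
      prof <- kmer_profile(contigs, config$kmer_small)
      proj_ok <- prof$projectable
      fit_rows <- proj_ok & contigs$length >= config$min_contig_len
      if (sum(fit_rows) < 2L) fit_rows <- proj_ok
      if (sum(fit_rows) < 2L) {
        # no composition model possible: retain undecided contigs
        res$label[!decided] <- "CLEAN"
        res$stage[!decided] <- "homology"
        res$flag[!decided] <- "homology_only"
        warnings <- c(warnings,
                      "insufficient contigs for composition binning; undecided contigs retained")
      } else {
        m <- min(config$n_components, sum(fit_rows) - 1L, ncol(prof$freq))
        model <- fit_pca(prof$freq[fit_rows, , drop = FALSE],
                         n_components = m)
        coords <- project_pca(model, prof$freq[proj_ok, , drop = FALSE])
        points <- projection_table(contigs, coords, proj_ok)
        is_clean_cal <- hom$label == "CLEAN" &
          contigs$length >= config$min_contig_len
        if (!any(is_clean_cal & proj_ok)) {   # all clean contigs are short
          is_clean_cal <- hom$label == "CLEAN"
        }
        is_con_cal <- hom$label %in% c("CONTAMINANT", "EUK_CONTAMINANT") &
          contigs$length >= config$min_contig_len
        clean_pts <- points[is_clean_cal, , drop = FALSE]
        contam_pts <- points[is_con_cal, , drop = FALSE]
        if (!is.null(config$user_cutoff)) {
          w <- clean_pts$weight[clean_pts$projectable]
          ctr <- colSums(pc_matrix(clean_pts)[clean_pts$projectable, ,
                                              drop = FALSE] * w) / sum(w)
          cutoff <- distance_cutoff(ctr, config$user_cutoff, "USER")
        } else {
          cutoff <- calibrate_cutoff(clean_pts, contam_pts,
                                     config$target_specificity)
        }
        dist_lab <- classify_by_distance(points, cutoff)
        res$distance <- dist_lab$distance[match(res$contig_id,
                                                dist_lab$contig_id)]
        fill <- !decided
        j <- match(res$contig_id[fill], dist_lab$contig_id)
        res$label[fill] <- dist_lab$label[j]
        res$stage[fill] <- "kmer5"
        res$flag[fill] <- dist_lab$flag[j]
      }
    }
  } else {
    nb <- ninemer_binning(contigs, config)
    j <- match(res$contig_id, nb$labels$contig_id)
    res$label <- nb$labels$label[j]
    res$stage <- "kmer9"
    res$distance <- nb$labels$distance[j]
    res$bin <- nb$labels$bin[j]
    res$flag <- nb$labels$flag[j]
    if (!is.null(hom)) {
      res$homology_label <- hom$label[match(res$contig_id, hom$contig_id)]
    }
    # the eukaryote screen outranks composition
    if (length(euk_flagged)) {
      i <- res$contig_id %in% euk_flagged
      res$label[i] <- "CONTAMINANT"
      res$stage[i] <- "euk_screen"
    }
    cutoff <- nb$cutoff
    points <- nb$points
    if (!is.null(nb$warning)) warnings <- c(warnings, nb$warning)
  }

  short <- contigs$length < config$min_contig_len
  if (any(short)) {
    res$flag[short] <- ifelse(is.na(res$flag[short]), "short",
                              paste(res$flag[short], "short", sep = ";"))
  }
  if (anyNA(res$label)) abort("Internal error: unlabelled contig.")

  summary <- list(
    mode = mode,
    n_contigs = nrow(contigs),
    total_bases = sum(contigs$length),
    n_clean = sum(res$label == "CLEAN"),
    n_contaminant = sum(res$label == "CONTAMINANT"),
    clean_bases = sum(res$length[res$label == "CLEAN"]),
    contaminant_bases = sum(res$length[res$label == "CONTAMINANT"]),
    cutoff_radius = if (is.null(cutoff)) NA_real_ else cutoff$radius,
    cutoff_source = if (is.null(cutoff)) NA_character_ else cutoff$source,
    target = format_lineage(target),
    seed = config$seed,
    warnings = warnings
  )
  report <- structure(
    list(contigs = res, summary = summary, config = config,
         cutoff = cutoff, points = points),
    class = "prodege_report")
  if (!is.null(out_dir)) write_report(report, contigs, out_dir)
  report
}

#' Write run outputs to a directory
#'
#' Emits `clean.fna`, `contaminant.fna`, `report.tsv` (per-contig),
#' `summary.txt`, and `projection.tsv` (PC coordinates, bin, distance)
#' when a composition stage ran. Clean plus contaminant bases always
#' equal the input assembly bases.
#'
#' @param report A `prodege_report`.
#' @param contigs The assembly tibble the report was computed from.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, contigs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$contigs
  keep <- res$label == "CLEAN"
  ord <- match(res$contig_id, contigs$id)
  write_fasta(contigs[ord[keep], ], file.path(dir, "clean.fna"))
  write_fasta(contigs[ord[!keep], ], file.path(dir, "contaminant.fna"))
  write_tsv_plain(res, file.path(dir, "report.tsv"))
  s <- report$summary
  lines <- c(
    sprintf("mode\t%s", s$mode),
    sprintf("target\t%s", s$target),
    sprintf("n_contigs\t%d", s$n_contigs),
    sprintf("total_bases\t%d", s$total_bases),
    sprintf("clean\t%d contigs\t%d bases", s$n_clean, s$clean_bases),
    sprintf("contaminant\t%d contigs\t%d bases", s$n_contaminant,
            s$contaminant_bases),
    sprintf("cutoff_radius\t%s", format(s$cutoff_radius, digits = 10)),
    sprintf("cutoff_source\t%s", s$cutoff_source),
    sprintf("seed\t%d", s$seed),
    if (length(s$warnings)) sprintf("warning\t%s", s$warnings)
  )
  writeLines(lines, file.path(dir, "summary.txt"))
  if (!is.null(report$points)) {
    proj <- dplyr::left_join(
      report$points,
      dplyr::select(res, "contig_id", "label", "distance"),
      by = "contig_id")
    write_tsv_plain(proj, file.path(dir, "projection.tsv"))
  }
  invisible(dir)
}

#' @export
print.prodege_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<prodege_report> mode %s, %d contigs (%d bases)\n",
              s$mode, s$n_contigs, s$total_bases))
  cat(sprintf("  clean:       %5d contigs  %9d bases\n",
              s$n_clean, s$clean_bases))
  cat(sprintf("  contaminant: %5d contigs  %9d bases\n",
              s$n_contaminant, s$contaminant_bases))
  if (!is.na(s$cutoff_radius)) {
    cat(sprintf("  cutoff: %.6g (%s)\n", s$cutoff_radius, s$cutoff_source))
  }
  for (w in s$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tidy a decontamination report
#'
#' @param x A `prodege_report`.
#' @param ... Unused.
#' @return The per-contig tibble (`tidy`), or a one-row run summary
#'   (`glance`).
#' @export
tidy.prodege_report <- function(x, ...) x$contigs

#' @rdname tidy.prodege_report
#' @export
glance.prodege_report <- function(x, ...) {
  s <- x$summary
  tibble(mode = s$mode, n_contigs = s$n_contigs,
         total_bases = s$total_bases, n_clean = s$n_clean,
         n_contaminant = s$n_contaminant, clean_bases = s$clean_bases,
         contaminant_bases = s$contaminant_bases,
         cutoff_radius = s$cutoff_radius, cutoff_source = s$cutoff_source,
         seed = s$seed)
}

#' Plot the composition projection of a run
#'
#' Scatter of the first two principal components, coloured by final
#' label, sized by contig length; the cutoff radius is drawn around the
#' clean centroid when the stage operated in at least two dimensions.
#'
#' @param object A `prodege_report` whose run included a composition
#'   stage.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prodege_report <- function(object, ...) {
  if (is.null(object$points)) {
    abort("This run has no composition projection to plot.")
  }
  d <- dplyr::left_join(
    object$points,
    dplyr::select(object$contigs, "contig_id", "label"),
    by = "contig_id") |>
    dplyr::filter(.data$projectable)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                       colour = .data$label,
                                       size = .data$weight)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "label",
                  title = "Contig composition projection") +
    ggplot2::theme_minimal()
  co <- object$cutoff
  if (!is.null(co) && length(co$center) >= 2L) {
    th <- seq(0, 2 * pi, length.out = 181)
    circ <- tibble(PC1 = co$center[1] + co$radius * cos(th),
                   PC2 = co$center[2] + co$radius * sin(th))
    p <- p + ggplot2::geom_path(data = circ,
                                ggplot2::aes(.data$PC1, .data$PC2),
                                inherit.aes = FALSE, linetype = 2)
  }
  p
}
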