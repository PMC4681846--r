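#' Run configuration
#'
#' Collects every tunable the decontamination engine uses, with the
#' defaults the protocol was calibrated for. Returned object is passed to
#' [run_prodege()] and the stage functions.
#'
#' @param kmer_small Word size for the homology-calibrated composition
#'   stage (default 5).
#' @param kmer_large Word size for the taxonomy-free composition mode
#'   (default 9). Must exceed `kmer_small`.
#' @param n_components Number of principal components the distance
#'   classification operates in (default 3).
#' @param target_specificity Base-weighted fraction of contaminant
#'   calibration sequence that must fall outside the clean radius, in
#'   (0, 1] (default 0.8).
#' @param user_cutoff Optional user-supplied distance cutoff (radius in PC
#'   space); overrides any calibrated or pre-calibrated radius.
#' @param min_contig_len Contigs shorter than this (bases) are still
#'   classified but excluded from PCA fitting and cutoff calibration
#'   (default 2000).
#' @param min_identity Minimum alignment identity fraction for a homology
#'   hit to qualify (default 0.95).
#' @param min_aln_len Minimum alignment length in bases for a hit to
#'   qualify (default 200).
#' @param rank_required_for_homology Rank the target lineage (and a best
#'   hit's agreement with it) must reach for the homology path
#'   (default "class").
#' @param min_orf_len Minimum open reading frame length in bases for the
#'   built-in gene caller (default 300).
#' @param ninemer_factor Pre-calibrated multiplier applied to the
#'   neighbour-graph linking distance to obtain the 9-mer-mode radius;
#'   the shipped value is derived by [calibration_suite()].
#' @param seed Integer seed echoed into reports; all pipeline stages are
#'   deterministic, the seed matters for simulation.
#'
#' @return A list of class `prodege_config`.
#' @export
#' @examples
#' cfg <- prodege_config(target_specificity = 0.9)
#' cfg$min_identity
prodege_config <- function(kmer_small = 5L,
                           kmer_large = 9L,
                           n_components = 3L,
                           target_specificity = 0.8,
                           user_cutoff = NULL,
                           min_contig_len = 2000L,
                           min_identity = 0.95,
                           min_aln_len = 200L,
                           rank_required_for_homology = "class",
                           min_orf_len = 300L,
                           ninemer_factor = NULL,
                           seed = 1L) {
  kmer_small <- as.integer(kmer_small)
  kmer_large <- as.integer(kmer_large)
  if (kmer_small >= kmer_large) {
    abort("`kmer_small` must be strictly less than `kmer_large`.")
  }
  if (kmer_small < 1L || kmer_large > 12L) {
    abort("k-mer sizes must lie in [1, 12].")
  }
  if (!(target_specificity > 0 && target_specificity <= 1)) {
    abort("`target_specificity` must lie in (0, 1].")
  }
  if (!(min_identity > 0 && min_identity <= 1)) {
    abort("`min_identity` must lie in (0, 1].")
  }
  if (!is.null(user_cutoff) && user_cutoff < 0) {
    abort("`user_cutoff` must be non-negative.")
  }
  if (n_components < 1L) abort("`n_components` must be >= 1.")
  rank_index(rank_required_for_homology)  # validates the rank name
  structure(
    list(
      kmer_small = kmer_small,
      kmer_large = kmer_large,
      n_components = as.integer(n_components),
      target_specificity = target_specificity,
      user_cutoff = user_cutoff,
      min_contig_len = as.integer(min_contig_len),
      min_identity = min_identity,
      min_aln_len = as.integer(min_aln_len),
      rank_required_for_homology = rank_required_for_homology,
      min_orf_len = as.integer(min_orf_len),
      ninemer_factor = ninemer_factor %||% ninemer_precalibrated_factor(),
      seed = as.integer(seed)
    ),
    class = "prodege_config"
  )
}

#' @export
print.prodege_config <- function(x, ...) {
  cat("<prodege_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}
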