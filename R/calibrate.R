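# Pre-calibration of the 9-mer cutoff factor on a synthetic mixture grid.
# The procedure -- not the shipped constant -- is the contract: the grid
# sweeps contamination fraction, compositional divergence (GC gap) and
# replicate seeds, and the factor chosen is the largest one whose median
# base-weighted specificity stays at or above the target.

.grid_lineages <- function() {
  list(
    target = "Bacteria;Calibrobacterota;Calibrobacteria;Calibrales;Calibraceae;Calibrivirga;synthetica",
    contam = "Bacteria;Contamiphyla;Contamia;Contamales;Contamaceae;Contamivirga;spuria"
  )
}

#' Derive the pre-calibrated 9-mer cutoff factor
#'
#' Runs taxonomy-free 9-mer binning over a grid of synthetic mixtures
#' (contamination fraction x GC gap x replicate seeds), sweeping candidate
#' radius factors over the shared binning geometry, and returns the
#' largest factor whose median base-weighted specificity across the grid
#' is at least `target_specificity`. Larger factors trade specificity for
#' sensitivity, so this picks the most sensitive cutoff that still meets
#' the specificity floor.
#'
#' @param seed Master seed; per-cell seeds are derived from it.
#' @param candidate_f Candidate factors, ascending.
#' @param contam_fracs Grid of contamination fractions of assembly bases.
#' @param gc_gaps Grid of GC gaps (target at `0.5 - gap/2`, contaminant at
#'   `0.5 + gap/2`).
#' @param n_seeds Replicates per grid cell.
#' @param total_bases Assembly size per mixture.
#' @param genome_length Source genome length (>= 50 kb).
#' @param target_specificity Specificity floor (default 0.8).
#' @param config Base [prodege_config()] for the binning geometry.
#' @return List: `factor` (the selected f), `grid` (tibble with one row
#'   per grid cell x candidate: specificity, sensitivity, accuracy), and
#'   `medians` (per-candidate median specificity/sensitivity).
#' @export
calibration_suite <- function(seed = 20150609,
                              candidate_f = seq(1, 4, by = 0.25),
                              contam_fracs = c(0.05, 0.10, 0.25, 0.40),
                              gc_gaps = c(0.10, 0.20, 0.30),
                              n_seeds = 3L,
                              total_bases = 2e5,
                              genome_length = 3e5,
                              target_specificity = 0.8,
                              config = prodege_config()) {
  if (genome_length < 5e4) abort("Calibration genomes must be >= 50 kb.")
  lins <- .grid_lineages()
  cells <- tidyr::expand_grid(frac = contam_fracs, gap = gc_gaps,
                              rep = seq_len(n_seeds))
  grid <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    frac <- cells$frac[i]; gap <- cells$gap[i]; rep <- cells$rep[i]
    cell_seed <- (seed + 7919L * i) %% .Machine$integer.max
    mix <- generate_mixture(mixture_spec(
      target = genome_spec(lins$target, genome_length, 0.5 - gap / 2,
                           seed = cell_seed),
      contaminants = list(list(
        spec = genome_spec(lins$contam, genome_length, 0.5 + gap / 2,
                           seed = cell_seed + 1L),
        fraction = frac)),
      total_bases = total_bases, seed = cell_seed + 2L))
    geo <- .ninemer_geometry(mix$contigs, config)
    if (is.null(geo)) return(NULL)
    truth <- setNames(mix$truth$truth, mix$truth$contig_id)
    purrr::map_dfr(candidate_f, function(f) {
      cutoff <- distance_cutoff(geo$center, geo$eps * f, "PRECALIBRATED")
      lab <- classify_by_distance(geo$points, cutoff)
      ev <- score_run(
        tibble(contig_id = lab$contig_id,
               length = mix$contigs$length[match(lab$contig_id,
                                                 mix$contigs$id)],
               label = lab$label),
        mix$truth)
      g <- glance(ev)
      tibble(frac = frac, gap = gap, rep = rep, f = f,
             specificity = g$specificity, sensitivity = g$sensitivity,
             accuracy = g$accuracy)
    })
  })
  medians <- grid |>
    dplyr::group_by(.data$f) |>
    dplyr::summarise(median_specificity = median(.data$specificity),
                     median_sensitivity = median(.data$sensitivity),
                     .groups = "drop")
  ok <- medians$f[medians$median_specificity >= target_specificity]
  if (!length(ok)) {
    abort(sprintf(
      "No candidate factor reaches median specificity %.2f on the grid.",
      target_specificity))
  }
  list(factor = max(ok), grid = grid, medians = medians)
}
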