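# Stage 2 fallback: taxonomy-free binning in 9-mer PCA space. Bins are
# connected components of the graph linking points within a data-derived
# distance eps; the largest bin by bases is presumed to be the target
# organism (a deliberate heuristic -- it inverts when contamination
# exceeds half the assembly bases).

# Geometry shared by classification and by cutoff pre-calibration:
# projection, eps, bins, target-bin centroid. Deterministic.
.ninemer_geometry <- function(contigs, config) {
  prof <- kmer_profile(contigs, config$kmer_large)
  proj_ok <- prof$projectable
  if (sum(proj_ok) < 2L) return(NULL)
  long_enough <- contigs$length >= config$min_contig_len
  fit_rows <- proj_ok & long_enough
  if (sum(fit_rows) < 2L) fit_rows <- proj_ok   # too few long contigs
  nz <- which(colSums(prof$freq[proj_ok, , drop = FALSE]) > 0)
  freq <- prof$freq[, nz, drop = FALSE]
  m <- min(config$n_components, sum(fit_rows) - 1L, length(nz))
  model <- fit_pca(freq[fit_rows, , drop = FALSE], n_components = m)
  coords <- project_pca(model, freq[proj_ok, , drop = FALSE])
  points <- projection_table(contigs, coords, proj_ok)

  xy <- coords[fit_rows[proj_ok], , drop = FALSE]
  ids_fit <- contigs$id[fit_rows]
  w_fit <- contigs$length[fit_rows]
  dmat <- as.matrix(stats::dist(xy))
  diag(dmat) <- Inf
  eps <- 2 * median(apply(dmat, 1L, min))
  g <- igraph::graph_from_adjacency_matrix(dmat <= eps, mode = "undirected",
                                           diag = FALSE)
  comp <- as.integer(igraph::components(g)$membership)
  bins <- tibble(contig_id = ids_fit, bin = comp, weight = w_fit) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(bases = sum(.data$weight), n = dplyr::n(),
                     min_id = min(.data$contig_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$bases), dplyr::desc(.data$n),
                   .data$min_id)
  target_bin <- bins$bin[1]
  in_target <- comp == target_bin
  center <- colSums(xy[in_target, , drop = FALSE] * w_fit[in_target]) /
    sum(w_fit[in_target])
  bin_of <- setNames(comp, ids_fit)
  points$bin <- unname(bin_of[points$contig_id])
  list(points = points, eps = eps, center = center, model = model,
       bins = bins, target_bin = target_bin)
}

#' Taxonomy-free 9-mer composition binning
#'
#' Projects all projectable contigs into the top principal components of
#' their canonical 9-mer frequency matrix (contigs shorter than
#' `min_contig_len` are excluded from the fit and projected afterwards).
#' Points within `eps` (twice the median nearest-neighbour distance among
#' fitted points) of each other join the same bin; the bin with the most
#' bases (ties: more contigs, then smallest lexicographic member id) is
#' the target bin. Everything within radius `user_cutoff` (if set) or
#' `eps * ninemer_factor` (pre-calibrated for at least 80% base-weighted
#' specificity on the synthetic calibration grid) of the target bin's
#' base-weighted centroid is CLEAN.
#'
#' With fewer than two projectable contigs no composition model exists;
#' everything is labelled CLEAN and the run is flagged.
#'
#' @param contigs Contig tibble.
#' @param config A [prodege_config()].
#' @return List: `labels` (tibble `contig_id`, `label`, `distance`,
#'   `bin`, `flag`), `points` (projection table with bin assignment),
#'   `cutoff` (`distance_cutoff`), `eps`, `model` (`pca_model`), and
#'   `warning` (string or NULL).
#' @export
ninemer_binning <- function(contigs, config = prodege_config()) {
  geo <- .ninemer_geometry(contigs, config)
  if (is.null(geo)) {
    msg <- "insufficient contigs for composition binning"
    labels <- tibble(contig_id = contigs$id, label = "CLEAN",
                     distance = NA_real_, bin = NA_integer_, flag = msg)
    return(list(labels = labels, points = NULL, cutoff = NULL,
                eps = NA_real_, model = NULL, warning = msg))
  }
  cutoff <- if (!is.null(config$user_cutoff)) {
    distance_cutoff(geo$center, config$user_cutoff, "USER")
  } else {
    distance_cutoff(geo$center, geo$eps * config$ninemer_factor,
                    "PRECALIBRATED")
  }
  labels <- classify_by_distance(geo$points, cutoff)
  labels$bin <- geo$points$bin
  labels <- labels[, c("contig_id", "label", "distance", "bin", "flag")]
  list(labels = labels, points = geo$points, cutoff = cutoff,
       eps = geo$eps, model = geo$model, warning = NULL)
}

#' Shipped pre-calibrated 9-mer cutoff factor
#'
#' The multiplier applied to the neighbour-linking distance `eps` to form
#' the 9-mer-mode radius. Derived by [calibration_suite()] as the largest
#' factor whose median base-weighted specificity over a synthetic mixture
#' grid stays at or above 0.80; the derivation script and the grid table
#' ship with the package (`scripts/calibrate_ninemer.R`,
#' `inst/extdata/ninemer_calibration.tsv`).
#'
#' @return A single numeric factor.
#' @export
ninemer_precalibrated_factor <- function() .NINEMER_FACTOR
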