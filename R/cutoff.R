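# Projection tables ("points") are tibbles with columns contig_id, weight
# (contig length in bases) and PC1..PCm coordinates; unprojectable contigs
# carry NA coordinates.

pc_cols <- function(points) grep("^PC[0-9]+$", names(points), value = TRUE)

pc_matrix <- function(points) {
  as.matrix(points[, pc_cols(points), drop = FALSE])
}

#' Build a projection table
#'
#' @param contigs Contig tibble.
#' @param coords Coordinate matrix from [project_pca()] whose rows align
#'   with the projectable contigs.
#' @param projectable Logical vector, one per contig.
#' @return Tibble `contig_id`, `weight`, `PC1..PCm`, `projectable`.
#' @export
projection_table <- function(contigs, coords, projectable) {
  m <- matrix(NA_real_, nrow = nrow(contigs), ncol = ncol(coords),
              dimnames = list(NULL, colnames(coords)))
  m[projectable, ] <- coords
  dplyr::bind_cols(
    tibble(contig_id = contigs$id, weight = contigs$length,
           projectable = unname(projectable)),
    as_tibble(m)
  )
}

#' Distance cutoff in component space
#'
#' @param center Numeric vector (the clean centroid in PC space).
#' @param radius Non-negative radius; points at Euclidean distance `<=
#'   radius` from `center` classify as clean (boundary inclusive).
#' @param source One of `"CALIBRATED"`, `"PRECALIBRATED"`, `"USER"`.
#' @return A `distance_cutoff` object.
#' @export
distance_cutoff <- function(center, radius,
                            source = c("CALIBRATED", "PRECALIBRATED", "USER")) {
  source <- match.arg(source)
  if (is.na(radius) || radius < 0) abort("`radius` must be non-negative.")
  structure(list(center = as.numeric(center), radius = radius,
                 source = source),
            class = "distance_cutoff")
}

#' @export
print.distance_cutoff <- function(x, ...) {
  cat(sprintf("<distance_cutoff> radius %.6g (%s), center (%s)\n",
              x$radius, x$source,
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

euclidean_from <- function(coords, center) {
  sqrt(rowSums(sweep(coords, 2L, center, "-")^2))
}

#' Calibrate a clean-centroid distance cutoff at a target specificity
#'
#' The centre is the base-weighted centroid of the clean calibration
#' points. The radius is the largest value such that the base-weighted
#' fraction of contaminant calibration points lying at or inside it is at
#' most `1 - target_specificity`; by this sorting construction the
#' specificity bound holds exactly on the calibration data. With no
#' contaminant points the radius is the maximum clean distance times a
#' slack factor of 1.5.
#'
#' @param clean_pts Projection table (see [projection_table()]) of
#'   homology-clean contigs; at least one projectable row.
#' @param contam_pts Projection table of homology-contaminant contigs, or
#'   `NULL`/empty.
#' @param target_specificity Fraction in (0, 1].
#' @param slack Slack multiplier used when no contaminant points exist.
#' @return A `distance_cutoff` with `source = "CALIBRATED"`.
#' @export
calibrate_cutoff <- function(clean_pts, contam_pts = NULL,
                             target_specificity = 0.8, slack = 1.5) {
  clean_pts <- dplyr::filter(clean_pts, .data$projectable)
  if (is.null(contam_pts)) contam_pts <- clean_pts[0, ]
  contam_pts <- dplyr::filter(contam_pts, .data$projectable)
  if (nrow(clean_pts) == 0L) {
    abort("No clean calibration points: use 9-mer-only binning instead.")
  }
  if (!(target_specificity > 0 && target_specificity <= 1)) {
    abort("`target_specificity` must lie in (0, 1].")
  }
  w <- clean_pts$weight
  center <- colSums(pc_matrix(clean_pts) * w) / sum(w)
  d_clean <- euclidean_from(pc_matrix(clean_pts), center)
  if (nrow(contam_pts) == 0L) {
    return(distance_cutoff(center, max(d_clean) * slack, "CALIBRATED"))
  }
  d_con <- euclidean_from(pc_matrix(contam_pts), center)
  w_con <- contam_pts$weight
  tol <- 1 - target_specificity
  # group equal distances: they enter or leave the ball together
  ord <- order(d_con)
  d_s <- d_con[ord]
  cum <- cumsum(w_con[ord]) / sum(w_con)
  grp_last <- !duplicated(d_s, fromLast = TRUE)   # last index of each distance
  du <- d_s[grp_last]
  cu <- cum[grp_last]                             # fraction inside ball of radius du
  ok <- cu <= tol + 1e-12
  if (all(ok)) {
    radius <- max(c(d_clean, du))
  } else {
    first_excluded <- du[which(!ok)[1]]
    radius <- first_excluded * (1 - 1e-9)
  }
  distance_cutoff(center, max(radius, 0), "CALIBRATED")
}

#' Classify points against a distance cutoff
#'
#' Boundary inclusive: distance equal to the radius classifies as CLEAN.
#' Unprojectable contigs are labelled CONTAMINANT and flagged
#' `"unprojectable"`.
#'
#' @param points Projection table.
#' @param cutoff A `distance_cutoff`.
#' @return Tibble `contig_id`, `label`, `distance`, `flag`.
#' @export
classify_by_distance <- function(points, cutoff) {
  stopifnot(inherits(cutoff, "distance_cutoff"))
  d <- rep(NA_real_, nrow(points))
  proj <- points$projectable
  if (any(proj)) {
    d[proj] <- euclidean_from(pc_matrix(points)[proj, , drop = FALSE],
                              cutoff$center)
  }
  tibble(
    contig_id = points$contig_id,
    label = dplyr::if_else(!proj, "CONTAMINANT",
                           dplyr::if_else(d <= cutoff$radius,
                                          "CLEAN", "CONTAMINANT",
                                          missing = "CONTAMINANT")),
    distance = d,
    flag = dplyr::if_else(proj, NA_character_, "unprojectable")
  )
}
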