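#' Fit a principal components model of k-mer frequencies
#'
#' Columns are centred by their unweighted mean; no variance scaling is
#' applied. Components are the top eigenvectors of the sample covariance
#' matrix. For wide matrices (many more k-mer columns than contigs) the
#' eigendecomposition is carried out in the n-dimensional sample space
#' (the Gram matrix), which is exact and avoids forming the p x p
#' covariance. Sign convention: each component's entry of largest absolute
#' value is made positive, so fitted models are reproducible bit-for-bit.
#'
#' @param x Numeric matrix, one row per contig, columns = k-mer
#'   frequencies (e.g. `kmer_profile()$freq`, projectable rows only).
#' @param n_components Number of components to retain.
#' @return An object of class `pca_model`: list with `mean`, `components`
#'   (p x m, orthonormal columns), `explained_variance` (descending
#'   eigenvalues of the sample covariance).
#' @export
fit_pca <- function(x, n_components = 3L) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) {
    abort(paste("Fewer than 2 projectable contigs: a composition model",
                "cannot be fitted; use homology-only classification."))
  }
  m <- as.integer(n_components)
  if (m < 1L || m > min(n - 1L, p)) {
    abort(sprintf("`n_components` must lie in [1, %d] for a %d x %d matrix.",
                  min(n - 1L, p), n, p))
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, "-")
  if (p <= max(n, 512L)) {
    cv <- crossprod(xc) / (n - 1)
    eg <- eigen(cv, symmetric = TRUE)
    ev <- eg$values[seq_len(m)]
    comp <- eg$vectors[, seq_len(m), drop = FALSE]
  } else {
    g <- tcrossprod(xc)                      # n x n Gram matrix
    eg <- eigen(g, symmetric = TRUE)
    mu <- pmax(eg$values[seq_len(m)], 0)
    if (any(mu <= 1e-12 * max(mu, 1e-300))) {
      abort("Frequency matrix rank is below `n_components`.")
    }
    comp <- crossprod(xc, eg$vectors[, seq_len(m), drop = FALSE])
    comp <- sweep(comp, 2L, sqrt(mu), "/")
    ev <- mu / (n - 1)
  }
  # deterministic sign: largest-|entry| of each component positive
  for (j in seq_len(m)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  ev <- pmax(ev, 0)
  structure(list(mean = ctr, components = comp, explained_variance = ev),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  tot <- sum(x$explained_variance)
  cat(sprintf("<pca_model> %d components over %d features\n",
              ncol(x$components), nrow(x$components)))
  cat("  explained variance:",
      paste(signif(x$explained_variance, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project frequency rows into component space
#'
#' @param model A `pca_model`.
#' @param x Frequency matrix with the same columns the model was fitted on.
#' @return Matrix of coordinates, one row per input row, `m` columns
#'   named `PC1..PCm`.
#' @export
project_pca <- function(model, x) {
  x <- as.matrix(x)
  coords <- sweep(x, 2L, model$mean, "-") %*% model$components
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  coords
}
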