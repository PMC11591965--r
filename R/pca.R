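#' Essential-dynamics PCA
#'
#' Principal component analysis of the superposed Cartesian C-alpha
#' coordinates: the eigendecomposition of the `3N x 3N` covariance matrix of
#' the flattened frames. Eigenvalues (Angstrom^2) are collective-mode
#' variances; their normalized values are the fraction of total motion each
#' mode explains. No mass weighting is applied.
#'
#' @param sup a [superpose()] result with more than one frame.
#' @param n_components number of components to keep in `projections`;
#'   defaults to all available (`min(3N, frames - 1)`).
#' @return An object of class `pca_result`: `eigenvalues` (all, descending),
#'   `variance_fraction`, `cumulative_fraction`, `projections`
#'   (frames x components), `loadings` (3N x components), `mean_structure`
#'   (3N vector).
#' @export
pca_trajectory <- function(sup, n_components = NULL) {
  stopifnot(inherits(sup, "superposition"))
  m <- flatten_coords(sup$aligned)
  if (nrow(m) < 2L) stop_nd("PCA needs more than one frame")
  max_comp <- min(ncol(m), nrow(m) - 1L)
  if (is.null(n_components)) n_components <- max_comp
  check_count(n_components, "n_components")
  if (n_components > max_comp)
    stop_nd(sprintf("n_components = %d exceeds the %d available components",
                    n_components, max_comp))
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  vf <- ev / sum(ev)
  structure(list(eigenvalues = ev,
                 variance_fraction = vf,
                 cumulative_fraction = cumsum(vf),
                 projections = p$x[, seq_len(n_components), drop = FALSE],
                 loadings = p$rotation[, seq_len(n_components), drop = FALSE],
                 mean_structure = p$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3L, length(x$variance_fraction))
  cat(sprintf("<pca_result> %d frames; PC1-%d explain %s (cum. %.1f%%)\n",
              nrow(x$projections), k,
              paste(sprintf("%.2f%%", 100 * x$variance_fraction[seq_len(k)]),
                    collapse = "/"),
              100 * x$cumulative_fraction[k]))
  invisible(x)
}

#' Scree table
#'
#' Eigenvalue rank against variance explained, the table behind a scree
#' plot, including the cumulative fraction (the "first three PCs" summary
#' is row 3 of the `cumulative` column).
#'
#' @param pca a [pca_trajectory()] result.
#' @param n_components rows to report (default 10 or all, whichever is
#'   fewer).
#' @return data frame `rank`, `eigenvalue`, `fraction`, `cumulative`.
#' @export
scree_table <- function(pca, n_components = 10L) {
  stopifnot(inherits(pca, "pca_result"))
  k <- min(n_components, length(pca$eigenvalues))
  data.frame(rank = seq_len(k),
             eigenvalue = pca$eigenvalues[seq_len(k)],
             fraction = pca$variance_fraction[seq_len(k)],
             cumulative = pca$cumulative_fraction[seq_len(k)])
}
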