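#' Principal component analysis of population allele frequencies
#'
#' PCA of the populations x loci matrix of reference-allele frequencies,
#' column-centered and (by default) unscaled, keeping at most
#' `min(K - 1, L)` axes. One column per locus is used: for biallelic loci
#' the alternate-allele column is perfectly anticorrelated with the
#' reference column and would only double-count the same geometry.
#'
#' @param freqs An `allele_freq_matrix` (or [genotype_table()], converted
#'   internally).
#' @param loci Optional locus subset; every retained cell must have data.
#' @param scale. Scale columns to unit variance before decomposition
#'   (default `FALSE`: frequencies already share a common scale).
#' @return Object of class `pca_result`: list with `eigenvalues`
#'   (descending, non-negative), `scores` (population coordinates),
#'   `loadings` (unit eigenvectors, loci x axes), `prop_var` (share of
#'   total variance per axis) and `loci`.
#' @export
population_pca <- function(freqs, loci = NULL, scale. = FALSE) {
  afm <- if (inherits(freqs, "genotype_table")) {
    compute_allele_frequencies(freqs)
  } else freqs
  ids <- if (is.null(loci)) afm$loci else loci
  idx <- match(ids, afm$loci)
  if (anyNA(idx)) stop("unknown locus id(s)")
  X <- afm$freq[, idx, drop = FALSE]
  if (anyNA(X)) stop("undefined frequencies in the requested subset")
  K <- nrow(X); L <- ncol(X)
  stopifnot(K >= 3, L >= 2)
  if (scale. && any(apply(X, 2, stats::sd) == 0)) {
    stop("cannot scale: constant locus column present")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  n_axes <- min(K - 1, L)
  ev <- pc$sdev[seq_len(n_axes)]^2
  if (sum(ev) <= .Machine$double.eps) {
    warning("all populations identical: eigenvalues are all zero")
  }
  structure(list(eigenvalues = ev,
                 scores = pc$x[, seq_len(n_axes), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_axes), drop = FALSE],
                 prop_var = if (sum(ev) > 0) ev / sum(ev) else ev,
                 loci = ids),
            class = "pca_result")
}

#' Average locus contribution to leading principal components (LC)
#'
#' The contribution of a locus to an axis is its squared loading on that
#' axis's unit eigenvector, so per-axis contributions sum to one. The LC
#' score is the unweighted mean contribution over the first `n_components`
#' axes (optionally eigenvalue-weighted); axes with (numerically) zero
#' eigenvalue among the first `n_components` carry no direction and are
#' excluded with a warning. Higher LC means the locus drives more of the
#' between-population structure.
#'
#' @param pca A `pca_result` from [population_pca()].
#' @param n_components Number of leading axes to average over (default 5);
#'   if fewer axes are available, all are used with a warning.
#' @param eigenvalue_weighted Weight axis contributions by their
#'   eigenvalues instead of equally (default `FALSE`).
#' @return Named numeric vector of LC scores, one per locus.
#' @export
locus_contribution_lc <- function(pca, n_components = 5,
                                  eigenvalue_weighted = FALSE) {
  stopifnot(inherits(pca, "pca_result"))
  n_avail <- length(pca$eigenvalues)
  if (n_avail < n_components) {
    warning("only ", n_avail, " axes available; using all of them")
    n_components <- n_avail
  }
  use <- seq_len(n_components)
  tol <- max(pca$eigenvalues, 1) * 1e-12
  nonzero <- pca$eigenvalues[use] > tol
  if (!any(nonzero)) stop("no non-degenerate axes among the first ",
                          n_components)
  if (!all(nonzero)) {
    warning("excluding ", sum(!nonzero), " zero-eigenvalue axis/axes ",
            "from the LC average")
    use <- use[nonzero]
  }
  contrib <- pca$loadings[, use, drop = FALSE]^2
  w <- if (eigenvalue_weighted) pca$eigenvalues[use] else rep(1, length(use))
  lc <- as.numeric(contrib %*% w) / sum(w)
  stats::setNames(lc, pca$loci)
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centers `-D^2 / 2` and eigendecomposes it, returning the top
#' `n_axes` coordinates and each axis's share of the positive-eigenvalue
#' sum. Axes with negative eigenvalues (non-Euclidean distances) are
#' reported but dropped from the coordinates.
#'
#' @param distance_matrix Symmetric, zero-diagonal distance matrix.
#' @param n_axes Number of coordinates to return (default 6; capped at the
#'   number of positive eigenvalues).
#' @return List with `coordinates` (items x axes), `eigenvalues` (all,
#'   including any negative ones) and `prop_var` (positive-eigenvalue
#'   shares for the returned axes).
#' @export
pcoa <- function(distance_matrix, n_axes = 6) {
  d <- as.matrix(distance_matrix)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  mds <- stats::cmdscale(stats::as.dist(d), k = min(n_axes, n - 1),
                         eig = TRUE)
  eig <- mds$eig
  pos <- eig[eig > 1e-12]
  coords <- mds$points
  keep <- seq_len(min(ncol(coords), length(pos), n_axes))
  coords <- coords[, keep, drop = FALSE]
  colnames(coords) <- paste0("axis", keep)
  list(coordinates = coords,
       eigenvalues = eig,
       prop_var = eig[keep] / sum(pos))
}
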