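#' PCA score projection
#'
#' Mean-centered principal component analysis (no scaling by default, as the
#' score plots are computed on raw TFR features). The sign of each component
#' is fixed by forcing its largest-magnitude loading to be positive, so the
#' projection is fully deterministic.
#'
#' @param x Numeric matrix (`n x p`) or a [feature_dataset()].
#' @param n_components Number of components requested; reduced with a warning
#'   if it exceeds the available rank.
#' @param standardize Scale columns to unit variance before PCA
#'   (default `FALSE`).
#' @return An object of class `tfr_pca`: list with `scores`
#'   (`n x n_components`), `loadings` (`p x n_components`, orthonormal
#'   columns), `explained_variance` (component variances, non-increasing),
#'   `center`, `scale`.
#' @export
pca_project <- function(x, n_components = 2L, standardize = FALSE) {
  if (inherits(x, "tfr_dataset")) x <- x$matrix
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("matrix contains non-finite values")
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_rank) {
    warning("requested ", n_components, " components but rank allows only ",
            max_rank, "; reducing")
    n_components <- max_rank
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize, rank. = n_components)
  k <- min(n_components, ncol(pc$rotation))
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    imax <- which.max(abs(loadings[, j]))
    if (loadings[imax, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance = pc$sdev[seq_len(k)]^2,
         center = pc$center,
         scale = if (standardize) pc$scale else NULL),
    class = "tfr_pca")
}

#' Davies-Bouldin cluster-quality index
#'
#' For clusters defined by the supplied labels, with centroid `c_i` (the
#' arithmetic mean) and dispersion `sigma_i` (mean Euclidean distance of the
#' cluster's rows to its centroid), the index is
#' `DB = (1/n) * sum_i max_{j != i} (sigma_i + sigma_j) / d(c_i, c_j)`.
#' Well-separated, tight clusters give a small index.
#'
#' @param x Numeric matrix or a [feature_dataset()] (its labels are used when
#'   `labels` is missing).
#' @param labels Class label per row; at least two distinct labels.
#' @return An object of class `tfr_cluster_report`: list with `db_index`,
#'   `centroids` (one row per label), `dispersions` (named), and
#'   `pairwise_centroid_distances` (symmetric matrix).
#' @export
#' @examples
#' m <- rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2))
#' davies_bouldin(m, c("A", "A", "B", "B"))$db_index  # 0.5
davies_bouldin <- function(x, labels = NULL) {
  if (inherits(x, "tfr_dataset")) {
    if (is.null(labels)) labels <- x$labels
    x <- x$matrix
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  classes <- unique(labels)
  n <- length(classes)
  if (n < 2L) stop("Davies-Bouldin index needs at least 2 distinct labels")
  centroids <- t(vapply(classes, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(ncol(x))))
  rownames(centroids) <- classes
  dispersions <- vapply(classes, function(cl) {
    rows <- x[labels == cl, , drop = FALSE]
    mean(sqrt(rowSums((rows - rep(centroids[cl, ], each = nrow(rows)))^2)))
  }, numeric(1L))
  d <- as.matrix(stats::dist(centroids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d[i, j] == 0)
      stop("clusters '", classes[i], "' and '", classes[j],
           "' have coincident centroids; Davies-Bouldin is undefined")
  }
  ratios <- vapply(seq_len(n), function(i)
    max((dispersions[i] + dispersions[-i]) / d[i, -i]), numeric(1L))
  structure(
    list(db_index = mean(ratios), centroids = centroids,
         dispersions = dispersions, pairwise_centroid_distances = d),
    class = "tfr_cluster_report")
}

#' @rdname davies_bouldin
#' @param ... Ignored.
#' @export
print.tfr_cluster_report <- function(x, ...) {
  cat(sprintf("<tfr_cluster_report> %d clusters, Davies-Bouldin index %.4f\n",
              length(x$dispersions), x$db_index))
  invisible(x)
}

#' Davies-Bouldin index per frequency band
#'
#' Applies [select_band()] then [davies_bouldin()] for each band, optionally
#' standardizing the selected columns first.
#'
#' @param ds A [feature_dataset()].
#' @param bands A list of [band()] objects; names are carried into the result.
#' @param standardize Scale each selected column to zero mean, unit variance
#'   before computing the index (default `FALSE`: raw features).
#' @return Data frame with columns `band`, `f_lo`, `f_hi`, `n_features`,
#'   `db_index`, one row per band.
#' @export
band_db_scan <- function(ds, bands, standardize = FALSE) {
  stopifnot(inherits(ds, "tfr_dataset"))
  if (inherits(bands, "tfr_band")) bands <- list(bands)
  nm <- names(bands)
  if (is.null(nm)) nm <- rep("", length(bands))
  out <- lapply(seq_along(bands), function(i) {
    sub <- select_band(ds, bands[[i]])
    m <- sub$matrix
    if (standardize) {
      sds <- apply(m, 2L, stats::sd)
      sds[sds == 0] <- 1
      m <- scale(m, center = TRUE, scale = sds)
    }
    data.frame(
      band = if (nzchar(nm[i])) nm[i]
             else sprintf("%g-%g Hz", bands[[i]]$f_lo, bands[[i]]$f_hi),
      f_lo = bands[[i]]$f_lo, f_hi = bands[[i]]$f_hi,
      n_features = ncol(m),
      db_index = davies_bouldin(m, sub$labels)$db_index,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
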