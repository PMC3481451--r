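#' Correlation distance between two profiles
#'
#' \code{1 - Pearson(x, y)}, the distance used throughout the clustering;
#' ranges over [0, 2].
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return The correlation distance.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("vectors must have equal length >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation distance undefined for zero-variance input")
  1 - stats::cor(x, y)
}

# Standardize each half of every row (zero mean, unit norm per track segment)
# then rescale the whole row to unit norm. Rows are then zero-mean and
# unit-norm, so Pearson correlation between rows is their dot product and the
# two marks contribute equally.
standardize_profile_rows <- function(mat, half_len = ncol(mat) %/% 2L) {
  out <- t(apply(mat, 1, function(r) {
    s1 <- standardize_segment(r[seq_len(half_len)])
    s2 <- standardize_segment(r[(half_len + 1L):length(r)])
    c(s1, s2)
  }))
  nrm <- sqrt(rowSums(out^2))
  nrm[nrm == 0] <- 1
  out / nrm
}

#' K-means clustering with correlation distance
#'
#' Lloyd iterations on standardized profile rows, realized as spherical
#' k-means: on centered unit-norm vectors the correlation distance is half
#' the squared Euclidean distance, so the usual mean-centroid update
#' monotonically decreases the within-cluster correlation distance and Lloyd
#' convergence is guaranteed. The best of \code{n_init} seeded restarts (by
#' total within-cluster distance) is returned. An empty cluster arising
#' during iteration is re-seeded from the point farthest from its centroid.
#'
#' @param mat Profile matrix (rows = concatenated Pol-II/H3K4me2 profiles);
#'   every row segment must be non-constant.
#' @param k Number of clusters.
#' @param n_init Number of random restarts (default 10).
#' @param seed Integer seed making the restarts reproducible.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A \code{signature_clusters} object: \code{labels} (1..k per row),
#'   \code{centroids} (k x ncol standardized), \code{k}, \code{withinss}
#'   (total within-cluster correlation distance), \code{silhouette} (NA for
#'   k = 1), \code{seed}.
#' @export
kmeans_correlation <- function(mat, k, n_init = 10L, seed = 1L,
                               max_iter = 100L) {
  n <- nrow(mat)
  if (n < k) stop("need at least k rows")
  std <- standardize_profile_rows(mat)
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      cent <- std[sample.int(n, k), , drop = FALSE]
      labels <- rep(0L, n)
      for (iter in seq_len(max_iter)) {
        sim <- std %*% t(cent)                 # dot product = correlation
        new_labels <- max.col(sim, ties.method = "first")
        for (j in seq_len(k)) {
          if (!any(new_labels == j)) {
            # re-seed an empty cluster from the worst-fit point, never
            # stripping a cluster down to zero members in the process
            d <- 1 - sim[cbind(seq_len(n), new_labels)]
            sizes <- tabulate(new_labels, k)
            eligible <- which(sizes[new_labels] > 1L)
            far <- eligible[which.max(d[eligible])]
            cent[j, ] <- std[far, ]
            new_labels[far] <- j
          }
        }
        if (identical(new_labels, labels)) break
        labels <- new_labels
        for (j in seq_len(k)) {
          m <- colMeans(std[labels == j, , drop = FALSE])
          cent[j, ] <- standardize_profile_rows(matrix(m, 1))
        }
      }
      sim <- std %*% t(cent)
      wss <- sum(1 - sim[cbind(seq_len(n), labels)])
      if (is.null(best) || wss < best$withinss - 1e-12)
        best <- list(labels = labels, centroids = cent, withinss = wss)
    }
  })
  sil <- if (k >= 2) silhouette_score(mat, best$labels) else NA_real_
  structure(list(labels = best$labels, centroids = best$centroids, k = k,
                 withinss = best$withinss, silhouette = sil, seed = seed),
            class = "signature_clusters")
}

#' @export
print.signature_clusters <- function(x, ...) {
  cat("<signature_clusters> k =", x$k, "\n")
  cat("  sizes:     ", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  cat("  within-ss: ", format(x$withinss), "\n")
  cat("  silhouette:", format(x$silhouette), "\n")
  invisible(x)
}

#' Mean silhouette under correlation distance
#'
#' Standard silhouette width (b - a) / max(a, b) averaged over points, with
#' the pairwise dissimilarity \code{1 - cor}; singleton clusters contribute 0.
#'
#' @param mat Profile matrix.
#' @param labels Integer cluster labels, at least two distinct clusters.
#' @return Mean silhouette width in [-1, 1].
#' @export
silhouette_score <- function(mat, labels) {
  if (length(unique(labels)) < 2)
    stop("silhouette needs at least 2 clusters")
  d <- stats::as.dist(1 - stats::cor(t(mat)))
  sil <- cluster::silhouette(as.integer(labels), d)
  if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0  # all-singleton case
}

#' Choose the number of clusters by silhouette
#'
#' Runs \code{\link{kmeans_correlation}} for each candidate k and returns the
#' clustering with the highest mean silhouette; ties break toward smaller k.
#'
#' @param mat Profile matrix.
#' @param k_range Candidate cluster counts (default 2:8).
#' @param seed Integer seed.
#' @param n_init Restarts per k.
#' @return The winning \code{signature_clusters} object.
#' @export
select_k <- function(mat, k_range = 2:8, seed = 1L, n_init = 10L) {
  if (length(k_range) == 0) stop("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(k_range, function(k)
    kmeans_correlation(mat, k, n_init = n_init, seed = seed))
  sils <- vapply(fits, function(f)
    if (is.na(f$silhouette)) -Inf else f$silhouette, numeric(1))
  best <- fits[[which.max(sils)]]        # which.max takes the first = smallest k
  best$silhouette_by_k <- stats::setNames(sils, k_range)
  best
}
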