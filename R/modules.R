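# Silhouette-guided choice of k and k-means assignment of distal genes to
# modules, in Laplacian-eigenmap coordinates.

#' Mean silhouette of a labelled point set
#'
#' Per point, `s = (b - a) / max(a, b)` with `a` the mean distance to the
#' other members of its own cluster and `b` the smallest mean distance to
#' any other cluster; singletons score 0, as do points with `a = b = 0`.
#' Euclidean distances.
#'
#' @param points numeric matrix (points x dimensions); ignored when
#'   `dist_matrix` is supplied.
#' @param labels cluster labels, one per point (at least 2 clusters).
#' @param dist_matrix optional precomputed symmetric distance matrix.
#' @return mean silhouette in `[-1, 1]`.
#' @export
mean_silhouette <- function(points, labels, dist_matrix = NULL) {
  labels <- as.character(labels)
  if (is.null(dist_matrix)) {
    stopifnot(is.matrix(points))
    dist_matrix <- as.matrix(dist(points))
  }
  n <- nrow(dist_matrix)
  stopifnot(length(labels) == n)
  clusters <- unique(labels)
  if (length(clusters) < 2L) stop("silhouette needs at least 2 clusters")
  G <- vapply(clusters, function(cl) as.numeric(labels == cl),
              numeric(n))
  sizes <- colSums(G)
  sums <- dist_matrix %*% G                  # n x k total distance to cluster
  lab_idx <- match(labels, clusters)
  own_size <- sizes[lab_idx]
  a <- sums[cbind(seq_len(n), lab_idx)] / pmax(own_size - 1, 1)
  means <- sweep(sums, 2, sizes, "/")
  means[cbind(seq_len(n), lab_idx)] <- Inf    # mask own cluster
  b <- apply(means, 1, min)
  s <- (b - a) / pmax(a, b)
  s[own_size == 1] <- 0                       # singleton convention
  s[!is.finite(s)] <- 0                       # a = b = 0
  mean(s)
}

# k-means++ seeding.
kmeans_pp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(0, k, ncol(points))
  first <- sample.int(n, 1L)
  centers[1L, ] <- points[first, ]
  d2 <- rowSums(sweep(points, 2, centers[1L, ])^2)
  if (k > 1L) {
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      pick <- sample.int(n, 1L, prob = prob)
      centers[j, ] <- points[pick, ]
      d2 <- pmin(d2, rowSums(sweep(points, 2, centers[j, ])^2))
    }
  }
  centers
}

# k-means with k-means++ restarts; returns the best fit by total
# within-cluster sum of squares.  Caller controls the RNG state.
fit_kmeans <- function(points, k, n_init = 25L) {
  best <- NULL
  for (rep in seq_len(n_init)) {
    centers <- kmeans_pp_centers(points, k)
    centers <- centers + 1e-12 * matrix(rnorm(length(centers)), k)
    fit <- tryCatch(
      suppressWarnings(kmeans(points, centers = centers, iter.max = 100L,
                              algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for every restart (k = ", k, ")")
  best
}

#' Scan candidate k by mean silhouette
#'
#' Runs k-means (k-means++ seeding, `n_init` restarts, seeded RNG stream)
#' for every `k` in `k_range` and records the mean silhouette of each
#' clustering; the chosen `k` maximizes it, with ties going to the smaller
#' `k`.  By default the silhouette is evaluated with Euclidean distances in
#' the clustering space; supplying `dist_matrix` evaluates it in another
#' space (e.g. expression-space distances, so that clusters that exist only
#' as embedding artifacts do not inflate the chosen `k`).
#'
#' @param points numeric matrix (points x dimensions) that k-means runs on.
#' @param k_range candidate numbers of clusters (default `2:15`).
#' @param n_init k-means restarts per candidate (default 25).
#' @param seed RNG seed for the scan.
#' @param dist_matrix optional symmetric distance matrix (rows aligned with
#'   `points`) used for the silhouette evaluation.
#' @return list with `chosen_k` and `silhouette_by_k` (named vector).
#' @export
select_k_by_silhouette <- function(points, k_range = 2:15, n_init = 25L,
                                   seed = 1L, dist_matrix = NULL) {
  stopifnot(length(k_range) >= 1L, max(k_range) < nrow(points))
  D <- if (is.null(dist_matrix)) as.matrix(dist(points)) else dist_matrix
  stopifnot(nrow(D) == nrow(points))
  sil <- setNames(numeric(length(k_range)), as.character(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    fit <- with_seed(stage_seed(seed, paste0("kscan", k)), {
      fit_kmeans(points, k, n_init)
    })
    sil[j] <- mean_silhouette(labels = fit$cluster, dist_matrix = D,
                              points = NULL)
  }
  chosen <- k_range[which.max(sil)]   # which.max: first max -> smaller k wins
  list(chosen_k = chosen, silhouette_by_k = sil)
}

#' Assign points to named modules by k-means
#'
#' Clusters are renamed `M1..Mk` by descending size (ties broken by the
#' smallest member row index), making the naming deterministic and
#' order-invariant.
#'
#' @param points numeric matrix with rownames (gene IDs).
#' @param k number of modules (>= 2).
#' @param n_init k-means restarts (default 25).
#' @param seed RNG seed.
#' @return a `module_assignment` list with `labels` (named character,
#'   `"M1".."Mk"`), `k`, `centroids` (k x m, in `M1..Mk` order), `sizes` and
#'   `tot_withinss`.
#' @export
assign_modules <- function(points, k, n_init = 25L, seed = 1L) {
  stopifnot(is.matrix(points), k >= 2L)
  if (k > nrow(points)) stop("k exceeds the number of points")
  fit <- with_seed(stage_seed(seed, paste0("assign", k)), {
    fit_kmeans(points, k, n_init)
  })
  sizes <- tabulate(fit$cluster, nbins = k)
  first_member <- vapply(seq_len(k),
                         function(cl) min(which(fit$cluster == cl)),
                         numeric(1))
  ord <- order(-sizes, first_member)
  new_name <- character(k)
  new_name[ord] <- paste0("M", seq_len(k))
  labels <- setNames(new_name[fit$cluster], rownames(points))
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("M", seq_len(k))
  structure(list(labels = labels, k = as.integer(k), centroids = centroids,
                 sizes = setNames(sizes[ord], paste0("M", seq_len(k))),
                 tot_withinss = fit$tot.withinss),
            class = "module_assignment")
}
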