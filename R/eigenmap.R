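# Laplacian eigenmap of genes: Mahalanobis metric over sample coordinates,
# kNN graph, and the generalized (random-walk) Laplacian eigenproblem.

#' Estimate the Mahalanobis metric over sample coordinates
#'
#' Genes are treated as observations in sample space; the sample-by-sample
#' covariance is estimated across genes and inverted with a Moore-Penrose
#' pseudo-inverse, optionally after shrinkage toward a scaled identity.
#'
#' @param x numeric matrix (genes x samples) or an [expression_matrix()].
#' @param shrinkage shrinkage intensity in `[0, 1]` toward
#'   `mean(diag(S)) * I` (0 = plain pseudo-inverse).
#' @return a `metric_model` list with `covariance`, `inverse` and
#'   `shrinkage`.
#' @export
estimate_metric <- function(x, shrinkage = 0) {
  if (inherits(x, "expression_matrix")) x <- x$values
  stopifnot(is.matrix(x), shrinkage >= 0, shrinkage <= 1)
  if (nrow(x) < 2L) stop("need at least 2 genes to estimate a covariance")
  S <- cov(x)
  if (shrinkage > 0) {
    S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(ncol(x))
  }
  inv <- MASS::ginv(S)
  inv <- (inv + t(inv)) / 2
  structure(list(covariance = S, inverse = inv, shrinkage = shrinkage),
            class = "metric_model")
}

#' Pairwise Mahalanobis distances between genes
#'
#' `d(x, y) = sqrt((x - y)' M^- (x - y))` with `M^-` the (pseudo-)inverse
#' covariance of the metric model.  With an identity metric this is the
#' Euclidean distance.
#'
#' @param x numeric matrix (genes x samples) or [expression_matrix()].
#' @param metric a `metric_model` from [estimate_metric()], or `NULL` for
#'   the identity metric.
#' @return symmetric genes x genes distance matrix with zero diagonal.
#' @export
pairwise_mahalanobis <- function(x, metric = NULL) {
  if (inherits(x, "expression_matrix")) x <- x$values
  stopifnot(is.matrix(x))
  A <- if (is.null(metric)) diag(ncol(x)) else metric$inverse
  if (nrow(A) != ncol(x)) stop("metric dimension does not match sample count")
  ev_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(abs(A))) {
    stop("metric inverse is not positive semi-definite")
  }
  Y <- x %*% A
  sq <- rowSums(Y * x)
  D2 <- outer(sq, sq, "+") - 2 * Y %*% t(x)
  D2 <- (D2 + t(D2)) / 2
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D <- sqrt(D2)
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

#' Build a symmetric k-nearest-neighbour graph from a distance matrix
#'
#' Each node is connected to its `k` nearest other nodes (ties broken by
#' lower index); the adjacency is symmetrized by union (an edge exists if
#' either endpoint selected the other), giving every node degree at least
#' `k`.  Edges are unweighted unless `affinity = "heat"`, in which case the
#' selected edges carry heat-kernel weights `exp(-d^2 / sigma^2)` with
#' `sigma` the median of the selected kNN distances.
#'
#' @param distances symmetric distance matrix.
#' @param k number of neighbours (default 23).
#' @param affinity `"binary"` (default) or `"heat"`.
#' @return a `knn_graph` list with the sparse `adjacency`, `k`, `n_nodes`,
#'   `n_components`, `component_membership` and `node_ids`.
#' @export
build_knn_graph <- function(distances, k = 23L, affinity = c("binary", "heat")) {
  affinity <- match.arg(affinity)
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  n <- nrow(distances)
  if (k >= n) stop("k must be smaller than the number of nodes")
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- distances[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))   # ties broken by lower index
    idx[i, ] <- ord[seq_len(k)]
  }
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(idx))
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  A <- ((A + Matrix::t(A)) > 0) * 1   # union symmetrization, binary
  if (affinity == "heat") {
    edges <- Matrix::which(A > 0, arr.ind = TRUE)
    d_sel <- distances[cbind(from, to)]
    sigma <- median(d_sel)
    if (sigma <= 0) sigma <- 1
    w <- exp(-(distances[edges]^2) / sigma^2)
    A <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = w,
                              dims = c(n, n))
  }
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  comp <- igraph::components(g)
  structure(list(adjacency = A, k = as.integer(k), n_nodes = n,
                 n_components = comp$no,
                 component_membership = comp$membership,
                 node_ids = rownames(distances)),
            class = "knn_graph")
}

# Eigen-decomposition of the (optionally random-walk normalized) Laplacian.
# Returns eigenvalues ascending with matching eigenvectors.
laplacian_eigen <- function(W, normalization = c("randomwalk", "unnormalized")) {
  normalization <- match.arg(normalization)
  W <- as.matrix(W)
  d <- rowSums(W)
  if (any(d <= 0)) stop("graph has isolated nodes")
  if (normalization == "randomwalk") {
    # Generalized problem L v = lambda D v via the symmetric form
    # L_sym = I - D^{-1/2} W D^{-1/2}; v = D^{-1/2} u.
    s <- 1 / sqrt(d)
    M <- diag(nrow(W)) - (s * W) * rep(s, each = nrow(W))
    M <- (M + t(M)) / 2
    e <- eigen(M, symmetric = TRUE)
    ord <- order(e$values)
    vecs <- e$vectors[, ord, drop = FALSE] * s
    list(values = e$values[ord], vectors = vecs)
  } else {
    L <- diag(d) - W
    e <- eigen((L + t(L)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
  }
}

#' Full Laplacian spectrum of a kNN graph
#'
#' Mainly a diagnostic: the number of (near-)zero eigenvalues equals the
#' number of connected components.
#'
#' @param graph a `knn_graph`.
#' @param normalization `"randomwalk"` or `"unnormalized"`.
#' @return numeric vector of eigenvalues, ascending.
#' @export
laplacian_spectrum <- function(graph,
                               normalization = c("randomwalk", "unnormalized")) {
  laplacian_eigen(graph$adjacency, normalization)$values
}

#' Laplacian eigenmap coordinates of graph nodes
#'
#' Solves the generalized eigenproblem `L v = lambda D v` (`L = D - W`),
#' sorts eigenvalues ascending, drops the trivial (near-zero eigenvalue)
#' eigenvectors -- one per connected component -- and returns the next `m`
#' coordinates per node.  Eigenvectors are `D`-orthonormal.
#'
#' @param graph a `knn_graph`.
#' @param m number of embedding coordinates (default 8).
#' @param include_trivial keep the trivial constant eigenvector(s) among the
#'   returned coordinates (alternative 1-based-counting convention).
#' @param normalization `"randomwalk"` (generalized problem, default) or
#'   `"unnormalized"`.
#' @param min_component_frac minimum fraction of nodes the largest connected
#'   component must cover; below this the embedding errors out.
#' @param largest_component_only embed the largest component even when the
#'   graph is disconnected (dropped nodes are reported).
#' @return an `eigenmap_embedding` list with `coordinates` (nodes x m,
#'   rownames = node IDs), `eigenvalues` (ascending, the retained ones),
#'   `dropped_trivial`, `gene_ids` and `dropped_gene_ids`.
#' @export
laplacian_embedding <- function(graph, m = 8L, include_trivial = FALSE,
                                normalization = c("randomwalk", "unnormalized"),
                                min_component_frac = 0.95,
                                largest_component_only = FALSE) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(graph, "knn_graph"), m >= 1L)
  W <- graph$adjacency
  ids <- graph$node_ids
  if (is.null(ids)) ids <- as.character(seq_len(graph$n_nodes))
  dropped_ids <- character(0)
  if (graph$n_components > 1L) {
    sizes <- tabulate(graph$component_membership)
    frac <- max(sizes) / graph$n_nodes
    if (frac < min_component_frac && !largest_component_only) {
      stop(sprintf(
        "graph is disconnected (%d components; largest covers %.1f%% < %.1f%%)",
        graph$n_components, 100 * frac, 100 * min_component_frac))
    }
    keep <- graph$component_membership == which.max(sizes)
    dropped_ids <- ids[!keep]
    W <- W[keep, keep, drop = FALSE]
    ids <- ids[keep]
  }
  e <- laplacian_eigen(W, normalization)
  trivial <- e$values < 1e-10
  n_trivial <- sum(trivial)
  first <- if (include_trivial) 1L else n_trivial + 1L
  last <- first + m - 1L
  if (last > length(e$values)) {
    stop("m exceeds the available nontrivial spectrum")
  }
  coords <- e$vectors[, first:last, drop = FALSE]
  rownames(coords) <- ids
  colnames(coords) <- paste0("phi", seq_len(m))
  structure(list(coordinates = coords,
                 eigenvalues = e$values[first:last],
                 dropped_trivial = if (include_trivial) 0L else n_trivial,
                 gene_ids = ids,
                 dropped_gene_ids = dropped_ids,
                 normalization = normalization),
            class = "eigenmap_embedding")
}
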