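test_that("whitened data give Euclidean distances; closed-form toy metric", {
  # identity covariance: Mahalanobis == Euclidean
  set.seed(10)
  x <- matrix(rnorm(100), 20, 5)
  metric <- structure(list(covariance = diag(5), inverse = diag(5),
                           shrinkage = 0), class = "metric_model")
  expect_equal(pairwise_mahalanobis(x, metric),
               unname(as.matrix(dist(x))), tolerance = 1e-10,
               ignore_attr = TRUE)

  # covariance diag(2, 0.5): d((1,0), (0,0)) = 1/sqrt(2)
  metric2 <- structure(list(covariance = diag(c(2, 0.5)),
                            inverse = diag(c(0.5, 2)), shrinkage = 0),
                       class = "metric_model")
  pts <- rbind(c(1, 0), c(0, 0))
  expect_equal(pairwise_mahalanobis(pts, metric2)[1, 2], 1 / sqrt(2),
               tolerance = 1e-12)
})

test_that("estimated metric reproduces distances after explicit whitening", {
  set.seed(11)
  x <- matrix(rnorm(250), 50, 5) %*% matrix(runif(25, -1, 1), 5, 5)
  metric <- estimate_metric(x)
  D <- pairwise_mahalanobis(x, metric)
  # oracle: whiten with S^{-1/2} and take plain Euclidean distances
  S <- cov(x)
  e <- eigen(S, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  D_oracle <- as.matrix(dist(x %*% W))
  expect_equal(D, D_oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(diag(D), rep(0, 50), ignore_attr = TRUE)
  expect_equal(D, t(D), tolerance = 1e-12)
})

test_that("Mahalanobis distances are invariant under invertible transforms", {
  set.seed(12)
  x <- matrix(rnorm(300), 60, 5)
  A <- matrix(rnorm(25), 5, 5) + 5 * diag(5)   # well-conditioned
  D1 <- pairwise_mahalanobis(x, estimate_metric(x))
  D2 <- pairwise_mahalanobis(x %*% A, estimate_metric(x %*% A))
  expect_lt(max(abs(D1 - D2)), 1e-8)
})

test_that("elementwise scalar oracle reproduces the distance matrix", {
  set.seed(13)
  x <- matrix(rnorm(40), 10, 4)
  metric <- estimate_metric(x, shrinkage = 0.2)
  D <- pairwise_mahalanobis(x, metric)
  for (i in 1:10) {
    for (j in 1:10) {
      d <- x[i, ] - x[j, ]
      expect_equal(D[i, j], sqrt(drop(t(d) %*% metric$inverse %*% d)),
                   tolerance = 1e-10)
    }
  }
})

test_that("kNN graph matches a brute-force oracle and keeps degree >= k", {
  # 3 nodes in a chain with k = 1
  D <- as.matrix(dist(matrix(c(0, 1.1, 2), 3, 1)))
  g <- build_knn_graph(D, 1)
  A <- as.matrix(g$adjacency)
  expect_equal(A, rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
               ignore_attr = TRUE)

  set.seed(14)
  pts <- matrix(rnorm(60), 30, 2)
  D2 <- as.matrix(dist(pts))
  g2 <- build_knn_graph(D2, 5)
  A2 <- as.matrix(g2$adjacency) > 0
  # brute-force: per node take 5 smallest distances (ties by index)
  oracle <- matrix(FALSE, 30, 30)
  for (i in 1:30) {
    d <- D2[i, ]
    d[i] <- Inf
    nn <- order(d, seq_len(30))[1:5]
    oracle[i, nn] <- TRUE
  }
  oracle <- oracle | t(oracle)
  expect_equal(unname(A2), oracle)
  expect_true(all(Matrix::rowSums(g2$adjacency) >= 5))
  expect_error(build_knn_graph(D2, 30), "smaller")
})

test_that("Laplacian spectrum counts components; K4 eigenvalues are 4/3", {
  # two disjoint triangles -> exactly two (near-)zero eigenvalues
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1 - diag(3)
  A[4:6, 4:6] <- 1 - diag(3)
  g <- structure(list(adjacency = Matrix::Matrix(A, sparse = TRUE),
                      k = 2L, n_nodes = 6L, n_components = 2L,
                      component_membership = rep(1:2, each = 3),
                      node_ids = letters[1:6]), class = "knn_graph")
  ev <- laplacian_spectrum(g)
  expect_equal(sum(ev < 1e-10), 2)

  # complete graph K4: all nontrivial generalized eigenvalues are 4/3
  K4 <- Matrix::Matrix(1 - diag(4), sparse = TRUE)
  g4 <- structure(list(adjacency = K4, k = 3L, n_nodes = 4L,
                       n_components = 1L, component_membership = rep(1L, 4),
                       node_ids = as.character(1:4)), class = "knn_graph")
  ev4 <- laplacian_spectrum(g4)
  expect_equal(ev4, c(0, 4 / 3, 4 / 3, 4 / 3), tolerance = 1e-12)

  # disconnected graph rejected unless restricted to largest component
  expect_error(laplacian_embedding(g, m = 2), "disconnected")
  emb <- laplacian_embedding(g, m = 2, largest_component_only = TRUE)
  expect_equal(nrow(emb$coordinates), 3)
  expect_equal(emb$dropped_gene_ids, letters[4:6])
})

test_that("dumbbell embedding separates the two lobes by Fiedler sign", {
  # two K5 blobs joined by one edge
  A <- matrix(0, 10, 10)
  A[1:5, 1:5] <- 1 - diag(5)
  A[6:10, 6:10] <- 1 - diag(5)
  A[5, 6] <- A[6, 5] <- 1
  g <- structure(list(adjacency = Matrix::Matrix(A, sparse = TRUE),
                      k = 4L, n_nodes = 10L, n_components = 1L,
                      component_membership = rep(1L, 10),
                      node_ids = as.character(1:10)), class = "knn_graph")
  emb <- laplacian_embedding(g, m = 2)
  fiedler <- emb$coordinates[, 1]
  expect_equal(length(unique(sign(fiedler[1:5]))), 1)
  expect_equal(length(unique(sign(fiedler[6:10]))), 1)
  expect_true(sign(fiedler[1]) != sign(fiedler[10]))
  expect_equal(emb$dropped_trivial, 1L)
  # eigenvalues ascending, coordinates D-orthonormal
  expect_true(all(diff(emb$eigenvalues) >= -1e-12))
  d <- rowSums(A)
  gram <- t(emb$coordinates * d) %*% emb$coordinates
  expect_equal(gram, diag(2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("geometric median handles symmetry and matches a grid oracle", {
  expect_equal(geometric_median(matrix(c(3, 4), 1, 2))$median, c(3, 4),
               ignore_attr = TRUE)
  cross <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(geometric_median(cross)$median, c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)

  grid_oracle <- function(pts) {
    obj <- function(y) sum(sqrt((pts[, 1] - y[1])^2 + (pts[, 2] - y[2])^2))
    lo <- apply(pts, 2, min)
    hi <- apply(pts, 2, max)
    centre <- (lo + hi) / 2
    span <- max(hi - lo)
    for (level in 1:8) {
      xs <- seq(centre[1] - span / 2, centre[1] + span / 2, length.out = 41)
      ys <- seq(centre[2] - span / 2, centre[2] + span / 2, length.out = 41)
      gr <- expand.grid(x = xs, y = ys)
      vals <- apply(gr, 1, obj)
      centre <- as.numeric(gr[which.min(vals), ])
      span <- span / 8
    }
    obj(centre)
  }
  set.seed(15)
  for (rep in 1:10) {
    pts <- matrix(rnorm(14, sd = 2), 7, 2)
    gm <- geometric_median(pts)
    expect_lt(abs(gm$objective - grid_oracle(pts)), 1e-6)
    # objective never increases across Weiszfeld iterations
    expect_true(all(diff(gm$objective_trace) <= 1e-12))
    # no worse than the coordinate-wise mean
    mean_obj <- sum(sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2)))
    expect_lte(gm$objective, mean_obj + 1e-12)
  }

  # iterate landing on a data point: subgradient correction still converges
  spike <- rbind(c(0, 0), c(0, 0), c(0, 0), c(10, 0))
  gm2 <- geometric_median(spike)
  expect_equal(gm2$median, c(0, 0), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("standardized distances skip degenerate dimensions", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 1), c(2, 2))
  med <- c(1, 1)
  s <- apply(pts, 2, sd)
  expected <- sqrt(((pts[, 1] - 1) / s[1])^2 + ((pts[, 2] - 1) / s[2])^2)
  expect_equal(unname(distance_to_median(pts, med)), expected,
               tolerance = 1e-12)
  expect_equal(distance_to_median(rbind(med, pts), med)[[1]], 0)

  # unit-sd dimensions reduce to plain Euclidean distance
  z <- scale(matrix(rnorm(40), 10, 4))
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  z <- matrix(as.numeric(z), 10, 4)
  expect_equal(unname(distance_to_median(z, rep(0, 4))),
               sqrt(rowSums(z^2)), tolerance = 1e-12)

  pts_deg <- cbind(c(1, 2, 3), c(7, 7, 7))
  expect_warning(d <- distance_to_median(pts_deg, c(2, 7)), "skipped")
  expect_equal(unname(d), abs(c(1, 2, 3) - 2), tolerance = 1e-12)
  expect_error(distance_to_median(matrix(1, 3, 2), c(1, 1)), "degenerate")
})

test_that("exact 1-D 2-means equals exhaustive sorted-split enumeration", {
  sp <- split_proximal_distal(c(a = 1, b = 1, c = 1, d = 9, e = 9))
  expect_equal(as.character(sp$labels),
               c("proximal", "proximal", "proximal", "distal", "distal"))

  # order invariance
  x <- c(5, 1, 9, 2, 7)
  l1 <- split_proximal_distal(x)$labels
  l2 <- split_proximal_distal(rev(x))$labels
  expect_equal(as.character(l1), rev(as.character(l2)))

  set.seed(16)
  for (rep in 1:20) {
    d <- runif(20, 0, 10)
    sp <- split_proximal_distal(d)
    # exhaustive oracle over all contiguous sorted 2-partitions
    xs <- sort(d)
    best_wss <- Inf
    best_cut <- NA
    for (cut in 1:19) {
      left <- xs[1:cut]
      right <- xs[(cut + 1):20]
      wss <- sum((left - mean(left))^2) + sum((right - mean(right))^2)
      if (wss < best_wss) {
        best_wss <- wss
        best_cut <- cut
      }
    }
    expect_equal(sum(sp$labels == "proximal"), best_cut)
    expect_equal(sp$within_ss, best_wss, tolerance = 1e-10)
    expect_lt(sp$means[["proximal"]], sp$means[["distal"]])
  }
  expect_error(split_proximal_distal(rep(3, 5)), "identical")
})
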