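# Geometric median of the embedded genes, standardized distances to it, and
# the exact 1-D 2-means split into proximal (uninformative) and distal genes.

#' Geometric median by Weiszfeld iteration
#'
#' Minimizes the sum of Euclidean distances to the rows of `points`.  When
#' an iterate coincides with a data point the standard subgradient
#' (Vardi-Zhang) correction is applied.  The objective is checked to be
#' non-increasing at every step.
#'
#' @param points numeric matrix (points x dimensions).
#' @param tol stop when the iterate moves less than `tol` (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return list with `median` (numeric vector), `objective`, `iterations`
#'   and `objective_trace`.
#' @export
geometric_median <- function(points, tol = 1e-10, max_iter = 1000L) {
  stopifnot(is.matrix(points), nrow(points) >= 1L)
  if (nrow(points) == 1L) {
    return(list(median = points[1L, ], objective = 0, iterations = 0L,
                objective_trace = 0))
  }
  objective <- function(y) {
    sum(sqrt(rowSums(sweep(points, 2, y)^2)))
  }
  y <- colMeans(points)
  trace <- objective(y)
  for (it in seq_len(max_iter)) {
    diffs <- sweep(points, 2, y)
    d <- sqrt(rowSums(diffs^2))
    coincident <- d < 1e-12
    if (any(coincident)) {
      # Subgradient correction at a data point.
      others <- !coincident
      if (!any(others)) break
      inv <- 1 / d[others]
      T_tilde <- colSums(points[others, , drop = FALSE] * inv) / sum(inv)
      R <- colSums(diffs[others, , drop = FALSE] / d[others])
      r <- sqrt(sum(R^2))
      eta <- sum(coincident)
      if (r <= eta) break  # current point is the geometric median
      step <- min(1, eta / r)
      y_new <- (1 - step) * T_tilde + step * y
    } else {
      inv <- 1 / d
      y_new <- colSums(points * inv) / sum(inv)
    }
    obj_new <- objective(y_new)
    if (obj_new > trace[length(trace)] + 1e-9 * (1 + abs(obj_new))) {
      stop("Weiszfeld objective increased; numerical failure")
    }
    trace <- c(trace, obj_new)
    moved <- sqrt(sum((y_new - y)^2))
    y <- y_new
    if (moved < tol) break
  }
  list(median = y, objective = trace[length(trace)], iterations = length(trace) - 1L,
       objective_trace = trace)
}

#' Standardized Euclidean distance of each point to a centre
#'
#' Each dimension is scaled by its sample standard deviation across points
#' before computing the Euclidean distance; zero-variance dimensions are
#' skipped with a warning.
#'
#' @param points numeric matrix (points x dimensions).
#' @param centre numeric vector (the geometric median).
#' @return named numeric vector of non-negative distances.
#' @export
distance_to_median <- function(points, centre) {
  stopifnot(is.matrix(points), length(centre) == ncol(points))
  s <- apply(points, 2, sd)
  degenerate <- s == 0 | !is.finite(s)
  if (all(degenerate)) stop("all dimensions are degenerate")
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance dimension(s) skipped")
  }
  keep <- !degenerate
  z <- sweep(points[, keep, drop = FALSE], 2, centre[keep]) /
    rep(s[keep], each = nrow(points))
  d <- sqrt(rowSums(z^2))
  names(d) <- rownames(points)
  d
}

#' Exact 1-D 2-means split of distances into proximal and distal genes
#'
#' The optimal 2-means clustering of scalars is a contiguous split of the
#' sorted values; all `n - 1` split points are enumerated and the one
#' minimizing the within-cluster sum of squares is chosen (deterministic,
#' globally optimal).  The cluster with the smaller mean is labelled
#' `proximal`.
#'
#' @param distances numeric vector (typically from [distance_to_median()]).
#' @return a `median_split` list with `labels` (factor `proximal`/`distal`,
#'   named like `distances`), `threshold` (midpoint between the two sides of
#'   the optimal split), `means` and `within_ss`.
#' @export
split_proximal_distal <- function(distances) {
  n <- length(distances)
  stopifnot(n >= 2L)
  if (length(unique(distances)) < 2L) {
    stop("all distances are identical; no proximal/distal split exists")
  }
  ord <- order(distances)
  x <- distances[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  total <- cs[n]
  total2 <- cs2[n]
  i <- seq_len(n - 1L)
  wss_left <- cs2[i] - cs[i]^2 / i
  wss_right <- (total2 - cs2[i]) - (total - cs[i])^2 / (n - i)
  wss <- wss_left + wss_right
  best <- which.min(wss)   # first minimum -> deterministic tie-break
  labels <- rep("distal", n)
  labels[ord[seq_len(best)]] <- "proximal"
  labels <- factor(labels, levels = c("proximal", "distal"))
  names(labels) <- names(distances)
  mean_prox <- cs[best] / best
  mean_dist <- (total - cs[best]) / (n - best)
  structure(list(labels = labels,
                 threshold = (x[best] + x[best + 1L]) / 2,
                 means = c(proximal = mean_prox, distal = mean_dist),
                 within_ss = wss[best]),
            class = "median_split")
}
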