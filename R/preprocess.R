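# Normalization and gene filtering: median-of-ratios size factors, the two
# pooled-25%-quantile filters, row z-scoring and hierarchical clustering.

#' Median-of-ratios size factors
#'
#' The classic bulk RNA-seq estimator: a pseudo-reference per gene is the
#' geometric mean of its counts across samples, computed over genes with
#' strictly positive counts in every sample; each sample's size factor is
#' the median over those genes of the count-to-reference ratio.
#'
#' @param em an [expression_matrix()] of raw counts.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
compute_size_factors <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$flavor != "raw_counts") stop("size factors expect raw counts")
  counts <- em$values
  all_pos <- rowSums(counts <= 0) == 0
  if (!any(all_pos)) {
    stop("no gene has strictly positive counts in every sample; ",
         "median-of-ratios size factors are undefined")
  }
  ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
  ratios <- counts[all_pos, , drop = FALSE] / ref
  apply(ratios, 2, median)
}

#' Divide counts by per-sample size factors
#'
#' @param em an [expression_matrix()] of raw counts.
#' @param factors positive size factors, one per sample (in column order).
#' @return an [expression_matrix()] with flavor `"normalized"`.
#' @export
normalize_counts <- function(em, factors = compute_size_factors(em)) {
  stopifnot(inherits(em, "expression_matrix"))
  if (length(factors) != ncol(em$values)) {
    stop("need one size factor per sample")
  }
  if (any(factors <= 0)) stop("size factors must be positive")
  vals <- sweep(em$values, 2, factors, "/")
  expression_matrix(vals, em$metadata, "normalized")
}

#' Remove genes whose values all fall in the lowest quartile of the data
#'
#' The threshold is the pooled `q`-quantile of all matrix entries
#' (linear-interpolation type-7 quantile); a gene is removed iff every one
#' of its values is `<=` the threshold.
#'
#' @param em a normalized [expression_matrix()].
#' @param q pooled quantile defining "low" (default 0.25).
#' @return list with `matrix` (survivors), `removed` (gene IDs) and
#'   `threshold`.
#' @export
filter_all_low <- function(em, q = 0.25) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$flavor != "normalized") stop("filter expects a normalized matrix")
  if (nrow(em$values) == 0L) stop("empty matrix")
  threshold <- quantile(as.vector(em$values), q, type = 7, names = FALSE)
  low <- rowSums(em$values > threshold) == 0
  if (all(low)) {
    warning("all genes fall entirely below the pooled quantile; ",
            "all genes removed")
  }
  list(matrix = subset_genes(em, !low),
       removed = gene_ids(em)[low],
       threshold = threshold)
}

#' Remove genes in the lowest quartile of per-gene variance
#'
#' Per-gene sample variance (denominator `n - 1`); the threshold is the
#' `q`-quantile of the variance vector; a gene is removed iff its variance
#' is `<=` the threshold.  Intended to run after [filter_all_low()].
#'
#' @param em a normalized [expression_matrix()] with at least 2 samples.
#' @param q variance quantile defining "low" (default 0.25).
#' @param log2_scale compute variances on `log2(x + 1)` values instead of
#'   linear values.
#' @return list with `matrix`, `removed`, `threshold` and `variances`.
#' @export
filter_low_variance <- function(em, q = 0.25, log2_scale = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$flavor != "normalized") stop("filter expects a normalized matrix")
  if (ncol(em$values) < 2L) stop("variance filter needs >= 2 samples")
  vals <- if (log2_scale) log2(em$values + 1) else em$values
  v <- apply(vals, 1, var)
  threshold <- quantile(v, q, type = 7, names = FALSE)
  low <- v <= threshold
  if (all(low)) {
    warning("all gene variances tie at the threshold; all genes removed")
  }
  list(matrix = subset_genes(em, !low),
       removed = gene_ids(em)[low],
       threshold = threshold,
       variances = v)
}

#' Z-score the rows of a matrix
#'
#' Each row is centred and scaled to unit standard deviation (denominator
#' `n - 1`).  Zero-variance rows become rows of zeros, with a warning.
#'
#' @param x numeric matrix (or an [expression_matrix()], whose values are
#'   used) with at least 2 columns.
#' @return numeric matrix of the same shape.
#' @export
zscore_rows <- function(x) {
  if (inherits(x, "expression_matrix")) x <- x$values
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  degenerate <- s == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance row(s) set to zero")
    s[degenerate] <- 1
  }
  (x - mu) / s
}

#' Agglomerative hierarchical clustering of matrix rows
#'
#' Euclidean distance with single ("nearest distance") linkage by default,
#' the convention used for the expression heat maps; Ward's method
#' (`ward.D2`) is available for the marker heat-map convention.
#'
#' @param x numeric matrix; rows are clustered.
#' @param linkage `"single"` or `"ward"`.
#' @return list with the `hclust` object, the `merge` matrix, `height`
#'   vector and leaf `order`.
#' @export
hierarchical_cluster <- function(x, linkage = c("single", "ward")) {
  linkage <- match.arg(linkage)
  if (inherits(x, "expression_matrix")) x <- x$values
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (any(!is.finite(x))) stop("input contains non-finite values")
  method <- if (linkage == "single") "single" else "ward.D2"
  hc <- hclust(dist(x, method = "euclidean"), method = method)
  list(hclust = hc, merge = hc$merge, height = hc$height, order = hc$order,
       labels = hc$labels)
}

#' Export a dendrogram as a Newick tree
#'
#' @param hc an `hclust` object (or the list returned by
#'   [hierarchical_cluster()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  if (is.list(hc) && !inherits(hc, "hclust")) hc <- hc$hclust
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
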