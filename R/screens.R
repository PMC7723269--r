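# Correlation screens downstream of module assignment: gene-wise BATness
# correlations per module, the paired pre/differentiated stability screen,
# marker correlation panels and k-means grouping of the BATness scatter.

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson `r` with the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom;
#' `|r| = 1` gives `p = 0`.  Zero-variance inputs are flagged degenerate
#' (`r` and `p` are `NA`).
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `r`, `p`, `n` and `degenerate`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- min(max(cor(x, y), -1), 1)
  list(r = r, p = pearson_p_value(r, n), n = n, degenerate = FALSE)
}

# Align an expression matrix's samples with a BATness state: returns the
# expression columns (clone-ordered) and matching score vector.
align_batness <- function(em, batness, state) {
  validate_batness(batness)
  if (is.null(em$metadata)) stop("expression matrix has no sample metadata")
  bat <- batness[batness$state == state, , drop = FALSE]
  clones <- intersect(em$metadata$clone_id, bat$clone_id)
  if (!length(clones)) stop("no overlapping clones between expression and BATness")
  cols <- match(clones, em$metadata$clone_id)
  scores <- bat$score[match(clones, bat$clone_id)]
  list(values = em$values[, cols, drop = FALSE], scores = scores,
       clones = clones)
}

#' Gene-wise correlation to BATness, per module
#'
#' For every module gene, the Pearson correlation across clones between the
#' gene's expression and the BATness score of the requested state.  The
#' three comparisons mirror the standard report: preadipocyte expression vs
#' preadipocyte BATness, preadipocyte expression vs differentiated BATness,
#' and differentiated expression vs differentiated BATness (which one you
#' get depends on the matrix and `batness_state` you pass).
#'
#' @param em a normalized [expression_matrix()] for one state.
#' @param module_labels named character vector mapping gene IDs to module
#'   names (genes absent from `em` are ignored).
#' @param batness BATness table (`clone_id`, `state`, `score`).
#' @param batness_state which state's scores to correlate against.
#' @param log2_scale correlate on `log2(x + 1)` expression values.
#' @param n_bins histogram bins over `[-1, 1]` for the per-module summary.
#' @return list with `per_gene` (gene_id, module, r, p, degenerate),
#'   `per_module` (module, n, n_degenerate, mean_r) and `bins` (per-module
#'   histogram counts over `n_bins` equal-width bins on `[-1, 1]`).
#' @export
correlate_module_to_batness <- function(em, module_labels, batness,
                                        batness_state = c("preadipocyte",
                                                          "adipocyte"),
                                        log2_scale = FALSE, n_bins = 20L) {
  batness_state <- match.arg(batness_state)
  al <- align_batness(em, batness, batness_state)
  genes <- intersect(names(module_labels), rownames(al$values))
  if (!length(genes)) stop("no module genes present in the matrix")
  X <- al$values[genes, , drop = FALSE]
  if (log2_scale) X <- log2(X + 1)
  Y <- matrix(al$scores, length(genes), length(al$scores), byrow = TRUE)
  r <- row_pearson(X, Y)
  p <- pearson_p_value(r, ncol(X))
  per_gene <- data.frame(gene_id = genes,
                         module = unname(module_labels[genes]),
                         r = r, p = p, degenerate = is.na(r),
                         stringsAsFactors = FALSE)
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  mods <- sort(unique(per_gene$module))
  per_module <- do.call(rbind, lapply(mods, function(m) {
    rs <- per_gene$r[per_gene$module == m]
    data.frame(module = m, n = length(rs), n_degenerate = sum(is.na(rs)),
               mean_r = mean(rs, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  bins <- vapply(mods, function(m) {
    rs <- per_gene$r[per_gene$module == m]
    rs <- rs[!is.na(rs)]
    tabulate(findInterval(rs, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = n_bins)
  }, integer(n_bins))
  colnames(bins) <- mods
  list(per_gene = per_gene, per_module = per_module, bins = bins,
       breaks = breaks, batness_state = batness_state)
}

#' Paired pre/differentiated stability screen
#'
#' For each candidate gene, the Pearson correlation across clones between
#' its preadipocyte profile and its differentiated profile.  A gene is
#' selected ("stable") iff the two-sided `p < alpha` and, by default, the
#' correlation is positive -- stability means the clone ranking is
#' preserved, not inverted.
#'
#' @param pre,diff normalized [expression_matrix()] objects with identical
#'   clone sets (paired design).
#' @param module_genes gene IDs to screen (typically the distal module
#'   genes); must be present in both matrices.
#' @param alpha significance threshold (default 0.05, unadjusted).
#' @param require_positive require `r > 0` for selection (default `TRUE`).
#' @param log2_scale correlate on `log2(x + 1)` values.
#' @return a `stable_gene_set` list with `table` (gene_id, r, p, selected,
#'   degenerate), `selected_ids` and the selection `rule`.
#' @export
stable_gene_screen <- function(pre, diff, module_genes, alpha = 0.05,
                               require_positive = TRUE, log2_scale = FALSE) {
  if (is.null(pre$metadata) || is.null(diff$metadata)) {
    stop("both matrices need sample metadata for pairing")
  }
  if (!length(module_genes)) stop("empty module gene list")
  clones <- pre$metadata$clone_id
  if (!setequal(clones, diff$metadata$clone_id)) {
    stop("unpaired design: clone sets differ between states")
  }
  genes <- intersect(module_genes, intersect(rownames(pre$values),
                                             rownames(diff$values)))
  if (!length(genes)) stop("none of the requested genes are in both matrices")
  X <- pre$values[genes, order(pre$metadata$clone_id), drop = FALSE]
  Y <- diff$values[genes, order(diff$metadata$clone_id), drop = FALSE]
  if (log2_scale) {
    X <- log2(X + 1)
    Y <- log2(Y + 1)
  }
  r <- row_pearson(X, Y)
  p <- pearson_p_value(r, ncol(X))
  selected <- !is.na(p) & p < alpha & (!require_positive | r > 0)
  tab <- data.frame(gene_id = genes, r = r, p = p, selected = selected,
                    degenerate = is.na(r), stringsAsFactors = FALSE)
  structure(list(table = tab,
                 selected_ids = genes[selected],
                 rule = list(alpha = alpha,
                             require_positive = require_positive),
                 n_input = length(genes),
                 n_selected = sum(selected),
                 n_degenerate = sum(is.na(r))),
            class = "stable_gene_set")
}

#' Pairwise marker-versus-target correlation panel
#'
#' All marker x target Pearson correlations with two-sided p-values and a
#' significance flag at `alpha` (unadjusted).
#'
#' @param em a normalized [expression_matrix()].
#' @param marker_ids,target_ids gene IDs present in `em`.
#' @param alpha significance threshold for the flag (default 0.05).
#' @param log2_scale correlate on `log2(x + 1)` values.
#' @return data.frame with `marker`, `target`, `r`, `p`, `significant`.
#' @export
marker_correlation_panel <- function(em, marker_ids, target_ids,
                                     alpha = 0.05, log2_scale = FALSE) {
  missing <- setdiff(c(marker_ids, target_ids), rownames(em$values))
  if (length(missing)) {
    stop("gene ID(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  vals <- em$values
  if (log2_scale) vals <- log2(vals + 1)
  grid <- expand.grid(marker = marker_ids, target = target_ids,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pearson_with_p(vals[grid$marker[i], ], vals[grid$target[i], ])
  })
  grid$r <- vapply(res, `[[`, numeric(1), "r")
  grid$p <- vapply(res, `[[`, numeric(1), "p")
  grid$significant <- !is.na(grid$p) & grid$p < alpha
  grid
}

#' k-means grouping of the pre/differentiated BATness scatter
#'
#' Clusters the clones on the 2-D points (preadipocyte BATness,
#' differentiated BATness); cluster labels are integers `1..k` ordered by
#' ascending mean differentiated-state BATness, so label 1 is the least
#' differentiated-brown group.
#'
#' @param batness BATness table with both states for every clone.
#' @param k number of clusters (default 3).
#' @param n_init k-means restarts (default 25).
#' @param seed RNG seed.
#' @return data.frame with `clone_id`, `pre`, `diff`, `cluster`.
#' @export
kmeans_batness_scatter <- function(batness, k = 3L, n_init = 25L, seed = 1L) {
  validate_batness(batness)
  pre <- batness[batness$state == "preadipocyte", ]
  dif <- batness[batness$state == "adipocyte", ]
  clones <- intersect(pre$clone_id, dif$clone_id)
  if (!setequal(pre$clone_id, dif$clone_id)) {
    stop("every clone needs a score in both states")
  }
  if (k > length(clones)) stop("k exceeds the number of clones")
  pts <- cbind(pre = pre$score[match(clones, pre$clone_id)],
               diff = dif$score[match(clones, dif$clone_id)])
  rownames(pts) <- clones
  fit <- with_seed(stage_seed(seed, "batscatter"), {
    fit_kmeans(pts, k, n_init)
  })
  mean_diff <- vapply(seq_len(k),
                      function(cl) mean(pts[fit$cluster == cl, "diff"]),
                      numeric(1))
  relabel <- integer(k)
  relabel[order(mean_diff)] <- seq_len(k)
  data.frame(clone_id = clones, pre = pts[, "pre"], diff = pts[, "diff"],
             cluster = relabel[fit$cluster], stringsAsFactors = FALSE,
             row.names = NULL)
}
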