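# End-to-end orchestration: normalize -> filter -> embed -> split ->
# modules -> screens -> enrichment, with deterministic seeding and a run
# record of configuration, stage timings and output checksums.

#' Pipeline configuration
#'
#' Defaults reproduce the reference settings of the analysis: `k = 23`
#' nearest neighbours, the first 8 nontrivial Laplacian eigenvectors,
#' silhouette scan over `k = 2..15`, and unadjusted `P < 0.05` screens.
#'
#' @param k_neighbors kNN graph degree parameter.
#' @param n_eigenvectors embedding dimensions.
#' @param k_range candidate module counts for the silhouette scan.
#' @param alpha significance threshold for the screens.
#' @param require_positive require positive correlation in the stability
#'   screen.
#' @param n_init k-means restarts.
#' @param seed global seed, expanded into independent per-stage streams.
#' @param quantile pooled/variance quantile used by the two gene filters.
#' @param shrinkage covariance shrinkage intensity for the Mahalanobis
#'   metric.
#' @param include_trivial count the trivial constant eigenvector among the
#'   embedding coordinates.
#' @param affinity kNN edge weighting, `"binary"` or `"heat"`.
#' @param log_transform embed `log2(x + 1)` expression values.
#' @param zscore_genes row-standardize genes before the embedding.  Off by
#'   default: the gene amplitude carries the signal that separates
#'   structured from unstructured genes at the proximal/distal split.
#' @param silhouette_space space in which the silhouette that guides the
#'   choice of k is evaluated: `"expression"` (default; the
#'   Mahalanobis-distance gene space the graph was built from, so the
#'   chosen k reflects co-expression structure) or `"embedding"`.
#' @param batness_k clusters for the BATness scatter grouping.
#' @param min_component_frac tolerated size of the largest graph component.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(k_neighbors = 23L, n_eigenvectors = 8L,
                            k_range = 2:15, alpha = 0.05,
                            require_positive = TRUE, n_init = 25L,
                            seed = 1L, quantile = 0.25, shrinkage = 0,
                            include_trivial = FALSE,
                            affinity = c("binary", "heat"),
                            log_transform = TRUE, zscore_genes = FALSE,
                            silhouette_space = c("expression", "embedding"),
                            batness_k = 3L, min_component_frac = 0.95) {
  affinity <- match.arg(affinity)
  silhouette_space <- match.arg(silhouette_space)
  stopifnot(k_neighbors >= 1L, n_eigenvectors >= 1L, length(k_range) >= 1L,
            alpha > 0, alpha < 1, n_init >= 1L,
            quantile > 0, quantile < 1, shrinkage >= 0, shrinkage <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 n_eigenvectors = as.integer(n_eigenvectors),
                 k_range = as.integer(k_range), alpha = alpha,
                 require_positive = require_positive,
                 n_init = as.integer(n_init), seed = as.integer(seed),
                 quantile = quantile, shrinkage = shrinkage,
                 include_trivial = include_trivial, affinity = affinity,
                 log_transform = log_transform, zscore_genes = zscore_genes,
                 silhouette_space = silhouette_space,
                 batness_k = as.integer(batness_k),
                 min_component_frac = min_component_frac),
            class = "pipeline_config")
}

# The gene-space coordinates fed to the embedding.
embedding_input <- function(em, config) {
  vals <- em$values
  if (config$log_transform) vals <- log2(vals + 1)
  if (config$zscore_genes) vals <- suppressWarnings(zscore_rows(vals))
  vals
}

#' Run the full module-discovery pipeline
#'
#' Stages, in order: median-of-ratios normalization and the two quantile
#' gene filters (independently per state); Laplacian-eigenmap embedding of
#' the preadipocyte genes on a Mahalanobis kNN graph; geometric-median
#' proximal/distal split; silhouette-guided k-means module assignment of
#' the distal genes; BATness correlation screens, the paired stability
#' screen and the BATness-scatter grouping; and, when `gene_sets` is given,
#' hypergeometric enrichment.  Identical inputs, config and seed give
#' identical results.
#'
#' @param counts_pre,counts_diff raw-count [expression_matrix()] objects for
#'   the preadipocyte and differentiated state (paired clones).
#' @param batness BATness table (`clone_id`, `state`, `score`).
#' @param gene_sets optional gene-set collection (named list) for
#'   enrichment.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, every stage's tables
#'   are written as TSV plus a `run_record.json`.
#' @param truth_labels optional named vector of planted module labels; when
#'   given, the adjusted Rand index of the recovered distal-gene modules is
#'   recorded in the run record.
#' @return a `pipeline_result` list; see the elements written by each stage
#'   (`normalized`, `filtered`, `embedding`, `median_split`, `modules`,
#'   `screens`, `enrichment`, `run_record`).
#' @export
run_pipeline <- function(counts_pre, counts_diff, batness, gene_sets = NULL,
                         config = pipeline_config(), output_dir = NULL,
                         truth_labels = NULL) {
  stopifnot(inherits(counts_pre, "expression_matrix"),
            inherits(counts_diff, "expression_matrix"),
            inherits(config, "pipeline_config"))
  validate_batness(batness)
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  # -- preprocess (independently per state) --
  prep <- clock("preprocess", {
    lapply(list(pre = counts_pre, diff = counts_diff), function(em) {
      sf <- compute_size_factors(em)
      norm <- normalize_counts(em, sf)
      f1 <- filter_all_low(norm, config$quantile)
      f2 <- filter_low_variance(f1$matrix, config$quantile)
      list(size_factors = sf, normalized = norm, filtered = f2$matrix,
           removed_all_low = f1$removed, removed_low_var = f2$removed)
    })
  })

  # -- embedding of the preadipocyte genes --
  embedding <- clock("embed", {
    x <- embedding_input(prep$pre$filtered, config)
    metric <- estimate_metric(x, config$shrinkage)
    D <- pairwise_mahalanobis(x, metric)
    graph <- build_knn_graph(D, config$k_neighbors, config$affinity)
    emb <- laplacian_embedding(graph, config$n_eigenvectors,
                               include_trivial = config$include_trivial,
                               min_component_frac = config$min_component_frac)
    list(embedding = emb, graph_components = graph$n_components,
         gene_distances = D)
  })

  # -- proximal/distal split --
  split <- clock("split", {
    med <- geometric_median(embedding$embedding$coordinates)
    dists <- distance_to_median(embedding$embedding$coordinates, med$median)
    sp <- split_proximal_distal(dists)
    list(median = med, distances = dists, split = sp)
  })
  distal_ids <- names(split$split$labels)[split$split$labels == "distal"]

  # -- module assignment --
  modules <- clock("modules", {
    pts <- embedding$embedding$coordinates[distal_ids, , drop = FALSE]
    sil_dist <- if (config$silhouette_space == "expression") {
      embedding$gene_distances[distal_ids, distal_ids, drop = FALSE]
    } else {
      NULL
    }
    scan <- select_k_by_silhouette(pts, config$k_range, config$n_init,
                                   stage_seed(config$seed, "kselect"),
                                   dist_matrix = sil_dist)
    assignment <- assign_modules(pts, scan$chosen_k, config$n_init,
                                 stage_seed(config$seed, "modules"))
    list(scan = scan, assignment = assignment)
  })
  embedding$gene_distances <- NULL
  module_labels <- modules$assignment$labels

  # -- screens --
  screens <- clock("screens", {
    bat_cor <- list(
      pre_vs_preBAT = correlate_module_to_batness(
        prep$pre$filtered, module_labels, batness, "preadipocyte"),
      pre_vs_diffBAT = correlate_module_to_batness(
        prep$pre$filtered, module_labels, batness, "adipocyte"),
      diff_vs_diffBAT = tryCatch(
        correlate_module_to_batness(
          prep$diff$filtered, module_labels, batness, "adipocyte"),
        error = function(e) NULL)
    )
    stable <- stable_gene_screen(prep$pre$filtered, prep$diff$filtered,
                                 intersect(names(module_labels),
                                           rownames(prep$diff$filtered$values)),
                                 config$alpha, config$require_positive)
    stable_bat <- if (length(stable$selected_ids)) {
      correlate_module_to_batness(prep$pre$filtered,
                                  module_labels[stable$selected_ids],
                                  batness, "preadipocyte")
    } else {
      NULL
    }
    scatter <- kmeans_batness_scatter(batness, config$batness_k,
                                      config$n_init,
                                      stage_seed(config$seed, "batscatter"))
    list(batness_correlation = bat_cor, stable = stable,
         stable_batness = stable_bat, batness_clusters = scatter)
  })

  # -- enrichment --
  enrichment <- if (!is.null(gene_sets)) {
    clock("enrich", {
      res <- enrich_modules(module_labels, gene_sets,
                            universe = gene_ids(prep$pre$filtered))
      network <- suppressWarnings(
        export_enrichment_network(res, config$alpha))
      list(results = res, network = network)
    })
  } else {
    NULL
  }

  run_record <- list(
    package_version = as.character(utils::packageVersion("batmodules")),
    seed = config$seed,
    config = unclass(config),
    chosen_k = modules$scan$chosen_k,
    n_genes_retained = c(pre = nrow(prep$pre$filtered$values),
                         diff = nrow(prep$diff$filtered$values)),
    n_proximal = sum(split$split$labels == "proximal"),
    n_distal = length(distal_ids),
    module_sizes = as.list(modules$assignment$sizes),
    n_stable = screens$stable$n_selected,
    timings = as.list(timings)
  )
  if (!is.null(truth_labels)) {
    common <- intersect(distal_ids, names(truth_labels))
    run_record$ari_distal <-
      adjusted_rand_index(module_labels[common], truth_labels[common])
  }

  result <- structure(list(
    normalized = list(pre = prep$pre$normalized, diff = prep$diff$normalized),
    size_factors = list(pre = prep$pre$size_factors,
                        diff = prep$diff$size_factors),
    filtered = list(pre = prep$pre$filtered, diff = prep$diff$filtered),
    removed = list(
      pre = list(all_low = prep$pre$removed_all_low,
                 low_variance = prep$pre$removed_low_var),
      diff = list(all_low = prep$diff$removed_all_low,
                  low_variance = prep$diff$removed_low_var)),
    embedding = embedding$embedding,
    median_split = split,
    modules = modules,
    screens = screens,
    enrichment = enrichment,
    run_record = run_record
  ), class = "pipeline_result")

  if (!is.null(output_dir)) {
    result$run_record <- write_result_bundle(result, output_dir)
  }
  result
}

# Writes the stage tables as TSV plus run_record.json; returns the run
# record augmented with per-file checksums.
write_result_bundle <- function(result, output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", output_dir)
  }
  emb <- result$embedding
  split <- result$median_split
  emb_tab <- data.frame(gene_id = rownames(emb$coordinates),
                        emb$coordinates,
                        distance = split$distances[rownames(emb$coordinates)],
                        label = as.character(
                          split$split$labels[rownames(emb$coordinates)]),
                        stringsAsFactors = FALSE, check.names = FALSE)
  module_tab <- data.frame(gene_id = names(result$modules$assignment$labels),
                           module = unname(result$modules$assignment$labels),
                           stringsAsFactors = FALSE)
  sil_tab <- data.frame(k = as.integer(names(result$modules$scan$silhouette_by_k)),
                        mean_silhouette = unname(result$modules$scan$silhouette_by_k))
  write_tsv(emb_tab, file.path(output_dir, "embedding.tsv"))
  write_tsv(module_tab, file.path(output_dir, "modules.tsv"))
  write_tsv(sil_tab, file.path(output_dir, "silhouette.tsv"))
  write_tsv(result$screens$stable$table,
            file.path(output_dir, "stable_genes.tsv"))
  write_tsv(result$screens$batness_clusters,
            file.path(output_dir, "batness_clusters.tsv"))
  for (cmp in names(result$screens$batness_correlation)) {
    res <- result$screens$batness_correlation[[cmp]]
    if (is.null(res)) next
    write_tsv(res$per_gene,
              file.path(output_dir, paste0("batness_cor_", cmp, ".tsv")))
  }
  if (!is.null(result$enrichment)) {
    write_tsv(result$enrichment$results,
              file.path(output_dir, "enrichment.tsv"))
    write_tsv(result$enrichment$network$nodes,
              file.path(output_dir, "enrichment_nodes.tsv"))
    write_tsv(result$enrichment$network$edges,
              file.path(output_dir, "enrichment_edges.tsv"))
  }
  files <- setdiff(list.files(output_dir), "run_record.json")
  checksums <- as.list(tools::md5sum(file.path(output_dir, files)))
  names(checksums) <- files
  record <- result$run_record
  record$checksums <- checksums
  jsonlite::write_json(record, file.path(output_dir, "run_record.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  record
}

#' @export
print.pipeline_result <- function(x, ...) {
  rec <- x$run_record
  cat("pipeline_result\n")
  cat(sprintf("  retained genes: pre = %d, diff = %d\n",
              rec$n_genes_retained[["pre"]], rec$n_genes_retained[["diff"]]))
  cat(sprintf("  proximal/distal: %d / %d\n", rec$n_proximal, rec$n_distal))
  cat(sprintf("  chosen k = %d; module sizes: %s\n", rec$chosen_k,
              paste(sprintf("%s=%d", names(rec$module_sizes),
                            unlist(rec$module_sizes)), collapse = ", ")))
  cat(sprintf("  stable genes: %d\n", rec$n_stable))
  invisible(x)
}
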