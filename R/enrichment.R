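# Hypergeometric over-representation of modules in gene-set collections,
# Benjamini-Hochberg adjustment and network export.

#' One-sided hypergeometric over-representation p-value
#'
#' `p = P(X >= overlap)` for `X ~ Hypergeometric(universe_size, set_size,
#' module_size)` -- the probability that a random draw of `module_size`
#' genes from the universe hits at least `overlap` members of the set.
#'
#' @param overlap observed number of module genes in the set.
#' @param module_size number of module genes in the universe.
#' @param set_size number of set genes in the universe.
#' @param universe_size number of genes in the universe.
#' @return p-value in `(0, 1]`.
#' @export
hypergeometric_test <- function(overlap, module_size, set_size,
                                universe_size) {
  if (any(c(overlap, module_size, set_size, universe_size) < 0) ||
      overlap > min(module_size, set_size) ||
      module_size > universe_size || set_size > universe_size ||
      overlap < module_size + set_size - universe_size) {
    stop("inconsistent hypergeometric counts")
  }
  phyper(overlap - 1, set_size, universe_size - set_size, module_size,
         lower.tail = FALSE)
}

#' Read a gene-set collection in GMT format
#'
#' Tab-separated lines: set name, description, member gene IDs.  Duplicate
#' members within a set are dropped; empty sets are rejected.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors (a `GeneSetCollection`).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  if (!length(sets)) stop("no gene sets in ", path)
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) in ", path)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  sets
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input p-values must lie in `(0, 1]`.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Hypergeometric enrichment of every module against every gene set
#'
#' Sets are intersected with the universe before testing; one test is run
#' per (module, set) pair with a non-empty intersected set.  BH adjustment
#' is applied within each module by default (or globally across all tests).
#'
#' @param module_labels named character vector mapping gene IDs to module
#'   names (e.g. from [assign_modules()]); genes outside `universe` are
#'   dropped.
#' @param sets a gene-set collection (named list, e.g. from [read_gmt()]).
#' @param universe character vector of gene IDs defining the background
#'   (all filtered genes).
#' @param adjust `"per_module"` (default) or `"global"` BH scope.
#' @return data.frame with `module`, `set_name`, `overlap`, `module_size`,
#'   `set_size`, `universe_size`, `p`, `p_adjusted`.
#' @export
enrich_modules <- function(module_labels, sets, universe,
                           adjust = c("per_module", "global")) {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(names(module_labels), universe)
  if (length(extra)) {
    module_labels <- module_labels[setdiff(names(module_labels), extra)]
  }
  sets_u <- lapply(sets, intersect, universe)
  sets_u <- sets_u[lengths(sets_u) >= 1L]
  mods <- sort(unique(unname(module_labels)))
  rows <- list()
  for (m in mods) {
    module_genes <- names(module_labels)[module_labels == m]
    for (s in names(sets_u)) {
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set_name = s,
        overlap = length(intersect(module_genes, sets_u[[s]])),
        module_size = length(module_genes),
        set_size = length(sets_u[[s]]),
        universe_size = length(universe),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no (module, set) pairs to test")
  res <- do.call(rbind, rows)
  res$p <- phyper(res$overlap - 1, res$set_size,
                  res$universe_size - res$set_size, res$module_size,
                  lower.tail = FALSE)
  if (adjust == "per_module") {
    res$p_adjusted <- NA_real_
    for (m in unique(res$module)) {
      idx <- res$module == m
      res$p_adjusted[idx] <- bh_adjust(res$p[idx])
    }
  } else {
    res$p_adjusted <- bh_adjust(res$p)
  }
  res
}

#' Export an enrichment result as node and edge tables
#'
#' Builds a bipartite module-pathway network restricted to significant
#' pairs (`p_adjusted < alpha`), with `-log10` p-value attributes, in a form
#' importable by standard graph-visualization tools.
#'
#' @param results data.frame from [enrich_modules()].
#' @param alpha significance threshold on the adjusted p-value.
#' @return list with `nodes` (id, type, neg_log10_p) and `edges` (module,
#'   set_name, p, p_adjusted); the edge table is empty (with a warning) when
#'   nothing is significant.
#' @export
export_enrichment_network <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) >= 1L)
  sig <- results[results$p_adjusted < alpha, , drop = FALSE]
  if (!nrow(sig)) {
    warning("no significant (module, set) pairs at alpha = ", alpha)
    return(list(nodes = data.frame(id = character(), type = character(),
                                   neg_log10_p = numeric()),
                edges = sig[, c("module", "set_name", "p", "p_adjusted")]))
  }
  pathway_p <- vapply(unique(sig$set_name), function(s) {
    min(sig$p[sig$set_name == s])
  }, numeric(1))
  nodes <- rbind(
    data.frame(id = unique(sig$module), type = "module",
               neg_log10_p = NA_real_, stringsAsFactors = FALSE),
    data.frame(id = names(pathway_p), type = "pathway",
               neg_log10_p = -log10(pathway_p), stringsAsFactors = FALSE)
  )
  edges <- sig[, c("module", "set_name", "p", "p_adjusted")]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
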