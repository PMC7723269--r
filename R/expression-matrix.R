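# The central container: a genes x samples matrix with per-sample metadata.

#' Construct an expression matrix
#'
#' A lightweight S3 container for a genes-by-samples expression matrix with
#' per-sample metadata (clone identity and differentiation state) and a
#' `flavor` recording whether the values are raw counts or size-factor
#' normalized counts.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs, unique),
#'   samples in columns (colnames = sample IDs, unique); finite, non-negative.
#' @param metadata data.frame with columns `sample_id`, `clone_id`, `state`
#'   (one row per sample; `state` in `"preadipocyte"`/`"adipocyte"`).  May be
#'   `NULL` for matrices used outside paired screens.
#' @param flavor `"raw_counts"` or `"normalized"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, metadata = NULL,
                              flavor = c("raw_counts", "normalized")) {
  flavor <- match.arg(flavor)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  # R stores no rownames at all for a zero-row matrix
  if ((is.null(rownames(values)) && nrow(values) > 0L) ||
      is.null(colnames(values))) {
    stop("`values` must have gene IDs as rownames and sample IDs as colnames")
  }
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g)) {
    stop("duplicate gene IDs: ", paste(unique(dup_g), collapse = ", "))
  }
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s)) {
    stop("duplicate sample IDs: ", paste(unique(dup_s), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("`values` must be finite")
  if (any(values < 0)) stop("`values` must be non-negative")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    required <- c("sample_id", "clone_id", "state")
    if (!all(required %in% names(metadata))) {
      stop("metadata must have columns: ", paste(required, collapse = ", "))
    }
    missing <- setdiff(colnames(values), metadata$sample_id)
    if (length(missing)) {
      stop("samples without metadata: ", paste(missing, collapse = ", "))
    }
    metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
    bad_state <- setdiff(unique(metadata$state),
                         c("preadipocyte", "adipocyte"))
    if (length(bad_state)) {
      stop("unknown state(s): ", paste(bad_state, collapse = ", "))
    }
  }
  structure(
    list(values = values, metadata = metadata, flavor = flavor),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples\n",
              x$flavor, nrow(x$values), ncol(x$values)))
  if (!is.null(x$metadata)) {
    cat("states:", paste(sprintf("%s=%d", names(table(x$metadata$state)),
                                 table(x$metadata$state)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# Subset genes, keeping metadata and flavor.
subset_genes <- function(em, keep) {
  vals <- em$values[keep, , drop = FALSE]
  if (nrow(vals) == 0L) {
    # R drops dimnames entirely on an empty subset
    dimnames(vals) <- list(character(0), colnames(em$values))
  }
  expression_matrix(vals, em$metadata, em$flavor)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample IDs and a first
#' column of gene IDs.  Duplicate gene or sample IDs are rejected by name.
#'
#' @param path path to the expression TSV.
#' @param metadata_path optional path to a metadata TSV with columns
#'   `sample_id`, `clone_id`, `state`.
#' @param flavor stored flavor of the values (see [expression_matrix()]).
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, metadata_path = NULL,
                                flavor = c("raw_counts", "normalized")) {
  flavor <- match.arg(flavor)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene ID column and >= 1 sample")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate gene IDs in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  metadata <- if (!is.null(metadata_path)) {
    read.delim(metadata_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  expression_matrix(values, metadata, flavor)
}

#' Write an expression matrix to TSV
#'
#' Values are written at full double precision so that write/read round-trips
#' are lossless.
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  vals <- em$values
  chr <- matrix(format_full(vals), nrow = nrow(vals),
                dimnames = dimnames(vals))
  out <- data.frame(gene_id = rownames(vals), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(vals))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BATness score table
#'
#' @param path TSV with columns `clone_id`, `state`, `score` (scores in
#'   `[0, 1]`, one row per clone/state pair).
#' @return a validated data.frame (a "BATness table").
#' @export
read_batness_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_batness(df)
}

validate_batness <- function(df) {
  required <- c("clone_id", "state", "score")
  if (!all(required %in% names(df))) {
    stop("BATness table must have columns: ", paste(required, collapse = ", "))
  }
  if (any(df$score < 0 | df$score > 1)) stop("BATness scores must lie in [0, 1]")
  key <- paste(df$clone_id, df$state)
  if (anyDuplicated(key)) {
    stop("duplicate (clone, state) pairs in BATness table")
  }
  df
}

write_tsv <- function(df, path) {
  is_dbl <- vapply(df, is.double, logical(1))
  df[is_dbl] <- lapply(df[is_dbl], format_full)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
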