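# Shared fixture builders; everything is generated in code at test time.

# A small expression matrix with explicit values and metadata.
toy_matrix <- function(values, state = "preadipocyte",
                       flavor = "normalized") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("C%02d_%s", seq_len(ncol(values)),
                                if (state == "preadipocyte") "pre" else "diff")
  }
  meta <- data.frame(sample_id = colnames(values),
                     clone_id = sprintf("C%02d", seq_len(ncol(values))),
                     state = state, stringsAsFactors = FALSE)
  expression_matrix(values, meta, flavor)
}

# A quick small synthetic configuration for smoke-level pipeline tests.
small_config <- function(seed = 1L, ...) {
  synthetic_config(n_genes = 600L, n_clones = 20L, n_modules = 3L,
                   module_sizes = c(70L, 55L, 45L), seed = seed, ...)
}

# Write a GMT file for a set collection; returns the path.
write_gmt <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  path
}

# Naive silhouette straight from the definition (loops, no vectorization);
# independent oracle for mean_silhouette.
naive_mean_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    si <- (b - a) / max(a, b)
    s[i] <- if (is.nan(si)) 0 else si
  }
  mean(s)
}
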