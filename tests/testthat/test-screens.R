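test_that("pearson_with_p handles exact, null and degenerate cases", {
  x <- c(1, 3, 2, 5, 4)
  r1 <- pearson_with_p(x, x)
  expect_equal(r1$r, 1)
  expect_equal(r1$p, 0)

  # orthogonal to the centred x: r = 0, p = 1
  y <- c(1, -1, 0, 0, 0)
  xc <- c(-1, 1, 0, 0, 0) * 2  # centred, orthogonal to y? build explicitly
  x2 <- c(0, 0, 1, -1, 0)
  expect_equal(pearson_with_p(x2, y)$r, 0, tolerance = 1e-12)
  expect_equal(pearson_with_p(x2, y)$p, 1, tolerance = 1e-12)

  d <- pearson_with_p(rep(2, 5), x)
  expect_true(d$degenerate)
  expect_true(is.na(d$r))
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
  expect_error(pearson_with_p(1:4, 1:5), "equal length")
})

test_that("pearson_with_p agrees with cor.test", {
  set.seed(30)
  for (rep in 1:20) {
    x <- rnorm(12)
    y <- rnorm(12) + 0.5 * x
    res <- pearson_with_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("pearson_with_p matches permutation p-values within MC error", {
  set.seed(31)
  n_perm <- 20000L
  for (rep in 1:5) {
    x <- rnorm(10)
    y <- rnorm(10) + 0.4 * x
    res <- pearson_with_p(x, y)
    perm_r <- vapply(seq_len(n_perm), function(i) {
      cor(x, sample(y))
    }, numeric(1))
    p_perm <- mean(abs(perm_r) >= abs(res$r) - 1e-12)
    se <- sqrt(p_perm * (1 - p_perm) / n_perm)
    expect_lt(abs(res$p - p_perm), 0.015 + 3 * se)
  }
})

test_that("module-BATness screen finds the planted module and only it", {
  cfg <- small_config(seed = 40L)
  ds <- generate_clonal_dataset(cfg)
  norm <- normalize_counts(ds$counts_pre)
  labels <- ds$true_module_labels
  module_labels <- setNames(paste0("M", labels[labels > 0]),
                            names(labels)[labels > 0])
  res <- correlate_module_to_batness(norm, module_labels, ds$batness,
                                     "preadipocyte")
  expect_setequal(res$per_gene$gene_id, names(module_labels))
  expect_true(all(abs(res$per_gene$r) <= 1, na.rm = TRUE))
  # histogram bins count every non-degenerate gene
  expect_equal(sum(res$bins), sum(!res$per_gene$degenerate))
  # planted BATness module has the largest mean |r|
  mean_abs <- tapply(abs(res$per_gene$r), res$per_gene$module, mean,
                     na.rm = TRUE)
  expect_equal(names(which.max(mean_abs)), "M1")

  # a gene equal to the BATness vector correlates at r = 1
  pre_scores <- ds$batness[ds$batness$state == "preadipocyte", ]
  probe <- matrix(pre_scores$score[match(norm$metadata$clone_id,
                                         pre_scores$clone_id)],
                  1, ncol(norm$values),
                  dimnames = list("probe", colnames(norm$values)))
  em2 <- expression_matrix(rbind(norm$values, probe), norm$metadata,
                           "normalized")
  res2 <- correlate_module_to_batness(em2, c(probe = "M9"), ds$batness,
                                      "preadipocyte")
  expect_equal(res2$per_gene$r[res2$per_gene$gene_id == "probe"], 1,
               tolerance = 1e-12)
})

test_that("null BATness: per-module mean correlations centre at zero", {
  cfg <- small_config(seed = 41L, batness_module = NA)
  ds <- generate_clonal_dataset(cfg)
  norm <- normalize_counts(ds$counts_pre)
  labels <- ds$true_module_labels
  module_labels <- setNames(paste0("M", labels[labels > 0]),
                            names(labels)[labels > 0])
  res <- correlate_module_to_batness(norm, module_labels, ds$batness,
                                     "preadipocyte")
  # genes within a module share one clone-level latent factor, so the
  # per-module mean r carries clone-level sampling error ~ 1/sqrt(n - 1),
  # not gene-level error
  se_clone <- 1 / sqrt(cfg$n_clones - 1)
  for (m in unique(res$per_module$module)) {
    rs <- res$per_gene$r[res$per_gene$module == m & !res$per_gene$degenerate]
    expect_lt(abs(mean(rs)), 3 * se_clone)
  }
  # across several independent datasets the grand mean centres at zero
  grand <- vapply(1:6, function(s) {
    d <- generate_clonal_dataset(small_config(seed = 500L + s,
                                              batness_module = NA))
    nm <- normalize_counts(d$counts_pre)
    lab <- d$true_module_labels
    ml <- setNames(paste0("M", lab[lab > 0]), names(lab)[lab > 0])
    r <- correlate_module_to_batness(nm, ml, d$batness, "preadipocyte")
    mean(r$per_gene$r, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(grand)), 3 * se_clone / sqrt(6))
})

test_that("stability screen selects everything when states are identical", {
  set.seed(42)
  vals <- matrix(rlnorm(200, 3, 1), 20, 10)
  rownames(vals) <- sprintf("g%02d", 1:20)
  colnames(vals) <- sprintf("C%02d_pre", 1:10)
  pre <- toy_matrix(vals)
  vals_d <- vals
  colnames(vals_d) <- sprintf("C%02d_diff", 1:10)
  diff_em <- toy_matrix(vals_d, state = "adipocyte")
  res <- stable_gene_screen(pre, diff_em, rownames(vals))
  expect_true(all(res$table$selected))
  expect_equal(res$n_selected + res$n_degenerate +
                 sum(!res$table$selected & !res$table$degenerate),
               res$n_input)
})

test_that("stability screen is invariant to clone and gene reordering", {
  ds <- generate_clonal_dataset(small_config(seed = 43L))
  pre <- normalize_counts(ds$counts_pre)
  dif <- normalize_counts(ds$counts_diff)
  genes <- names(ds$true_module_labels)[ds$true_module_labels > 0]
  res <- stable_gene_screen(pre, dif, genes)

  perm_s <- sample(ncol(pre$values))
  pre2 <- expression_matrix(pre$values[, perm_s],
                            pre$metadata[perm_s, ], "normalized")
  perm_g <- sample(length(genes))
  res2 <- stable_gene_screen(pre2, dif, genes[perm_g])
  expect_setequal(res2$selected_ids, res$selected_ids)

  # unpaired designs are rejected
  dif_drop <- expression_matrix(dif$values[, -1],
                                dif$metadata[-1, ], "normalized")
  expect_error(stable_gene_screen(pre, dif_drop, genes), "unpaired|differ")
})

test_that("planted stable genes are selected far above the null rate", {
  ds <- generate_clonal_dataset(small_config(seed = 44L))
  pre <- normalize_counts(ds$counts_pre)
  dif <- normalize_counts(ds$counts_diff)
  genes <- names(ds$true_module_labels)[ds$true_module_labels > 0]
  res <- stable_gene_screen(pre, dif, genes, log2_scale = TRUE)
  stable_truth <- ds$true_stable_flags[genes]
  sensitivity <- mean(res$table$selected[stable_truth])
  fp <- mean(res$table$selected[!stable_truth])
  expect_gt(sensitivity, 0.6)
  expect_gt(sensitivity, 10 * max(fp, 0.025))
})

test_that("marker panel composes pearson_with_p elementwise", {
  set.seed(45)
  vals <- matrix(rlnorm(120, 4, 1), 6, 20)
  rownames(vals) <- c("m1", "m2", "m3", "t1", "t2", "t3")
  colnames(vals) <- sprintf("C%02d_pre", 1:20)
  vals["t3", ] <- max(vals["m1", ]) + 1 - vals["m1", ]  # negated profile
  em <- toy_matrix(vals)
  panel <- marker_correlation_panel(em, c("m1", "m2", "m3"),
                                    c("t1", "t2", "t3"))
  expect_equal(nrow(panel), 9)
  for (i in seq_len(nrow(panel))) {
    ref <- pearson_with_p(vals[panel$marker[i], ], vals[panel$target[i], ])
    expect_equal(panel$r[i], ref$r, tolerance = 1e-12)
    expect_equal(panel$p[i], ref$p, tolerance = 1e-12)
  }
  expect_equal(panel$r[panel$marker == "m1" & panel$target == "t3"], -1,
               tolerance = 1e-12)
  self <- marker_correlation_panel(em, "m1", "m1")
  expect_equal(self$r, 1)
  expect_true(self$significant)
  expect_error(marker_correlation_panel(em, "m1", "nope"), "nope")
})

test_that("BATness scatter clustering orders clusters and recovers archetypes", {
  bat <- data.frame(
    clone_id = rep(c("A", "B", "C"), 2),
    state = rep(c("preadipocyte", "adipocyte"), each = 3),
    score = c(0, 0, 1, 0, 1, 1))
  res <- kmeans_batness_scatter(bat, k = 3, seed = 1)
  expect_equal(sort(res$cluster), 1:3)
  expect_equal(res$cluster[res$clone_id == "A"], 1)  # lowest diff score
  expect_true(res$cluster[res$clone_id == "B"] %in% 2:3)

  # planted archetypes: low/low, low/high, high/high
  aris <- vapply(1:10, function(s) {
    set.seed(s + 100)
    truth <- rep(1:3, c(7, 7, 6))
    centers <- rbind(c(0.15, 0.15), c(0.15, 0.85), c(0.85, 0.85))
    pts <- pmin(pmax(centers[truth, ] +
                       matrix(rnorm(40, 0, 0.06), 20, 2), 0), 1)
    bat <- data.frame(clone_id = rep(sprintf("C%02d", 1:20), 2),
                      state = rep(c("preadipocyte", "adipocyte"), each = 20),
                      score = c(pts[, 1], pts[, 2]))
    res <- kmeans_batness_scatter(bat, k = 3, seed = s)
    adjusted_rand_index(res$cluster, truth)
  }, numeric(1))
  expect_gte(mean(aris >= 0.9), 0.9)

  # duplicated clones always cluster together
  expect_error(kmeans_batness_scatter(bat, k = 5), "exceeds")
})
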