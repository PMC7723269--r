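# Clonal bulk-expression simulator with planted modules, planted stable
# genes and planted BATness scores.  Ground truth is returned alongside the
# counts so every downstream stage can be validated without external data.

#' Configuration for the clonal-expression simulator
#'
#' Defaults emulate the study design the pipeline targets: 20 clonal lines
#' profiled in both the preadipocyte and the differentiated adipocyte state,
#' five planted co-expression modules driven by clone-level latent factors,
#' negative-binomial counts with log-normal library-size factors, a planted
#' subset of "stable" genes whose clone profile is preserved across states,
#' and BATness scores generated as a noisy logistic function of one
#' designated module's latent factor.
#'
#' @param n_genes total number of genes.
#' @param n_clones number of clonal lines (each present in both states).
#' @param n_modules number of planted modules.
#' @param module_sizes integer vector of length `n_modules`; the sizes must
#'   sum to at most `n_genes`.
#' @param signal_sd scale of the clone-level latent-factor effect on the
#'   log mean (log-scale standard deviation contributed by a unit loading).
#' @param noise_sd standard deviation of gene-by-sample log-normal noise.
#' @param nb_dispersion negative-binomial dispersion `phi`; the count
#'   variance is `mu + phi * mu^2`.  `0` gives Poisson counts.
#' @param libsize_sd standard deviation of the per-sample log size factors.
#' @param stable_fraction fraction of each module's genes whose latent
#'   factor is shared between states (the planted "stable" genes).
#' @param neg_loading_prob probability that a module gene carries a negative
#'   loading.  The default is 0: anti-correlated members form a separate,
#'   antipodal cluster in any distance-based geometry, which would make the
#'   planted one-cluster-per-module ground truth unrecoverable by
#'   construction; within-module expression contrast across clones arises
#'   from the clone-level latent factor regardless.
#' @param batness_module index of the module whose latent factor drives the
#'   BATness scores, or `NA` for pure-noise scores.
#' @param batness_noise_sd standard deviation of the noise added to the
#'   latent factor before the logistic squashing.
#' @param baseline_range range (in counts) of per-gene baseline means;
#'   baselines are drawn log-uniformly over this range.
#' @param seed integer seed; identical configurations give bit-identical
#'   datasets.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 3000L,
                             n_clones = 20L,
                             n_modules = 5L,
                             module_sizes = c(200L, 170L, 140L, 110L, 80L),
                             signal_sd = 2,
                             noise_sd = 1,
                             nb_dispersion = 0.1,
                             libsize_sd = 0.15,
                             stable_fraction = 0.3,
                             neg_loading_prob = 0,
                             batness_module = 1L,
                             batness_noise_sd = 0.5,
                             baseline_range = c(5, 500),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_clones = as.integer(n_clones),
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              signal_sd = signal_sd, noise_sd = noise_sd,
              nb_dispersion = nb_dispersion, libsize_sd = libsize_sd,
              stable_fraction = stable_fraction,
              neg_loading_prob = neg_loading_prob,
              batness_module = if (is.na(batness_module)) NA_integer_ else
                as.integer(batness_module),
              batness_noise_sd = batness_noise_sd,
              baseline_range = baseline_range, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L)
  if (cfg$n_clones < 1L) stop("n_clones must be positive")
  if (cfg$n_modules < 0L) stop("n_modules must be non-negative")
  if (length(cfg$module_sizes) != cfg$n_modules) {
    stop("module_sizes must have length n_modules")
  }
  if (cfg$n_modules > 0L && any(cfg$module_sizes < 1L)) {
    stop("module sizes must be positive")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop("sum(module_sizes) exceeds n_genes")
  }
  for (nm in c("signal_sd", "noise_sd", "libsize_sd", "stable_fraction",
               "batness_noise_sd", "nb_dispersion")) {
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative")
  }
  if (cfg$stable_fraction > 1) stop("stable_fraction must lie in [0, 1]")
  if (!is.na(cfg$batness_module) &&
      (cfg$batness_module < 1L || cfg$batness_module > cfg$n_modules)) {
    stop("batness_module must index an existing module")
  }
  invisible(cfg)
}

nb_draw <- function(n, mu, phi) {
  # stored as double so count matrices round-trip through TSV unchanged
  as.double(if (phi > 0) rnbinom(n, mu = mu, size = 1 / phi) else
    rpois(n, mu))
}

#' Simulate a paired clonal expression dataset with planted structure
#'
#' For each module `m` a clone-level latent factor `z_m(clone, state)` is
#' drawn standard normal; for genes flagged stable the preadipocyte factor
#' is reused in the differentiated state, so their clone profile is
#' preserved across differentiation.  Gene `g` in module `m` has
#' `log mean = baseline_g + loading_g * signal_sd * z_m(clone, state) + eps`,
#' background genes have loading 0, and counts are drawn negative-binomial
#' (`variance = mu + phi mu^2`) with per-sample log-normal size factors.
#' Latent factors, gene-level parameters and sampling noise use separate
#' seed streams, so changing `n_genes` does not perturb the clone-level
#' draws.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_dataset` list with elements `counts_pre` and
#'   `counts_diff` ([expression_matrix()] of raw counts), `batness`
#'   (clone/state/score data.frame), `true_module_labels` (0 = background),
#'   `true_stable_flags`, `true_loadings`, `true_latents`
#'   (`n_modules x n_clones x 2` array), `true_size_factors`, and `config`.
#' @export
generate_clonal_dataset <- function(config) {
  validate_synthetic_config(config)
  n_g <- config$n_genes
  n_c <- config$n_clones
  n_m <- config$n_modules
  clone_ids <- sprintf("C%02d", seq_len(n_c))
  gene_ids <- sprintf("g%04d", seq_len(n_g))
  states <- c("preadipocyte", "adipocyte")

  # Clone-level latent factors, one stream of their own.
  latents <- with_seed(stage_seed(config$seed, "latents"), {
    array(rnorm(max(n_m, 1L) * n_c * 2L), dim = c(max(n_m, 1L), n_c, 2L),
          dimnames = list(NULL, clone_ids, states))
  })
  if (n_m == 0L) latents <- latents[0L, , , drop = FALSE]

  # Gene-level parameters.
  gene_pars <- with_seed(stage_seed(config$seed, "genes"), {
    baseline <- runif(n_g, log(config$baseline_range[1]),
                      log(config$baseline_range[2]))
    labels <- integer(n_g)
    if (n_m > 0L) {
      labels[seq_len(sum(config$module_sizes))] <-
        rep(seq_len(n_m), config$module_sizes)
    }
    loading <- numeric(n_g)
    in_mod <- labels > 0L
    loading[in_mod] <- runif(sum(in_mod), 0.5, 1.5) *
      ifelse(runif(sum(in_mod)) < config$neg_loading_prob, -1, 1)
    stable <- logical(n_g)
    for (m in seq_len(n_m)) {
      members <- which(labels == m)
      n_stable <- round(config$stable_fraction * length(members))
      if (n_stable > 0L) {
        stable[sample(members, n_stable)] <- TRUE
      }
    }
    list(baseline = baseline, labels = labels, loading = loading,
         stable = stable)
  })

  # Sampling noise, size factors and counts.
  counts <- with_seed(stage_seed(config$seed, "counts"), {
    sf <- lapply(states, function(s) {
      setNames(exp(rnorm(n_c, 0, config$libsize_sd)), clone_ids)
    })
    names(sf) <- states
    mats <- lapply(states, function(s) {
      log_mu <- matrix(gene_pars$baseline, n_g, n_c)
      if (n_m > 0L) {
        for (m in seq_len(n_m)) {
          members <- which(gene_pars$labels == m)
          if (!length(members)) next
          # Stable genes keep their preadipocyte factor in both states.
          z_pre <- latents[m, , "preadipocyte"]
          z_cur <- latents[m, , s]
          for (g in members) {
            z <- if (gene_pars$stable[g]) z_pre else z_cur
            log_mu[g, ] <- log_mu[g, ] +
              gene_pars$loading[g] * config$signal_sd * z
          }
        }
      }
      if (config$noise_sd > 0) {
        log_mu <- log_mu + matrix(rnorm(n_g * n_c, 0, config$noise_sd),
                                  n_g, n_c)
      }
      mu <- exp(log_mu) * matrix(sf[[s]], n_g, n_c, byrow = TRUE)
      m_counts <- matrix(nb_draw(n_g * n_c, as.vector(mu),
                                 config$nb_dispersion), n_g, n_c)
      suffix <- if (s == "preadipocyte") "pre" else "diff"
      dimnames(m_counts) <- list(gene_ids, paste0(clone_ids, "_", suffix))
      m_counts
    })
    names(mats) <- states
    list(mats = mats, sf = sf)
  })

  meta <- function(suffix, state) {
    data.frame(sample_id = paste0(clone_ids, "_", suffix),
               clone_id = clone_ids, state = state,
               stringsAsFactors = FALSE)
  }
  dataset <- structure(list(
    counts_pre = expression_matrix(counts$mats[["preadipocyte"]],
                                   meta("pre", "preadipocyte"), "raw_counts"),
    counts_diff = expression_matrix(counts$mats[["adipocyte"]],
                                    meta("diff", "adipocyte"), "raw_counts"),
    true_module_labels = setNames(gene_pars$labels, gene_ids),
    true_stable_flags = setNames(gene_pars$stable, gene_ids),
    true_loadings = setNames(gene_pars$loading, gene_ids),
    true_latents = latents,
    true_size_factors = counts$sf,
    config = config
  ), class = "synthetic_dataset")
  dataset$batness <- generate_batness(dataset, config)
  dataset
}

#' Generate BATness scores from a planted latent factor
#'
#' Emulates an externally estimated per-sample brown-adipose similarity
#' score scaled to `(0, 1)`:
#' `score(clone, state) = logistic(z_bat(clone, state) + N(0, batness_noise_sd))`
#' where `z_bat` is the latent factor of the designated module.  With
#' `batness_module = NA` the scores are pure noise.
#'
#' @param dataset a `synthetic_dataset` (provides the latent factors).
#' @param config the [synthetic_config()] used to generate it.
#' @return a BATness data.frame with columns `clone_id`, `state`, `score`.
#' @export
generate_batness <- function(dataset, config) {
  validate_synthetic_config(config)
  n_c <- config$n_clones
  clone_ids <- dimnames(dataset$true_latents)[[2]]
  states <- c("preadipocyte", "adipocyte")
  with_seed(stage_seed(config$seed, "batness"), {
    rows <- lapply(states, function(s) {
      z <- if (is.na(config$batness_module)) {
        rep(0, n_c)
      } else {
        dataset$true_latents[config$batness_module, , s]
      }
      score <- plogis(z + rnorm(n_c, 0, config$batness_noise_sd))
      data.frame(clone_id = clone_ids, state = s, score = score,
                 stringsAsFactors = FALSE)
    })
    validate_batness(do.call(rbind, rows))
  })
}

#' Write a synthetic dataset to a plain-text fixture bundle
#'
#' Writes the two count matrices, the sample metadata, the BATness table and
#' the ground-truth labels as TSV, plus a JSON manifest listing every file
#' with its row and column counts.  The bundle round-trips losslessly
#' through [read_expression_tsv()] / [read_batness_tsv()].
#'
#' @param dataset a `synthetic_dataset`.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_fixture_bundle <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  meta <- rbind(dataset$counts_pre$metadata, dataset$counts_diff$metadata)
  truth <- data.frame(gene_id = names(dataset$true_module_labels),
                      module = as.integer(dataset$true_module_labels),
                      stable = dataset$true_stable_flags,
                      loading = dataset$true_loadings,
                      stringsAsFactors = FALSE)
  files <- list(
    counts_pre = "counts_pre.tsv", counts_diff = "counts_diff.tsv",
    metadata = "metadata.tsv", batness = "batness.tsv", truth = "truth.tsv"
  )
  write_expression_tsv(dataset$counts_pre, file.path(directory, files$counts_pre))
  write_expression_tsv(dataset$counts_diff, file.path(directory, files$counts_diff))
  write_tsv(meta, file.path(directory, files$metadata))
  write_tsv(dataset$batness, file.path(directory, files$batness))
  write_tsv(truth, file.path(directory, files$truth))
  manifest <- list(
    files = list(
      counts_pre = list(path = files$counts_pre,
                        rows = nrow(dataset$counts_pre$values),
                        cols = ncol(dataset$counts_pre$values)),
      counts_diff = list(path = files$counts_diff,
                         rows = nrow(dataset$counts_diff$values),
                         cols = ncol(dataset$counts_diff$values)),
      metadata = list(path = files$metadata, rows = nrow(meta),
                      cols = ncol(meta)),
      batness = list(path = files$batness, rows = nrow(dataset$batness),
                     cols = ncol(dataset$batness)),
      truth = list(path = files$truth, rows = nrow(truth), cols = ncol(truth))
    ),
    n_genes = dataset$config$n_genes,
    n_clones = dataset$config$n_clones,
    seed = dataset$config$seed
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
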