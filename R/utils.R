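# Internal helpers shared across stages.

#' Derive a reproducible sub-seed for a named stage
#'
#' Expands one user-facing seed into independent per-stage streams so that
#' toggling one stage does not reshuffle the draws of another.  The derived
#' seed is a deterministic 31-bit hash of the parent seed and the stage name.
#'
#' @param seed integer parent seed.
#' @param stage character scalar naming the stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

# Pearson correlation between paired rows of two matrices, vectorized.
# Returns NA for rows where either side has zero variance.
row_pearson <- function(X, Y) {
  stopifnot(is.matrix(X), is.matrix(Y), all(dim(X) == dim(Y)))
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  sx <- sqrt(rowSums(Xc^2))
  sy <- sqrt(rowSums(Yc^2))
  r <- rowSums(Xc * Yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

# Two-sided p-value for a Pearson correlation via the t-distribution.
pearson_p_value <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  rr <- r[ok]
  p_ok <- ifelse(
    abs(rr) >= 1,
    0,
    2 * pt(-abs(rr * sqrt(n - 2) / sqrt(1 - rr^2)), df = n - 2)
  )
  p[ok] <- pmin(p_ok, 1)
  p
}

format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}
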