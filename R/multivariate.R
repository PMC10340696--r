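# Trait correlation matrix with t-based p-values, PCA on centred/scaled
# traits with a deterministic sign convention, and principal component
# regression of a response on the leading scores.

#' Pairwise Pearson correlations among traits
#'
#' Pairwise-complete Pearson r per trait pair with the two-sided
#' t-distribution p-value and the pairwise n. Significance stars follow the
#' legend conventional in quality-trial reports: (*) p < 0.1, (**) p < 0.05,
#' (***) p < 0.001; no multiplicity correction is applied.
#'
#' @param traits_df Data frame (or matrix) of numeric trait columns, one row
#'   per genotype (entry means).
#' @return A `trait_correlations` list with matrices `r`, `p`, `n`, `stars`.
#'   Zero-variance traits yield `NA` correlations and are listed in the
#'   `flagged` attribute.
#' @export
correlation_matrix <- function(traits_df) {
  m <- as.matrix(traits_df)
  if (!is.numeric(m)) stop("all trait columns must be numeric", call. = FALSE)
  k <- ncol(m)
  nm <- colnames(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in i:k) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    if (i == j) { r[i, i] <- 1; p[i, i] <- 0; next }
    if (nij < 3) next
    si <- stats::sd(m[ok, i]); sj <- stats::sd(m[ok, j])
    if (si == 0 || sj == 0) next
    rij <- stats::cor(m[ok, i], m[ok, j])
    r[i, j] <- r[j, i] <- rij
    tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.eps))
    pij <- 2 * stats::pt(-abs(tt), df = nij - 2)
    p[i, j] <- p[j, i] <- pij
  }
  stars <- matrix(cut(p, breaks = c(-Inf, 0.001, 0.05, 0.1, Inf),
                      labels = c("***", "**", "*", "ns")),
                  k, k, dimnames = list(nm, nm))
  zero_var <- nm[apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)]
  structure(list(r = r, p = p, n = n, stars = stars),
            class = "trait_correlations", flagged = zero_var)
}

#' Principal component analysis of trait data
#'
#' PCA of centred (and by default scaled) trait columns. Sporadic missing
#' cells are mean-imputed per trait (default) or their rows dropped.
#' Components are ordered by decreasing explained variance and the sign of
#' each loading column is fixed by making its largest-magnitude entry
#' positive, so results are reproducible across platforms.
#'
#' @param traits_df Numeric data frame/matrix, rows = genotypes (or
#'   genotype-by-year combinations), columns = traits.
#' @param scale Scale each trait to unit variance (default `TRUE`).
#' @param missing `"impute"` (trait-mean imputation, default) or `"drop"`.
#' @return A `trait_pca` list: `loadings` (traits x components, orthonormal),
#'   `scores` (rows x components), `explained` (variance fractions summing
#'   to 1), `center`, `scale`, `n_imputed`.
#' @export
trait_pca <- function(traits_df, scale = TRUE,
                      missing = c("impute", "drop")) {
  missing <- match.arg(missing)
  m <- as.matrix(traits_df)
  if (nrow(m) < 2) stop("need at least 2 rows", call. = FALSE)
  if (any(colSums(is.finite(m)) == 0))
    stop("trait column with no finite values", call. = FALSE)
  n_imputed <- 0L
  if (anyNA(m)) {
    if (missing == "impute") {
      for (j in seq_len(ncol(m))) {
        na <- !is.finite(m[, j])
        n_imputed <- n_imputed + sum(na)
        m[na, j] <- mean(m[, j], na.rm = TRUE)
      }
    } else {
      m <- m[stats::complete.cases(m), , drop = FALSE]
    }
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  # deterministic sign: largest-|loading| entry of each column positive
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, scores = pc$x, explained = expl,
                 center = pc$center,
                 scale = if (scale) pc$scale else NULL,
                 n_imputed = n_imputed),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("trait_pca: %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$explained), 100 * x$explained[1],
              100 * x$explained[2]))
  invisible(x)
}

#' Principal component regression
#'
#' Ordinary least squares of a response on the first `k` principal component
#' scores. Because the sign convention of each component is fixed upstream
#' (and a sign flip of a score column merely flips its coefficient), fitted
#' values and R-squared do not depend on the PCA sign choice.
#'
#' @param pca A `trait_pca` from [trait_pca()].
#' @param response Numeric response aligned with the score rows.
#' @param k Number of leading components to use (1 <= k <= available).
#' @return A `pcr_model` list: `k`, `coefficients` (intercept + k slopes),
#'   `r_squared`, `fitted`, `residuals`.
#' @export
pcr_fit <- function(pca, response, k) {
  stopifnot(inherits(pca, "trait_pca"))
  scores <- pca$scores
  if (length(response) != nrow(scores))
    stop("response length must match the score rows", call. = FALSE)
  if (k < 1 || k > ncol(scores))
    stop("k must be between 1 and the number of components", call. = FALSE)
  X <- scores[, seq_len(k), drop = FALSE]
  fit <- stats::lm(response ~ X)
  fitted <- unname(stats::fitted(fit))
  tss <- sum((response - mean(response))^2)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  coefs <- stats::coef(fit)
  names(coefs) <- c("(Intercept)", colnames(X))
  structure(list(k = k, coefficients = coefs, r_squared = r2,
                 fitted = fitted, residuals = response - fitted),
            class = "pcr_model")
}

#' Smallest k reaching a cumulative-variance threshold
#'
#' Convenience for choosing the PCR component count: the smallest number of
#' leading components whose cumulative explained-variance fraction reaches
#' `threshold` (default 0.97).
#'
#' @param pca A `trait_pca`.
#' @param threshold Cumulative variance fraction in (0, 1].
#' @return Integer k.
#' @export
k_for_variance <- function(pca, threshold = 0.97) {
  stopifnot(inherits(pca, "trait_pca"), threshold > 0, threshold <= 1)
  which(cumsum(pca$explained) >= threshold - 1e-12)[1]
}
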