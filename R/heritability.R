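# Broad-sense heritability on an entry-mean basis, from ANOVA mean squares:
# the mean-square-ratio estimator with F-distribution confidence limits
# (replicated designs), and the variance-component estimator with year as
# the replicate (unreplicated designs).

#' Mean-square-ratio heritability
#'
#' h2 = 1 - MS_gxy / MS_genotype, the broad-sense heritability of genotype
#' entry means in a replicated multi-year trial. The raw estimate can be
#' negative when the interaction mean square exceeds the genotype mean
#' square; it is reported raw unless `clamp = TRUE`.
#'
#' @param ms_genotype Genotype mean square (> 0).
#' @param ms_gxy Genotype-by-year mean square (>= 0).
#' @param clamp Clamp the estimate to `[0, 1]`.
#' @return Numeric heritability estimate.
#' @export
h2_ms <- function(ms_genotype, ms_gxy, clamp = FALSE) {
  if (!is.finite(ms_genotype) || ms_genotype <= 0)
    stop("ms_genotype must be > 0", call. = FALSE)
  if (!is.finite(ms_gxy) || ms_gxy < 0)
    stop("ms_gxy must be >= 0", call. = FALSE)
  h2 <- 1 - ms_gxy / ms_genotype
  if (clamp) h2 <- min(max(h2, 0), 1)
  h2
}

#' Confidence limits for the mean-square-ratio heritability
#'
#' Exact limits from the F distribution of the genotype to interaction
#' mean-square ratio (Knapp-style interval):
#' UL = 1 - 1 / ((MS_g / MS_gxy) * F(1 - alpha/2; df1, df2)) and
#' LL = 1 - 1 / ((MS_g / MS_gxy) * F(alpha/2; df1, df2)),
#' with df1 = genotype df (g - 1) and df2 = interaction df
#' ((g - 1)(y - 1)). Since F(alpha/2) < 1 < F(1 - alpha/2) on the same
#' degrees of freedom, the interval always brackets the point estimate.
#' Limits are returned unclamped; a `[0, 1]`-clamped display form is
#' attached as the `clamped` attribute.
#'
#' @param ms_genotype,ms_gxy Mean squares as in [h2_ms()].
#' @param df1 Genotype degrees of freedom (g - 1).
#' @param df2 Interaction degrees of freedom ((g - 1)(y - 1)).
#' @param alpha Two-sided error rate; default 0.10 for 90% limits.
#' @return Named numeric `c(LL, UL)` with attribute `clamped`.
#' @export
h2_ci <- function(ms_genotype, ms_gxy, df1, df2, alpha = 0.10) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.finite(df1) || !is.finite(df2) || df1 < 1 || df2 < 1)
    stop("degrees of freedom must be >= 1", call. = FALSE)
  if (ms_genotype <= 0 || ms_gxy <= 0)
    stop("mean squares must be > 0 for interval construction", call. = FALSE)
  ratio <- ms_genotype / ms_gxy
  ul <- 1 - 1 / (ratio * stats::qf(1 - alpha / 2, df1, df2))
  ll <- 1 - 1 / (ratio * stats::qf(alpha / 2, df1, df2))
  out <- c(LL = ll, UL = ul)
  attr(out, "clamped") <- c(LL = min(max(ll, 0), 1), UL = min(max(ul, 0), 1))
  out
}

#' Variance components by method of moments, year as replicate
#'
#' For traits measured once per year the interaction is confounded with
#' error, and sigma_g^2 = (MS_genotype - MS_error) / r with r the number of
#' years; sigma_e^2 = MS_error. A negative genotypic variance estimate is
#' truncated at zero and flagged.
#'
#' @param ms_genotype Genotype mean square (>= 0).
#' @param ms_error Error mean square (>= 0).
#' @param r Number of year-replicates (>= 1).
#' @return A `varcomp` object: list(sigma_g2, sigma_e2, r, truncated).
#' @export
varcomp_from_ms <- function(ms_genotype, ms_error, r) {
  if (!is.finite(ms_genotype) || ms_genotype < 0 ||
      !is.finite(ms_error) || ms_error < 0)
    stop("mean squares must be finite and >= 0", call. = FALSE)
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  sg2 <- (ms_genotype - ms_error) / r
  truncated <- sg2 < 0
  if (truncated) sg2 <- 0
  structure(list(sigma_g2 = sg2, sigma_e2 = ms_error, r = as.integer(r),
                 truncated = truncated),
            class = "varcomp")
}

#' Variance-component heritability
#'
#' h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2 / r): broad-sense heritability of
#' entry means with r replicates (years, for unreplicated-within-year
#' traits). Always in `[0, 1]` after truncation of the genotypic variance.
#'
#' @param vc A `varcomp` object from [varcomp_from_ms()].
#' @return Numeric heritability in `[0, 1]`.
#' @export
h2_vc <- function(vc) {
  stopifnot(inherits(vc, "varcomp"))
  denom <- vc$sigma_g2 + vc$sigma_e2 / vc$r
  if (denom <= 0) stop("zero denominator: no variance to partition",
                       call. = FALSE)
  vc$sigma_g2 / denom
}

#' Heritability estimate from a fitted ANOVA
#'
#' Dispatches on the fitted model: the full (within-year replicated) model
#' uses the mean-square-ratio estimator with F-based confidence limits; the
#' reduced model uses the variance-component estimator with year as the
#' replicate. Either path can be forced.
#'
#' @param anova_tab A `trial_anova` from [fit_anova()].
#' @param method `"auto"` (default), `"ms_ratio"` or `"varcomp"`.
#' @param alpha Two-sided error rate for the ms-ratio limits (default 0.10).
#' @param clamp Clamp the ms-ratio point estimate to `[0, 1]`.
#' @return One-row data frame: trait, method, h2, LL, UL, alpha, df1, df2,
#'   sigma_g2, sigma_e2, truncated.
#' @export
estimate_h2 <- function(anova_tab, method = c("auto", "ms_ratio", "varcomp"),
                        alpha = 0.10, clamp = FALSE) {
  stopifnot(inherits(anova_tab, "trial_anova"))
  method <- match.arg(method)
  if (method == "auto")
    method <- if (attr(anova_tab, "model") == "full") "ms_ratio" else
      "varcomp"
  trait <- attr(anova_tab, "trait")
  if (method == "ms_ratio") {
    ms_g <- .ms(anova_tab, "genotype")
    ms_gxy <- .ms(anova_tab, "genotype_x_year")
    if (is.na(ms_gxy))
      stop("no genotype_x_year stratum: reduced model requires the ",
           "varcomp method", call. = FALSE)
    df1 <- .df(anova_tab, "genotype")
    df2 <- .df(anova_tab, "genotype_x_year")
    h2 <- h2_ms(ms_g, ms_gxy, clamp = clamp)
    ci <- h2_ci(ms_g, ms_gxy, df1, df2, alpha = alpha)
    data.frame(trait = trait, method = "ms_ratio", h2 = h2,
               LL = ci[["LL"]], UL = ci[["UL"]], alpha = alpha,
               df1 = df1, df2 = df2, sigma_g2 = NA_real_,
               sigma_e2 = NA_real_, truncated = FALSE,
               stringsAsFactors = FALSE)
  } else {
    ms_g <- .ms(anova_tab, "genotype")
    ms_e <- .ms(anova_tab, "error")
    r <- attr(anova_tab, "n_years")
    vc <- varcomp_from_ms(ms_g, ms_e, r)
    data.frame(trait = trait, method = "varcomp", h2 = h2_vc(vc),
               LL = NA_real_, UL = NA_real_, alpha = NA_real_,
               df1 = .df(anova_tab, "genotype"),
               df2 = .df(anova_tab, "error"),
               sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
               truncated = vc$truncated, stringsAsFactors = FALSE)
  }
}

#' Heritability table across traits
#'
#' Runs [fit_anova()] + [estimate_h2()] for each trait in a phenotype table
#' and binds the rows; the per-trait estimator is chosen automatically from
#' the design unless forced.
#'
#' @inheritParams estimate_h2
#' @param pheno Long-format phenotype data frame.
#' @param traits Trait names (default: all present).
#' @return Data frame, one row per trait.
#' @export
heritability_table <- function(pheno, traits = unique(pheno$trait),
                               method = "auto", alpha = 0.10,
                               clamp = FALSE) {
  do.call(rbind, lapply(traits, function(tr)
    estimate_h2(fit_anova(pheno, tr), method = method, alpha = alpha,
                clamp = clamp)))
}
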