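# Genotype-by-year ANOVA: sequential (Type I) sums of squares in the model
# order year, rep-within-year, genotype, genotype-by-year; entry means and
# shrinkage BLUPs.

#' Fit the genotype-by-year analysis of variance for one trait
#'
#' Decomposes the trait as value = mean + year + rep(year) + genotype +
#' genotype-by-year + error with sequential (Type I) sums of squares in that
#' fixed order; for balanced data this equals the textbook two-way
#' decomposition (and Type I = Type III). When no genotype-year cell holds
#' more than one observation the within-year terms cannot be separated: the
#' reduced model value = mean + year + genotype is fitted and the
#' genotype-by-year interaction is confounded with error, as for traits
#' measured once per year (loaf volume and the like).
#'
#' F statistics and p-values for every term are computed against the error
#' mean square.
#'
#' @param pheno Long-format phenotype data frame (genotype, year, rep,
#'   trait, value).
#' @param trait Trait name to analyse.
#' @param pool_rep_error If `TRUE`, the rep-within-year stratum is pooled
#'   into error before F tests (off by default; both error definitions are
#'   legitimate when the rep stratum is small).
#' @return A `trial_anova` object: data frame with columns term, df, ss, ms,
#'   f, p and attributes `grand_mean`, `trait`, `model` ("full" or
#'   "reduced"), `n_genotypes`, `n_years`, `n_reps` (mean replications per
#'   genotype-year cell).
#' @export
fit_anova <- function(pheno, trait, pool_rep_error = FALSE) {
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("trait not present: ", trait, call. = FALSE)
  d <- d[is.finite(d$value), , drop = FALSE]

  yr_per_geno <- rowSums(table(d$genotype, d$year) > 0)
  single <- names(yr_per_geno)[yr_per_geno < 2]
  if (length(single)) {
    warning(sprintf("excluding %d genotype(s) observed in a single year: %s",
                    length(single),
                    paste(utils::head(single, 5), collapse = ", ")),
            call. = FALSE)
    d <- d[!d$genotype %in% single, , drop = FALSE]
  }
  if (length(unique(d$genotype)) < 2 || length(unique(d$year)) < 2)
    stop("need >= 2 genotypes and >= 2 years", call. = FALSE)

  d$genotype <- factor(d$genotype)
  d$year <- factor(d$year)
  cell <- table(d$genotype, d$year)
  full <- any(cell > 1)

  if (full) {
    d$rep_in_year <- interaction(d$year, d$rep, drop = TRUE)
    d$gxy <- interaction(d$genotype, d$year, drop = TRUE)
    fit <- stats::lm(value ~ year + rep_in_year + genotype + gxy, data = d)
    at <- stats::anova(fit)
    terms <- c("year", "rep_within_year", "genotype", "genotype_x_year",
               "error")
  } else {
    fit <- stats::lm(value ~ year + genotype, data = d)
    at <- stats::anova(fit)
    terms <- c("year", "genotype", "error")
  }
  tab <- data.frame(term = terms, df = at$Df, ss = at$`Sum Sq`,
                    ms = at$`Mean Sq`, f = at$`F value`, p = at$`Pr(>F)`,
                    stringsAsFactors = FALSE)

  if (pool_rep_error && full) {
    i_rep <- match("rep_within_year", tab$term)
    i_err <- match("error", tab$term)
    tab$df[i_err] <- tab$df[i_err] + tab$df[i_rep]
    tab$ss[i_err] <- tab$ss[i_err] + tab$ss[i_rep]
    tab$ms[i_err] <- tab$ss[i_err] / tab$df[i_err]
    tab <- tab[-i_rep, , drop = FALSE]
    i_err <- match("error", tab$term)
    pre <- seq_len(i_err - 1L)
    tab$f[pre] <- tab$ms[pre] / tab$ms[i_err]
    tab$p[pre] <- stats::pf(tab$f[pre], tab$df[pre], tab$df[i_err],
                            lower.tail = FALSE)
    tab$f[i_err] <- NA_real_
    tab$p[i_err] <- NA_real_
    rownames(tab) <- NULL
  }

  structure(tab,
            class = c("trial_anova", "data.frame"),
            grand_mean = mean(d$value), trait = trait,
            model = if (full) "full" else "reduced",
            n_genotypes = nlevels(d$genotype), n_years = nlevels(d$year),
            n_reps = mean(cell[cell > 0]))
}

#' @export
print.trial_anova <- function(x, ...) {
  cat(sprintf("Genotype-by-year ANOVA for '%s' (%s model), grand mean %.4g\n",
              attr(x, "trait"), attr(x, "model"), attr(x, "grand_mean")))
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

.ms <- function(anova_tab, term) {
  i <- match(term, anova_tab$term)
  if (is.na(i)) NA_real_ else anova_tab$ms[i]
}

.df <- function(anova_tab, term) {
  i <- match(term, anova_tab$term)
  if (is.na(i)) NA_integer_ else anova_tab$df[i]
}

#' Per-year and across-year genotype entry means
#'
#' Year means average over replications; the across-year mean averages the
#' available year means (genotypes missing a year are flagged in the
#' `incomplete` attribute).
#'
#' @param pheno Long-format phenotype data frame.
#' @param trait Trait name.
#' @return Data frame: `genotype`, one column per year, `across`.
#' @export
entry_means <- function(pheno, trait) {
  d <- pheno[pheno$trait == trait & is.finite(pheno$value), , drop = FALSE]
  if (!nrow(d)) stop("trait not present: ", trait, call. = FALSE)
  ym <- stats::aggregate(value ~ genotype + year, data = d, FUN = mean)
  years <- sort(unique(ym$year))
  genos <- sort(unique(ym$genotype))
  wide <- data.frame(genotype = genos, stringsAsFactors = FALSE)
  for (yy in years) {
    sub <- ym[ym$year == yy, ]
    wide[[yy]] <- sub$value[match(genos, sub$genotype)]
  }
  ymat <- as.matrix(wide[years])
  wide$across <- rowMeans(ymat, na.rm = TRUE)
  attr(wide, "incomplete") <- genos[rowSums(is.na(ymat)) > 0]
  attr(wide, "trait") <- trait
  wide
}

#' Shrinkage BLUPs of genotype entry means
#'
#' Each genotype's across-year entry mean is shrunk toward the grand mean by
#' k = sigma_g^2 / (sigma_g^2 + sigma_e^2 / r): blup = mean + k * (entry
#' mean - mean). k is clamped to `[0, 1]`; when the denominator is zero all
#' BLUPs equal the grand mean.
#'
#' @param pheno Long-format phenotype data frame.
#' @param trait Trait name.
#' @param vc A `varcomp` object (see [varcomp_from_ms()]).
#' @return Data frame (genotype, entry_mean, blup) with attribute `k`.
#' @export
compute_blups <- function(pheno, trait, vc) {
  stopifnot(inherits(vc, "varcomp"), vc$r >= 1)
  em <- entry_means(pheno, trait)
  mu <- mean(em$across)
  denom <- vc$sigma_g2 + vc$sigma_e2 / vc$r
  k <- if (denom <= 0) 0 else min(max(vc$sigma_g2 / denom, 0), 1)
  out <- data.frame(genotype = em$genotype, entry_mean = em$across,
                    blup = mu + k * (em$across - mu),
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "grand_mean") <- mu
  out
}
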