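# Single-marker association scan: marker QC filters, GLM scan with
# genotype-matrix principal-component covariates, Benjamini-Hochberg FDR,
# the multi-environment / multi-model consensus rule, and the allele-group
# t-test used to validate declared hits.

#' Quality-filter a marker panel
#'
#' A marker is retained iff its missing-call fraction is <= `max_missing`,
#' its minor allele frequency (on non-missing calls) is >= `min_maf`, and
#' its heterozygote fraction (on non-missing calls) is <= `max_het`. The
#' defaults are the conventional GBS panel filters (50% missing, 5% MAF,
#' 10% heterozygosity). Filtering is idempotent and invariant to which
#' allele is coded as reference.
#'
#' @param genos A `genotype_matrix`.
#' @param max_missing,min_maf,max_het Thresholds in `[0, 1]`.
#' @return List with `genotypes` (filtered matrix) and `report` (per-marker
#'   data frame: marker, missing, maf, het, pass, reason).
#' @export
filter_markers <- function(genos, max_missing = 0.5, min_maf = 0.05,
                           max_het = 0.10) {
  stopifnot(inherits(genos, "genotype_matrix"),
            max_missing >= 0, max_missing <= 1,
            min_maf >= 0, min_maf <= 1, max_het >= 0, max_het <= 1)
  calls <- genos$calls
  missing <- colMeans(is.na(calls))
  freq <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  het <- colMeans(calls == 1L, na.rm = TRUE)
  het[is.nan(het)] <- 0
  fail_missing <- missing > max_missing
  fail_maf <- !fail_missing & maf < min_maf
  fail_het <- !fail_missing & !fail_maf & het > max_het
  pass <- !(fail_missing | fail_maf | fail_het)
  reason <- rep(NA_character_, length(pass))
  reason[fail_missing] <- "missing"
  reason[fail_maf] <- "maf"
  reason[fail_het] <- "het"
  report <- data.frame(marker = genos$map$marker, missing = missing,
                       maf = maf, het = het, pass = pass, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(pass))
    warning("no markers survive filtering; association scan will refuse ",
            "an empty panel", call. = FALSE)
  keep <- which(pass)
  filtered <- new_genotype_matrix(
    genos$lines, genos$map[keep, , drop = FALSE],
    genos$calls[, keep, drop = FALSE],
    ref_allele = genos$ref_allele[keep], alt_allele = genos$alt_allele[keep])
  list(genotypes = filtered, report = report)
}

#' Principal components of a genotype matrix
#'
#' Population-structure covariates for the GLM scan: missing doses are
#' mean-imputed per marker, the matrix centred, and the leading right
#' singular directions returned as line scores.
#'
#' @param genos A `genotype_matrix`.
#' @param n Number of components.
#' @return Lines x n score matrix.
#' @export
genotype_pcs <- function(genos, n) {
  m <- genos$calls
  storage.mode(m) <- "double"
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (any(na)) m[na, j] <- mean(m[, j], na.rm = TRUE)
  }
  keep <- apply(m, 2, stats::sd) > 0
  pc <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  n <- min(n, ncol(pc$x))
  pc$x[, seq_len(n), drop = FALSE]
}

# least-squares t-test on the last column of X
.dose_assoc <- function(y, X) {
  qr_x <- qr(X)
  k <- ncol(X)
  if (qr_x$rank < k || nrow(X) - qr_x$rank < 1) return(NULL)
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  df <- nrow(X) - k
  sigma2 <- sum(res^2) / df
  xtxi <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtxi[k, k])
  tstat <- if (se > 0) beta[k] / se else Inf * sign(beta[k])
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df) else 0
  list(effect = unname(beta[k]), se = unname(se), t = unname(tstat),
       p = unname(p), n = nrow(X))
}

#' Single-marker GLM association scan
#'
#' For each marker, ordinary least squares of the trait on an intercept,
#' `n_pcs` genotype-matrix principal components, and the allele dose; the
#' reported p-value is the two-sided t-test on the dose coefficient. Lines
#' with a missing dose at a marker are dropped pairwise; markers with fewer
#' than `n_pcs + 3` complete lines, or a dose collinear with the covariates
#' (e.g. monomorphic), are skipped with a reason. Benjamini-Hochberg
#' adjusted p-values are computed over the scanned markers.
#'
#' @param genos A (filtered) `genotype_matrix`.
#' @param trait_values Named numeric vector of per-line trait values for one
#'   environment (names = line ids).
#' @param n_pcs Number of principal-component covariates (default 3).
#' @param env,model Tags recorded on every result row (default "ENV3",
#'   "GLM").
#' @param trait_mean Mean used to express effects as percent of the trait
#'   mean; defaults to `mean(trait_values)`.
#' @return Data frame: marker, chrom, pos, env, model, n, effect,
#'   effect_pct (= 100 * effect / trait_mean), p, p_adj. Skipped markers are
#'   listed in the `skipped` attribute with reasons.
#' @export
glm_scan <- function(genos, trait_values, n_pcs = 3, env = "ENV3",
                     model = "GLM", trait_mean = NULL) {
  stopifnot(inherits(genos, "genotype_matrix"), n_pcs >= 0)
  if (ncol(genos$calls) == 0)
    stop("empty marker panel: nothing to scan", call. = FALSE)
  if (is.null(names(trait_values)))
    stop("trait_values must be named by line id", call. = FALSE)
  idx <- match(genos$lines, names(trait_values))
  if (anyNA(idx))
    stop("trait values missing for line(s): ",
         paste(utils::head(genos$lines[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  y <- as.numeric(trait_values[idx])
  if (is.null(trait_mean)) trait_mean <- mean(y, na.rm = TRUE)
  pcs <- if (n_pcs > 0) genotype_pcs(genos, n_pcs) else NULL

  n_m <- ncol(genos$calls)
  eff <- se <- p <- nn <- rep(NA_real_, n_m)
  skip_reason <- rep(NA_character_, n_m)
  for (j in seq_len(n_m)) {
    d <- genos$calls[, j]
    ok <- !is.na(d) & is.finite(y)
    if (sum(ok) < n_pcs + 3) {
      skip_reason[j] <- "too_few_lines"
      next
    }
    X <- cbind(1, pcs[ok, , drop = FALSE], d[ok])
    fit <- .dose_assoc(y[ok], X)
    if (is.null(fit)) {
      skip_reason[j] <- "collinear_dose"
      next
    }
    eff[j] <- fit$effect; se[j] <- fit$se; p[j] <- fit$p; nn[j] <- fit$n
  }
  scanned <- is.na(skip_reason)
  out <- data.frame(marker = genos$map$marker, chrom = genos$map$chrom,
                    pos = genos$map$pos, env = env, model = model,
                    n = nn, effect = eff,
                    effect_pct = 100 * eff / trait_mean, p = p,
                    p_adj = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$p_adj[scanned] <- bh_adjust(p[scanned])
  out <- out[scanned, , drop = FALSE]
  attr(out, "skipped") <- data.frame(
    marker = genos$map$marker[!scanned],
    reason = skip_reason[!scanned], stringsAsFactors = FALSE)
  attr(out, "trait_mean") <- trait_mean
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, returned in the
#' input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Trait environments for a multi-environment association scan
#'
#' Builds the four response vectors conventional in multi-environment GWAS:
#' per-year entry means (ENV1, ENV2, ...), across-year entry means (the
#' next tag), and BLUPs (last tag), the latter shrunk with variance
#' components from the trait's fitted ANOVA.
#'
#' @param pheno Long-format phenotype data frame.
#' @param trait Trait name.
#' @return Named list of named numeric vectors, tagged ENV1..ENV(n_years+2).
#' @export
trait_environments <- function(pheno, trait) {
  em <- entry_means(pheno, trait)
  years <- setdiff(names(em), c("genotype", "across"))
  envs <- list()
  for (i in seq_along(years)) {
    v <- em[[years[i]]]
    names(v) <- em$genotype
    envs[[sprintf("ENV%d", i)]] <- v
  }
  v <- em$across; names(v) <- em$genotype
  envs[[sprintf("ENV%d", length(years) + 1L)]] <- v
  at <- fit_anova(pheno, trait)
  vc <- varcomp_from_ms(.ms(at, "genotype"), .ms(at, "error"),
                        attr(at, "n_years"))
  bl <- compute_blups(pheno, trait, vc)
  v <- bl$blup; names(v) <- bl$genotype
  envs[[sprintf("ENV%d", length(years) + 2L)]] <- v
  envs
}

#' Consensus hits across environments and association models
#'
#' A support is a (marker, environment, model) result row passing all gates:
#' raw p <= `raw_cutoff` (the 1/n-markers critical value by default; rows
#' with no raw p, e.g. imported result tables reporting only adjusted
#' p-values, pass this gate), FDR-adjusted p < `fdr_threshold`, and
#' |effect_pct| >= `effect_min_pct`. A marker is declared a consensus hit
#' iff its supports span at least `min_support` distinct environments or at
#' least `min_support` distinct models. Result tables from external
#' association models can be row-bound with the scan output and participate
#' identically.
#'
#' @param results Data frame of result rows across environments/models with
#'   columns marker, env, model, effect_pct, p_adj and optionally p.
#' @param n_markers Number of markers scanned, setting the default raw
#'   cutoff 1/n_markers.
#' @param min_support Distinct environments or models required (default 2).
#' @param fdr_threshold FDR gate (default 0.1).
#' @param raw_cutoff Raw-p gate (default `1/n_markers`); set to `NULL`
#'   to apply the FDR gate alone.
#' @param effect_min_pct Minimum |effect| as percent of the trait mean
#'   (default 0.1).
#' @return List with `hits` (marker, n_support, n_env, n_model) and
#'   `supports` (the passing result rows for hit markers).
#' @export
consensus_hits <- function(results, n_markers, min_support = 2,
                           fdr_threshold = 0.1,
                           raw_cutoff = 1 / n_markers,
                           effect_min_pct = 0.1) {
  req <- c("marker", "env", "model", "effect_pct", "p_adj")
  miss <- setdiff(req, names(results))
  if (length(miss))
    stop("results missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(results$marker, results$env, results$model, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (marker, env, model) result rows", call. = FALSE)
  raw_ok <- if (is.null(raw_cutoff)) TRUE else
    is.na(results$p) | results$p <= raw_cutoff
  if (is.null(results$p)) raw_ok <- TRUE
  sup <- results[raw_ok &
                   !is.na(results$p_adj) & results$p_adj < fdr_threshold &
                   !is.na(results$effect_pct) &
                   abs(results$effect_pct) >= effect_min_pct, ,
                 drop = FALSE]
  if (!nrow(sup))
    return(list(hits = data.frame(marker = character(), n_support = integer(),
                                  n_env = integer(), n_model = integer(),
                                  stringsAsFactors = FALSE),
                supports = sup))
  spl <- split(sup, sup$marker)
  hits <- do.call(rbind, lapply(spl, function(s)
    data.frame(marker = s$marker[1], n_support = nrow(s),
               n_env = length(unique(s$env)),
               n_model = length(unique(s$model)),
               stringsAsFactors = FALSE)))
  hits <- hits[hits$n_env >= min_support | hits$n_model >= min_support, ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits,
       supports = sup[sup$marker %in% hits$marker, , drop = FALSE])
}

#' Read an external association-result table
#'
#' CSV with columns trait, marker, chr, pos, env, model, effect_pct, p_adj
#' (and optionally p), as exported by other association software; rows can
#' be bound with [glm_scan()] output and fed to [consensus_hits()].
#'
#' @param path CSV path.
#' @return Data frame in the scan-result layout.
#' @export
read_gwas_results <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("marker", "env", "model", "effect_pct", "p_adj")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("result table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(d$p)) d$p <- NA_real_
  d
}

#' Allele-group comparison at a marker
#'
#' Welch two-sided t-test between the two homozygote dose classes (0 vs 2);
#' heterozygotes are excluded. Letter codes mark the classes "a"/"b" when
#' they differ at `alpha` and "a"/"a" otherwise. The test is refused (with
#' `ok = FALSE` and a reason) when either homozygote class has fewer than
#' two lines.
#'
#' @param genos A `genotype_matrix`.
#' @param trait_values Named numeric vector of per-line trait values.
#' @param marker Marker name.
#' @param alpha Significance level for the letter codes (default 0.05).
#' @return An `allele_ttest` list: ok, reason, group (data frame with dose,
#'   n, mean, se, letter), t, df, p.
#' @export
allele_group_ttest <- function(genos, trait_values, marker, alpha = 0.05) {
  stopifnot(inherits(genos, "genotype_matrix"))
  j <- match(marker, genos$map$marker)
  if (is.na(j)) stop("unknown marker: ", marker, call. = FALSE)
  dose <- genos$calls[, j]
  y <- as.numeric(trait_values[genos$lines])
  ok <- !is.na(dose) & is.finite(y) & dose != 1L
  d <- dose[ok]; y <- y[ok]
  n0 <- sum(d == 0L); n2 <- sum(d == 2L)
  grp <- data.frame(dose = c(0L, 2L), n = c(n0, n2),
                    mean = c(mean(y[d == 0L]), mean(y[d == 2L])),
                    se = c(stats::sd(y[d == 0L]) / sqrt(max(n0, 1)),
                           stats::sd(y[d == 2L]) / sqrt(max(n2, 1))),
                    letter = c("a", "a"), stringsAsFactors = FALSE)
  if (n0 < 2 || n2 < 2) {
    return(structure(list(ok = FALSE,
                          reason = "fewer than 2 lines in a homozygote class",
                          group = grp, t = NA_real_, df = NA_real_,
                          p = NA_real_),
                     class = "allele_ttest"))
  }
  tt <- stats::t.test(y[d == 0L], y[d == 2L], var.equal = FALSE)
  if (tt$p.value < alpha) grp$letter <- c("a", "b")
  structure(list(ok = TRUE, reason = NA_character_, group = grp,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "allele_ttest")
}
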