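# Synthetic multi-year breeding-trial generator: phenotypes under a
# year / rep-within-year / genotype / genotype-by-year random-effects model,
# biallelic SNP panels, and planted QTL, with a ground-truth record.

#' Specify a simulated trait
#'
#' Defines one trait for [simulate_phenotypes()]: its grand mean and the
#' variances of the random effects that build up an observation
#' (year, replication-within-year, genotype, genotype-by-year interaction,
#' residual).
#'
#' @param name Trait name (string).
#' @param mean Grand mean on the trait's scale.
#' @param var_genotype Genotypic variance (sigma_g^2).
#' @param var_error Residual variance (sigma_e^2).
#' @param var_gxy Genotype-by-year interaction variance (default 0).
#' @param var_year Year main-effect variance (default 0).
#' @param var_rep Replication(evaluator)-within-year variance (default 0).
#' @param scale_bounds Optional length-2 numeric `c(lo, hi)`. When given,
#'   simulated values are clipped to the interval and rounded to the nearest
#'   unit, emulating an ordinal sensory score (e.g. the 1-7 hedonic scale).
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, mean, var_genotype, var_error,
                       var_gxy = 0, var_year = 0, var_rep = 0,
                       scale_bounds = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  v <- c(var_genotype = var_genotype, var_error = var_error,
         var_gxy = var_gxy, var_year = var_year, var_rep = var_rep)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all variance components must be finite and >= 0", call. = FALSE)
  if (!is.null(scale_bounds)) {
    stopifnot(is.numeric(scale_bounds), length(scale_bounds) == 2L,
              scale_bounds[1] < scale_bounds[2])
  }
  structure(list(name = name, mean = mean,
                 var_year = var_year, var_rep = var_rep,
                 var_genotype = var_genotype, var_gxy = var_gxy,
                 var_error = var_error, scale_bounds = scale_bounds),
            class = "trait_spec")
}

#' Configure a simulated breeding trial
#'
#' @param n_genotypes Number of genotypes (>= 2). Default 76, the panel size
#'   of a typical advanced-stage soft red winter wheat quality trial.
#' @param n_years Number of years/environments (>= 2). Default 2.
#' @param n_reps Replications (evaluators) per year: a scalar for a balanced
#'   design or an integer vector of length `n_years`. Use 1 for traits that
#'   are unreplicated within year (loaf volume and the like).
#' @param traits A list of [trait_spec()] objects (at least one).
#' @param trait_correlation Optional genetic correlation matrix across traits
#'   (symmetric, unit diagonal, positive semidefinite). Imposed on the
#'   genotype effects only.
#' @param seed Integer seed for reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 76, n_years = 2, n_reps = 1,
                       traits, trait_correlation = NULL, seed = 1L) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(length(traits) >= 1L,
            all(vapply(traits, inherits, logical(1), "trait_spec")))
  if (n_genotypes < 2 || n_years < 2)
    stop("need n_genotypes >= 2 and n_years >= 2", call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (length(n_reps) == 1L) n_reps <- rep(n_reps, n_years)
  if (length(n_reps) != n_years || any(n_reps < 1L))
    stop("n_reps must be a scalar or one positive count per year",
         call. = FALSE)
  nms <- vapply(traits, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate trait names", call. = FALSE)
  k <- length(traits)
  if (is.null(trait_correlation)) {
    trait_correlation <- diag(k)
  } else {
    trait_correlation <- as.matrix(trait_correlation)
    if (!isTRUE(all.equal(dim(trait_correlation), c(k, k))) ||
        !isTRUE(all.equal(trait_correlation, t(trait_correlation))) ||
        !isTRUE(all.equal(unname(diag(trait_correlation)), rep(1, k))))
      stop("trait_correlation must be a symmetric correlation matrix ",
           "matching the number of traits", call. = FALSE)
    ev <- eigen(trait_correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("trait_correlation is not positive semidefinite", call. = FALSE)
  }
  names(traits) <- nms
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_years = as.integer(n_years), n_reps = n_reps,
                 traits = traits, trait_correlation = trait_correlation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds the same fields as [sim_config()]; `traits` is a list of
#' mappings with the [trait_spec()] arguments.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  traits <- lapply(raw$traits, function(tr) do.call(trait_spec, tr))
  corr <- raw$trait_correlation
  if (!is.null(corr)) corr <- matrix(unlist(corr), nrow = length(traits))
  sim_config(n_genotypes = raw$n_genotypes, n_years = raw$n_years,
             n_reps = raw$n_reps %||% 1, traits = traits,
             trait_correlation = corr, seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expected heritabilities implied by a variance configuration.
# ms_ratio path assumes a within-year-replicated design with r reps;
# varcomp path assumes the year-as-replicate design where G-by-Y variance is
# confounded with the residual.
.implied_h2 <- function(tr, n_years, r) {
  e_ms_gxy <- tr$var_error + r * tr$var_gxy
  e_ms_g   <- e_ms_gxy + r * n_years * tr$var_genotype
  h2_ms <- if (e_ms_g > 0) 1 - e_ms_gxy / e_ms_g else NA_real_
  sig_e_star <- tr$var_gxy + tr$var_error
  denom <- tr$var_genotype + sig_e_star / n_years
  h2_vc <- if (denom > 0) tr$var_genotype / denom else NA_real_
  list(ms_ratio = h2_ms, varcomp = h2_vc)
}

#' Simulate trial phenotypes
#'
#' Draws one observation per genotype x year x replication x trait under the
#' random-effects model value = mean + year + rep(year) + genotype +
#' genotype-by-year + residual. Each effect is drawn once per its index
#' combination from a zero-mean normal with the configured variance;
#' genotype effects across traits are drawn jointly under the configured
#' genetic correlation matrix. Traits with `scale_bounds` are clipped and
#' rounded to the nearest unit after all effects are summed.
#'
#' @param config A [sim_config()].
#' @return A list with `phenotypes` (long-format data frame: genotype, year,
#'   rep, trait, value) and `truth` (the generating variance components,
#'   implied heritabilities for both estimator paths, planted-QTL table, and
#'   seed).
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$n_genotypes; y <- config$n_years; reps <- config$n_reps
  traits <- config$traits; k <- length(traits)
  gid <- sprintf("G%03d", seq_len(g))
  yid <- sprintf("Y%d", seq_len(y))

  # genotype effects: jointly across traits
  sds <- sqrt(vapply(traits, `[[`, numeric(1), "var_genotype"))
  sigma_g <- diag(sds, k) %*% config$trait_correlation %*% diag(sds, k)
  geno_eff <- MASS::mvrnorm(g, mu = rep(0, k), Sigma = sigma_g)
  geno_eff <- matrix(geno_eff, nrow = g, ncol = k)

  out <- vector("list", k)
  for (t in seq_len(k)) {
    tr <- traits[[t]]
    year_eff <- stats::rnorm(y, 0, sqrt(tr$var_year))
    gxy_eff <- matrix(stats::rnorm(g * y, 0, sqrt(tr$var_gxy)), g, y)
    rows <- vector("list", y)
    for (i in seq_len(y)) {
      r_i <- reps[i]
      rep_eff <- stats::rnorm(r_i, 0, sqrt(tr$var_rep))
      idx <- expand.grid(genotype = seq_len(g), rep = seq_len(r_i))
      val <- tr$mean + year_eff[i] + rep_eff[idx$rep] +
        geno_eff[idx$genotype, t] + gxy_eff[idx$genotype, i] +
        stats::rnorm(nrow(idx), 0, sqrt(tr$var_error))
      rows[[i]] <- data.frame(genotype = gid[idx$genotype], year = yid[i],
                              rep = sprintf("R%d", idx$rep),
                              trait = tr$name, value = val,
                              stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    if (!is.null(tr$scale_bounds)) {
      d$value <- round(pmin(pmax(d$value, tr$scale_bounds[1]),
                            tr$scale_bounds[2]))
    }
    out[[t]] <- d
  }
  pheno <- do.call(rbind, out)
  rownames(pheno) <- NULL

  r_bar <- mean(reps)
  truth <- list(
    seed = config$seed,
    components = lapply(traits, function(tr)
      tr[c("mean", "var_year", "var_rep", "var_genotype", "var_gxy",
           "var_error")]),
    h2 = lapply(traits, .implied_h2, n_years = y, r = r_bar),
    qtl = data.frame(marker = character(), trait = character(),
                     effect = numeric(), effect_pct = numeric(),
                     stringsAsFactors = FALSE)
  )
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a biallelic SNP panel
#'
#' Generates a lines-by-markers allele-dose matrix (0/1/2, NA for missing).
#' Per marker, the reference-allele frequency is drawn uniformly from
#' `maf_range`; each call is heterozygous with probability `het_rate` and
#' otherwise homozygous with the dose-2 probability chosen so the expected
#' allele frequency matches the drawn frequency. Missing calls are masked at
#' `missing_rate`. Marker positions are strictly increasing within each
#' chromosome and names follow the `S<chrom>_<pos>` convention.
#'
#' @param n_lines Number of lines.
#' @param n_markers Number of markers (>= 1).
#' @param maf_range Interval in (0, 0.5] for the per-marker allele frequency.
#' @param missing_rate,het_rate Expected per-marker missing and heterozygote
#'   fractions, in `[0, 1)`.
#' @param chromosomes Chromosome labels; markers are assigned in contiguous
#'   blocks. Defaults to the 21 hexaploid wheat chromosomes.
#' @param seed Integer seed.
#' @return A `genotype_matrix`: list with `lines`, `map` (marker, chrom,
#'   pos), and `calls` (lines x markers integer matrix).
#' @export
simulate_genotypes <- function(n_lines, n_markers,
                               maf_range = c(0.05, 0.5),
                               missing_rate = 0, het_rate = 0,
                               chromosomes = paste0(rep(1:7, each = 3),
                                                    c("A", "B", "D")),
                               seed = 1L) {
  if (n_markers < 1) stop("n_markers must be >= 1", call. = FALSE)
  stopifnot(missing_rate >= 0, missing_rate < 1, het_rate >= 0, het_rate < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  set.seed(seed)
  n_chr <- min(length(chromosomes), n_markers)
  chr_of <- sort(rep_len(seq_len(n_chr), n_markers))
  pos <- integer(n_markers)
  for (c_i in seq_len(n_chr)) {
    idx <- which(chr_of == c_i)
    pos[idx] <- sort(sample.int(8e8, length(idx)))
  }
  chrom <- chromosomes[chr_of]
  map <- data.frame(marker = sprintf("S%s_%d", chrom, pos),
                    chrom = chrom, pos = pos, stringsAsFactors = FALSE)

  p <- stats::runif(n_markers, maf_range[1], maf_range[2])
  # P(dose 2 | homozygous) keeping E[freq] = p given the het rate
  q2 <- pmin(pmax((2 * p - het_rate) / (2 * (1 - het_rate)), 0), 1)
  calls <- matrix(0L, n_lines, n_markers,
                  dimnames = list(sprintf("G%03d", seq_len(n_lines)),
                                  map$marker))
  for (j in seq_len(n_markers)) {
    is_het <- stats::runif(n_lines) < het_rate
    dose <- ifelse(is_het, 1L,
                   2L * (stats::runif(n_lines) < q2[j]))
    if (missing_rate > 0)
      dose[stats::runif(n_lines) < missing_rate] <- NA_integer_
    calls[, j] <- as.integer(dose)
  }
  new_genotype_matrix(rownames(calls), map, calls)
}

#' Specify a QTL to plant in simulated phenotypes
#'
#' The additive effect is the trait-unit change per copy of the reference
#' allele; `effect_pct` expresses the full homozygote contrast as a
#' percentage of the trait mean (effect_pct = 100 * |2 * effect| / mean).
#' Give either `effect` or `effect_pct` together with `trait_mean`.
#'
#' @param marker Marker name present in the genotype matrix.
#' @param trait Trait name present in the phenotype table.
#' @param effect Additive effect in trait units per allele dose.
#' @param effect_pct Homozygote contrast as percent of the trait mean.
#' @param trait_mean Trait mean used to convert `effect_pct` to trait units.
#' @return A one-row data frame (marker, trait, effect, effect_pct).
#' @export
qtl_spec <- function(marker, trait, effect = NULL, effect_pct = NULL,
                     trait_mean = NULL) {
  if (is.null(effect)) {
    if (is.null(effect_pct) || is.null(trait_mean))
      stop("give either effect, or effect_pct with trait_mean", call. = FALSE)
    effect <- effect_pct / 100 * trait_mean / 2
  } else if (is.null(effect_pct)) {
    effect_pct <- if (is.null(trait_mean)) NA_real_ else
      100 * abs(2 * effect) / trait_mean
  }
  data.frame(marker = marker, trait = trait, effect = effect,
             effect_pct = effect_pct, stringsAsFactors = FALSE)
}

#' Add additive QTL effects to simulated phenotypes
#'
#' Each observation of a QTL's trait is incremented by
#' (allele dose - mean dose) x additive effect, so the trait mean is
#' unchanged. Lines with a missing call at the QTL marker contribute the
#' population-mean dose (increment 0).
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes Long-format phenotype data frame.
#' @param qtls Data frame of QTL rows as produced by [qtl_spec()] (rbind for
#'   several). An empty data frame is a no-op.
#' @param truth Optional truth record from [simulate_phenotypes()]; when
#'   given, its `qtl` table is extended and the updated record returned.
#' @return If `truth` is `NULL`, the modified phenotype table; otherwise a
#'   list with `phenotypes` and `truth`.
#' @export
inject_qtl <- function(genotypes, phenotypes, qtls, truth = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(qtls) > 0) {
    bad_m <- setdiff(qtls$marker, genotypes$map$marker)
    if (length(bad_m))
      stop("unknown marker(s): ", paste(bad_m, collapse = ", "),
           call. = FALSE)
    bad_t <- setdiff(qtls$trait, unique(phenotypes$trait))
    if (length(bad_t))
      stop("unknown trait(s): ", paste(bad_t, collapse = ", "),
           call. = FALSE)
    for (q in seq_len(nrow(qtls))) {
      dose <- genotypes$calls[, qtls$marker[q]]
      mu_d <- mean(dose, na.rm = TRUE)
      dose[is.na(dose)] <- mu_d
      delta <- (dose - mu_d) * qtls$effect[q]
      sel <- phenotypes$trait == qtls$trait[q]
      hit <- match(phenotypes$genotype[sel], genotypes$lines)
      if (anyNA(hit))
        stop("phenotype genotypes absent from the genotype matrix",
             call. = FALSE)
      phenotypes$value[sel] <- phenotypes$value[sel] + delta[hit]
    }
  }
  if (is.null(truth)) return(phenotypes)
  truth$qtl <- rbind(truth$qtl, qtls)
  list(phenotypes = phenotypes, truth = truth)
}

#' Write a truth record as JSON
#'
#' @param truth Truth record from [simulate_phenotypes()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
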