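# Readers/writers for phenotype tables, genotype matrices (numeric CSV,
# HapMap-dialect text, minimal VCF), and SE-HPLC fraction-area tables.

#' Construct a genotype matrix
#'
#' @param lines Character vector of line ids.
#' @param map Data frame with columns `marker`, `chrom`, `pos` (1-based bp).
#' @param calls Integer matrix, lines x markers, allele doses 0/1/2 with
#'   `NA` for missing.
#' @param ref_allele,alt_allele Optional per-marker allele labels; dose
#'   counts copies of `ref_allele`.
#' @return A `genotype_matrix` object.
#' @export
new_genotype_matrix <- function(lines, map, calls,
                                ref_allele = NULL, alt_allele = NULL) {
  stopifnot(is.matrix(calls), nrow(calls) == length(lines),
            ncol(calls) == nrow(map),
            all(c("marker", "chrom", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) stop("duplicate marker names", call. = FALSE)
  if (any(map$pos < 0)) stop("negative positions", call. = FALSE)
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("calls must be 0/1/2 or NA", call. = FALSE)
  dimnames(calls) <- list(lines, map$marker)
  structure(list(lines = lines, map = map, calls = calls,
                 ref_allele = ref_allele, alt_allele = alt_allele),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers (%.1f%% missing)\n",
              length(x$lines), nrow(x$map),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

.validate_phenotypes <- function(d, where = "phenotype table") {
  req <- c("genotype", "year", "rep", "trait", "value")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop(where, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$value <- suppressWarnings(as.numeric(d$value))
  dropped <- which(!is.finite(d$value))
  if (length(dropped)) d <- d[-dropped, , drop = FALSE]
  key <- do.call(paste, c(d[c("genotype", "year", "rep", "trait")],
                          sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop(where, ": duplicate (genotype, year, rep, trait) key at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  attr(d, "n_dropped") <- length(dropped)
  rownames(d) <- NULL
  d
}

#' Read a phenotype table
#'
#' Long dialect expects columns genotype, year, rep, trait, value. Wide
#' dialect expects genotype, year, rep plus one numeric column per trait,
#' which is melted to long. Records with missing/non-finite values are
#' dropped and counted in the `n_dropped` attribute.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return A validated long-format data frame.
#' @export
read_phenotype_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "wide") {
    id <- c("genotype", "year", "rep")
    miss <- setdiff(id, names(d))
    if (length(miss))
      stop("wide table: missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    traits <- setdiff(names(d), id)
    if (!length(traits)) stop("wide table has no trait columns", call. = FALSE)
    long <- do.call(rbind, lapply(traits, function(tr)
      data.frame(d[id], trait = tr, value = d[[tr]],
                 stringsAsFactors = FALSE)))
    d <- long
  }
  .validate_phenotypes(d, where = path)
}

#' Write a phenotype table as long-format CSV
#'
#' @param pheno Long-format phenotype data frame.
#' @param path Output path.
#' @export
write_phenotype_table <- function(pheno, path) {
  utils::write.csv(pheno[c("genotype", "year", "rep", "trait", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_snp_names <- function(marker) {
  m <- regmatches(marker, regexec("^S([0-9][A-D]|[0-9]+)_([0-9]+)$", marker))
  chrom <- vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                  character(1))
  pos <- vapply(m, function(x) if (length(x)) as.numeric(x[3]) else NA_real_,
                numeric(1))
  list(chrom = chrom, pos = pos)
}

# major-allele recode: flip dose orientation so dose 2 counts the major
# allele; at an exact 50% frequency the as-read orientation is kept.
.recode_major <- function(gm) {
  freq <- colMeans(gm$calls, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq < 0.5
  if (any(flip)) {
    gm$calls[, flip] <- 2L - gm$calls[, flip]
    if (!is.null(gm$ref_allele)) {
      tmp <- gm$ref_allele[flip]
      gm$ref_allele[flip] <- gm$alt_allele[flip]
      gm$alt_allele[flip] <- tmp
    }
  }
  gm
}

#' Read a genotype matrix
#'
#' Three dialects:
#' * `numeric`: CSV with a `line` column then one column per marker holding
#'   doses 0/1/2 and -1 (or empty/NA) for missing. Marker names of the form
#'   `S<chrom>_<pos>` are parsed into map coordinates.
#' * `hapmap`: tab-separated HapMap-dialect text (`rs#`, `alleles`, `chrom`,
#'   `pos`, ... 11 annotation columns, then two-letter genotype calls;
#'   `NN` = missing). Dose counts the second-listed allele, then markers are
#'   recoded so dose 2 counts the major allele (`recode = "major"`).
#' * `vcf`: biallelic SNP records only (others skipped with a warning); the
#'   GT field is parsed and dose counts the ALT allele before recoding.
#'   Positions are 1-based as in both standards.
#'
#' @param path Input file path.
#' @param format `"numeric"`, `"hapmap"` or `"vcf"`.
#' @param recode `"major"` (default for hapmap/vcf) re-orients each marker so
#'   dose 2 counts the major allele; `"none"` keeps the as-read orientation
#'   (default for numeric).
#' @return A `genotype_matrix`.
#' @export
read_genotype_matrix <- function(path, format = c("numeric", "hapmap", "vcf"),
                                 recode = NULL) {
  format <- match.arg(format)
  if (is.null(recode)) recode <- if (format == "numeric") "none" else "major"
  recode <- match.arg(recode, c("none", "major"))
  gm <- switch(format,
               numeric = .read_geno_numeric(path),
               hapmap = .read_geno_hapmap(path),
               vcf = .read_geno_vcf(path))
  if (recode == "major") gm <- .recode_major(gm)
  gm
}

.read_geno_numeric <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"line" %in% names(d))
    stop("numeric genotype CSV needs a 'line' column", call. = FALSE)
  lines <- as.character(d$line)
  calls <- as.matrix(d[setdiff(names(d), "line")])
  storage.mode(calls) <- "integer"
  calls[calls == -1L] <- NA_integer_
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("numeric genotype codes must be in {0,1,2,-1}",
                     call. = FALSE)
  parsed <- .parse_snp_names(colnames(calls))
  map <- data.frame(marker = colnames(calls),
                    chrom = ifelse(is.na(parsed$chrom), "un", parsed$chrom),
                    pos = ifelse(is.na(parsed$pos),
                                 seq_along(parsed$pos), parsed$pos),
                    stringsAsFactors = FALSE)
  new_genotype_matrix(lines, map, calls)
}

.hapmap_header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                    "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

.read_geno_hapmap <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) <= 11)
    stop("HapMap file has no sample columns", call. = FALSE)
  lines <- names(d)[-(1:11)]
  alle <- strsplit(d[[2]], "/", fixed = TRUE)
  a1 <- vapply(alle, `[`, character(1), 1)
  a2 <- vapply(alle, `[`, character(1), 2)
  calls <- matrix(NA_integer_, length(lines), nrow(d))
  for (j in seq_len(nrow(d))) {
    cc <- toupper(as.character(d[j, -(1:11)]))
    split <- strsplit(cc, "")
    dose <- vapply(split, function(al) {
      if (length(al) != 2L || any(!al %in% c(a1[j], a2[j])))
        return(NA_integer_)
      sum(al == a2[j])
    }, integer(1))
    calls[, j] <- dose
  }
  map <- data.frame(marker = d[[1]], chrom = as.character(d[[3]]),
                    pos = as.numeric(d[[4]]), stringsAsFactors = FALSE)
  new_genotype_matrix(lines, map, calls, ref_allele = a2, alt_allele = a1)
}

.read_geno_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_skip <- sum(!bi)
  if (n_skip > 0) {
    warning(sprintf("skipped %d multiallelic/non-SNP record(s)", n_skip),
            call. = FALSE)
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  fix <- vcfR::getFIX(v)
  calls <- t(dose)
  storage.mode(calls) <- "integer"
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- sprintf("S%s_%s", fix[noid, "CHROM"], fix[noid, "POS"])
  map <- data.frame(marker = unname(id), chrom = unname(fix[, "CHROM"]),
                    pos = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE)
  gm <- new_genotype_matrix(rownames(calls), map, calls,
                            ref_allele = unname(fix[, "ALT"]),
                            alt_allele = unname(fix[, "REF"]))
  attr(gm, "n_skipped") <- n_skip
  gm
}

#' Write a genotype matrix as numeric CSV
#'
#' Missing calls are written as -1.
#'
#' @param genos A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotype_csv <- function(genos, path) {
  calls <- genos$calls
  calls[is.na(calls)] <- -1L
  d <- data.frame(line = genos$lines, calls, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix as HapMap-dialect text
#'
#' Doses are rendered with per-marker allele labels (defaults `A`/`G` when
#' the matrix carries none): dose 2 as the reference homozygote, 1 as the
#' heterozygote, missing as `NN`.
#'
#' @param genos A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotype_hapmap <- function(genos, path) {
  n_m <- nrow(genos$map)
  ref <- genos$ref_allele %||% rep("G", n_m)
  alt <- genos$alt_allele %||% rep("A", n_m)
  rows <- vapply(seq_len(n_m), function(j) {
    dose <- genos$calls[, j]
    cc <- c("0" = paste0(alt[j], alt[j]), "1" = paste0(alt[j], ref[j]),
            "2" = paste0(ref[j], ref[j]))[as.character(dose)]
    cc[is.na(cc)] <- "NN"
    paste(c(genos$map$marker[j], paste0(alt[j], "/", ref[j]),
            genos$map$chrom[j], genos$map$pos[j], "+", rep("NA", 6), cc),
          collapse = "\t")
  }, character(1))
  header <- paste(c(.hapmap_header, genos$lines), collapse = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an SE-HPLC fraction-area table
#'
#' Expects a `sample` column plus absorbance areas (mAU*min) for the
#' SDS-extractable and SDS-unextractable fractions: `E_F1`..`E_F4` and
#' `U_F1`..`U_F4` (F4 columns optional, needed only for area percentages
#' over all four fractions).
#'
#' @param path CSV path.
#' @return Validated data frame of non-negative areas.
#' @export
read_fraction_areas <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample", paste0("E_F", 1:3), paste0("U_F", 1:3))
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("fraction-area table: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  num <- setdiff(names(d), "sample")
  for (cn in num) {
    d[[cn]] <- as.numeric(d[[cn]])
    if (any(is.finite(d[[cn]]) & d[[cn]] < 0))
      stop("negative absorbance area in column ", cn, call. = FALSE)
  }
  d
}

#' Reference ANOVA mean squares from a two-year wheat quality trial
#'
#' Published per-trait summary of a 76-genotype, two-year soft red winter
#' wheat bread-quality trial: entry-mean range and mean, and the mean
#' squares (year, genotype, genotype-by-year where the trait was replicated
#' within year, error) from the genotype-by-year analysis of variance. These
#' are the inputs the mean-square heritability estimators operate on;
#' traits without a genotype-by-year column were unreplicated within year,
#' so year serves as the replicate for the variance-component estimator.
#'
#' @return Data frame with columns trait, units, entry_min, entry_max,
#'   entry_mean, ms_year, ms_genotype, ms_gxy, ms_error.
#' @export
quality_reference_ms <- function() {
  path <- system.file("extdata", "quality_trial_anova_ms.csv",
                      package = "breedtrial", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
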