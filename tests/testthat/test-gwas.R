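make_gm <- function(calls, lines = sprintf("L%02d", seq_len(nrow(calls)))) {
  map <- data.frame(marker = sprintf("m%d", seq_len(ncol(calls))),
                    chrom = "1A", pos = seq_len(ncol(calls)),
                    stringsAsFactors = FALSE)
  new_genotype_matrix(lines, map, calls)
}

test_that("marker QC applies the missing/MAF/het gates with reasons", {
  n <- 20
  mono <- rep(0L, n)
  common <- rep(c(0L, 2L), each = n / 2)
  hetty <- c(rep(1L, 3), rep(0L, 8), rep(2L, 9))      # 15% het
  gappy <- c(rep(NA_integer_, 12), rep(c(0L, 2L), 4)) # 60% missing
  gm <- make_gm(cbind(mono, common, hetty, gappy))
  fl <- filter_markers(gm)
  expect_equal(fl$report$pass, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fl$report$reason, c("maf", NA, "het", "missing"))
  expect_equal(fl$genotypes$map$marker, "m2")
  # het/maf computed on non-missing calls
  expect_equal(fl$report$het[3], 0.15)
  expect_equal(fl$report$missing[4], 0.6)
})

test_that("a graded missingness ladder is cut exactly at the threshold", {
  n <- 10
  calls <- sapply(0:9, function(k)
    c(rep(NA_integer_, k), rep(c(0L, 2L), length.out = n - k)))
  gm <- make_gm(calls)
  fl <- filter_markers(gm, max_missing = 0.5, min_maf = 0, max_het = 1)
  expect_equal(sum(fl$report$pass), 6)  # fractions 0.0 .. 0.5 survive
})

test_that("marker QC is idempotent and orientation-invariant", {
  g <- simulate_genotypes(50, 200, missing_rate = 0.2, het_rate = 0.05,
                          seed = 30)
  fl1 <- filter_markers(g)
  fl2 <- filter_markers(fl1$genotypes)
  expect_true(all(fl2$report$pass))
  expect_identical(fl1$genotypes$calls, fl2$genotypes$calls)
  flipped <- new_genotype_matrix(g$lines, g$map, 2L - g$calls)
  expect_equal(filter_markers(flipped)$report$pass, fl1$report$pass)
})

test_that("a noise-free dose-linear trait is recovered exactly", {
  set.seed(31)
  g <- simulate_genotypes(40, 30, seed = 31)
  y <- as.numeric(g$calls[, 7])
  names(y) <- g$lines
  res <- glm_scan(g, y, n_pcs = 0)
  hit <- res[res$marker == g$map$marker[7], ]
  expect_equal(hit$effect, 1, tolerance = 1e-8)
  expect_lt(hit$p, 1e-30)
  expect_equal(which.min(res$p), which(res$marker == g$map$marker[7]))
})

test_that("markers with too few complete lines are skipped with a reason", {
  calls <- cbind(rep(c(0L, 2L), 10),
                 c(0L, 2L, rep(NA_integer_, 18)))
  gm <- make_gm(calls)
  y <- rnorm(20); names(y) <- gm$lines
  res <- glm_scan(gm, y, n_pcs = 0)
  expect_equal(nrow(res), 1)
  skipped <- attr(res, "skipped")
  expect_equal(skipped$marker, "m2")
  expect_equal(skipped$reason, "too_few_lines")
  expect_error(glm_scan(gm, unname(y)), "named")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(32)
  for (i in 1:25) {
    p <- runif(sample(2:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
})

test_that("consensus requires support in two environments or two models", {
  row <- function(marker, env, model, pct = 5, p = 1e-6, padj = 0.01)
    data.frame(marker = marker, env = env, model = model, effect_pct = pct,
               p = p, p_adj = padj, stringsAsFactors = FALSE)
  n_mark <- 100
  # one environment, one model: no hit
  r1 <- row("mA", "ENV1", "GLM")
  expect_equal(nrow(consensus_hits(r1, n_mark)$hits), 0)
  # two models in one environment: hit
  r2 <- rbind(row("mA", "ENV1", "GLM"), row("mA", "ENV1", "BLINK"))
  h2 <- consensus_hits(r2, n_mark)$hits
  expect_equal(h2$marker, "mA")
  expect_equal(h2$n_model, 2)
  # two environments, one model: hit
  r3 <- rbind(row("mB", "ENV1", "GLM"), row("mB", "ENV3", "GLM"))
  expect_equal(consensus_hits(r3, n_mark)$hits$marker, "mB")
  # a support failing the effect-size gate is discarded
  r4 <- rbind(row("mC", "ENV1", "GLM"),
              row("mC", "ENV2", "GLM", pct = 0.05))
  expect_equal(nrow(consensus_hits(r4, n_mark)$hits), 0)
  # the raw 1/n cutoff gates supports conjunctively
  r5 <- rbind(row("mD", "ENV1", "GLM", p = 0.02),
              row("mD", "ENV2", "GLM", p = 1e-6))
  expect_equal(nrow(consensus_hits(r5, n_mark)$hits), 0)
  expect_equal(consensus_hits(r5, n_mark, raw_cutoff = NULL)$hits$marker,
               "mD")
  # imported rows without raw p pass the raw gate
  r6 <- rbind(row("mE", "ENV1", "BLINK", p = NA),
              row("mE", "ENV2", "FARMCPU", p = NA))
  expect_equal(consensus_hits(r6, n_mark)$hits$marker, "mE")
  # duplicated (marker, env, model) rows are rejected
  expect_error(consensus_hits(rbind(r1, r1), n_mark), "duplicate")
})

test_that("external result tables join the scan output for consensus", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(
    "trait,marker,chr,pos,env,model,effect_pct,p_adj",
    "Loaf_Volume,mX,1D,100,ENV1,BLINK,12.5,0.01",
    "Loaf_Volume,mX,1D,100,ENV4,FARMCPU,9.1,0.05", sep = "\n"), path)
  ext <- read_gwas_results(path)
  expect_true(all(is.na(ext$p)))
  hits <- consensus_hits(ext, n_markers = 1000)$hits
  expect_equal(hits$marker, "mX")
  expect_equal(hits$n_env, 2)
})

test_that("allele-group t-test separates homozygote classes", {
  set.seed(33)
  dose <- rep(c(0L, 2L), each = 20)
  gm <- make_gm(cbind(dose))
  # identical class means
  y_eq <- rep(c(1, 2), 20); names(y_eq) <- gm$lines
  tt_eq <- allele_group_ttest(gm, y_eq, "m1")
  expect_true(tt_eq$ok)
  expect_equal(tt_eq$group$letter, c("a", "a"))
  # strongly separated classes
  y <- c(rnorm(20, 0, 1), rnorm(20, 5, 1)); names(y) <- gm$lines
  tt <- allele_group_ttest(gm, y, "m1")
  expect_lt(tt$p, 1e-3)
  expect_equal(tt$group$letter, c("a", "b"))
  expect_equal(tt$group$n, c(20L, 20L))
  # heterozygotes excluded
  dose_h <- dose; dose_h[1:5] <- 1L
  gm_h <- make_gm(cbind(dose_h))
  tt_h <- allele_group_ttest(gm_h, y, "m1")
  expect_equal(sum(tt_h$group$n), 35L)
  # single-line class refuses
  gm_one <- make_gm(cbind(c(0L, rep(2L, 39))))
  tt_one <- allele_group_ttest(gm_one, y, "m1")
  expect_false(tt_one$ok)
  expect_match(tt_one$reason, "fewer than 2")
  expect_error(allele_group_ttest(gm, y, "zz"), "unknown marker")
})

test_that("trait environments assemble year means, across means and BLUPs", {
  cfg <- sim_config(n_genotypes = 30, n_years = 2, n_reps = 1,
                    traits = trait_spec("t", 100, var_genotype = 4,
                                        var_error = 1),
                    seed = 34)
  sim <- simulate_phenotypes(cfg)
  envs <- trait_environments(sim$phenotypes, "t")
  expect_equal(names(envs), c("ENV1", "ENV2", "ENV3", "ENV4"))
  em <- entry_means(sim$phenotypes, "t")
  expect_equal(unname(envs$ENV3), em$across)
  expect_equal(unname(envs$ENV3), unname((envs$ENV1 + envs$ENV2) / 2))
  # BLUPs shrink toward the grand mean
  expect_lte(diff(range(envs$ENV4)), diff(range(envs$ENV3)))
  expect_equal(mean(envs$ENV4), mean(envs$ENV3), tolerance = 1e-10)
})
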