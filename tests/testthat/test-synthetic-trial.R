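test_that("residual-only configuration yields unit variance around the mean", {
  cfg <- sim_config(n_genotypes = 30, n_years = 2, n_reps = 10,
                    traits = trait_spec("t", mean = 5, var_genotype = 0,
                                        var_error = 1),
                    seed = 11)
  sim <- simulate_phenotypes(cfg)
  v <- sim$phenotypes$value
  expect_equal(length(v), 30 * 2 * 10)
  # sample variance of n iid values has sd ~ sqrt(2/(n-1))
  expect_lt(abs(var(v) - 1), 3 * sqrt(2 / (length(v) - 1)))
  expect_lt(abs(mean(v) - 5), 3 / sqrt(length(v)))
  # genotype means shrink toward the grand mean as reps grow
  gm <- tapply(v, sim$phenotypes$genotype, mean)
  expect_lt(sd(gm), 3 * sqrt(1 / 20))
})

test_that("simulation is byte-identical under a fixed seed and config", {
  cfg <- sim_config(n_genotypes = 10, n_years = 2, n_reps = c(4, 6),
                    traits = trait_spec("t", 4, var_genotype = 0.4,
                                        var_error = 1, var_gxy = 0.2,
                                        var_year = 0.3, var_rep = 0.1,
                                        scale_bounds = c(1, 7)),
                    seed = 99)
  s1 <- simulate_phenotypes(cfg)
  s2 <- simulate_phenotypes(cfg)
  expect_identical(s1, s2)
})

test_that("truth record carries the analytically implied heritabilities", {
  cfg <- sim_config(n_genotypes = 10, n_years = 2, n_reps = 1,
                    traits = trait_spec("t", 0, var_genotype = 1,
                                        var_error = 1),
                    seed = 1)
  tr <- simulate_phenotypes(cfg)$truth
  # year-as-replicate path: sigma_g^2 / (sigma_g^2 + sigma_e^2 / 2)
  expect_equal(tr$h2$t$varcomp, 1 / 1.5)

  cfg2 <- sim_config(n_genotypes = 10, n_years = 2, n_reps = 3,
                     traits = trait_spec("t", 0, var_genotype = 2,
                                         var_error = 1, var_gxy = 0.5),
                     seed = 1)
  tr2 <- simulate_phenotypes(cfg2)$truth
  e_gxy <- 1 + 3 * 0.5
  e_g <- e_gxy + 3 * 2 * 2
  expect_equal(tr2$h2$t$ms_ratio, 1 - e_gxy / e_g)
})

test_that("bounded sensory traits stay inside their scale after rounding", {
  cfg <- sim_config(n_genotypes = 40, n_years = 2, n_reps = 5,
                    traits = trait_spec("score", 4, var_genotype = 2,
                                        var_error = 4,
                                        scale_bounds = c(1, 7)),
                    seed = 5)
  v <- simulate_phenotypes(cfg)$phenotypes$value
  expect_true(all(v >= 1 & v <= 7))
  expect_true(all(v == round(v)))
})

test_that("invalid configurations are rejected", {
  expect_error(trait_spec("t", 0, var_genotype = -1, var_error = 1),
               ">= 0")
  bad_corr <- matrix(c(1, 2, 2, 1), 2)  # not PSD
  expect_error(sim_config(traits = list(trait_spec("a", 0, 1, 1),
                                        trait_spec("b", 0, 1, 1)),
                          trait_correlation = bad_corr),
               "positive semidefinite")
  expect_error(sim_config(n_genotypes = 1,
                          traits = trait_spec("t", 0, 1, 1)),
               "n_genotypes")
})

test_that("empirical variance components match the configuration", {
  # genotype-mean variance ~ sigma_g^2 + sigma_e^2 / (reps * years)
  cfg <- sim_config(n_genotypes = 200, n_years = 2, n_reps = 20,
                    traits = trait_spec("t", 0, var_genotype = 2,
                                        var_error = 1),
                    seed = 21)
  sim <- simulate_phenotypes(cfg)
  gm <- tapply(sim$phenotypes$value, sim$phenotypes$genotype, mean)
  expected <- 2 + 1 / 40
  se <- expected * sqrt(2 / 199)
  expect_lt(abs(var(gm) - expected), 3 * se)
})

test_that("genetic correlation is imposed on genotype effects", {
  corr <- matrix(c(1, 0.8, 0.8, 1), 2)
  cfg <- sim_config(n_genotypes = 400, n_years = 2, n_reps = 1,
                    traits = list(trait_spec("a", 0, 1, var_error = 1e-4),
                                  trait_spec("b", 0, 1, var_error = 1e-4)),
                    trait_correlation = corr, seed = 31)
  sim <- simulate_phenotypes(cfg)
  ma <- entry_means(sim$phenotypes, "a")$across
  mb <- entry_means(sim$phenotypes, "b")$across
  expect_lt(abs(cor(ma, mb) - 0.8), 0.06)
})

test_that("simulated SNP panels honour coding, frequency and map contracts", {
  g <- simulate_genotypes(60, 300, maf_range = c(0.5, 0.5),
                          missing_rate = 0, het_rate = 0, seed = 2)
  expect_true(all(g$calls %in% c(0L, 2L)))
  expect_lt(abs(mean(g$calls) / 2 - 0.5), 0.02)
  # determinism
  expect_identical(g, simulate_genotypes(60, 300, maf_range = c(0.5, 0.5),
                                         missing_rate = 0, het_rate = 0,
                                         seed = 2))
  # strictly increasing positions within each chromosome
  for (ch in unique(g$map$chrom)) {
    pos <- g$map$pos[g$map$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  expect_error(simulate_genotypes(10, 0), "n_markers")

  g2 <- simulate_genotypes(500, 200, missing_rate = 0.3, het_rate = 0.08,
                           seed = 3)
  expect_lt(abs(mean(is.na(g2$calls)) - 0.3), 0.02)
  expect_lt(abs(mean(g2$calls == 1L, na.rm = TRUE) - 0.08), 0.02)
})

test_that("markers simulated above the missingness threshold are filtered", {
  # 40 markers at 60% missing plus 40 clean: the filter keeps only the clean
  g_hi <- simulate_genotypes(80, 40, missing_rate = 0.6, seed = 4)
  g_lo <- simulate_genotypes(80, 40, missing_rate = 0, seed = 5)
  merged <- new_genotype_matrix(
    g_lo$lines,
    rbind(g_lo$map, data.frame(marker = paste0("hi_", g_hi$map$marker),
                               chrom = g_hi$map$chrom, pos = g_hi$map$pos)),
    cbind(g_lo$calls, g_hi$calls))
  fl <- filter_markers(merged, max_missing = 0.5, min_maf = 0, max_het = 1)
  kept_hi <- grepl("^hi_", fl$genotypes$map$marker)
  hi_missing <- colMeans(is.na(g_hi$calls))
  expect_equal(sum(kept_hi), sum(hi_missing <= 0.5))
})

test_that("inject_qtl shifts homozygote class means by the homozygote contrast", {
  cfg <- sim_config(n_genotypes = 50, n_years = 2, n_reps = 1,
                    traits = trait_spec("t", 500, var_genotype = 0,
                                        var_error = 0),
                    seed = 6)
  sim <- simulate_phenotypes(cfg)
  g <- simulate_genotypes(50, 20, maf_range = c(0.4, 0.5), seed = 7)
  q <- qtl_spec(g$map$marker[3], "t", effect_pct = 20, trait_mean = 500)
  expect_equal(q$effect, 50)  # effect_pct = 100 * |2 * effect| / mean

  # empty QTL list is the identity
  empty <- q[0, ]
  expect_identical(inject_qtl(g, sim$phenotypes, empty), sim$phenotypes)

  ph <- inject_qtl(g, sim$phenotypes, q)
  dose <- g$calls[, q$marker]
  m0 <- mean(ph$value[ph$genotype %in% g$lines[dose == 0]])
  m2 <- mean(ph$value[ph$genotype %in% g$lines[dose == 2]])
  expect_equal(m2 - m0, 2 * q$effect)
  # trait mean preserved (centred increments)
  expect_equal(mean(ph$value), 500, tolerance = 1e-10)

  expect_error(inject_qtl(g, sim$phenotypes,
                          qtl_spec("nope", "t", effect = 1)), "unknown marker")
  expect_error(inject_qtl(g, sim$phenotypes,
                          qtl_spec(g$map$marker[1], "zz", effect = 1)),
               "unknown trait")
})

test_that("truth record tracks planted QTL and serialises to JSON", {
  cfg <- sim_config(n_genotypes = 20, n_years = 2, n_reps = 1,
                    traits = trait_spec("t", 100, 1, 1), seed = 8)
  sim <- simulate_phenotypes(cfg)
  g <- simulate_genotypes(20, 10, seed = 9)
  q <- qtl_spec(g$map$marker[1], "t", effect_pct = 10, trait_mean = 100)
  upd <- inject_qtl(g, sim$phenotypes, q, truth = sim$truth)
  expect_equal(nrow(upd$truth$qtl), 1)
  expect_true(upd$truth$qtl$marker %in% g$map$marker)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(upd$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$h2$t$varcomp, sim$truth$h2$t$varcomp)
})

test_that("simulation configs round-trip through YAML and JSON", {
  cfg_list <- list(n_genotypes = 12, n_years = 2, n_reps = 3, seed = 4,
                   traits = list(list(name = "t", mean = 5,
                                      var_genotype = 1, var_error = 2)))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_list, yml)
  cfg <- read_sim_config(yml)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genotypes, 12L)
  expect_equal(cfg$traits$t$var_error, 2)

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg_list, js, auto_unbox = TRUE)
  cfg2 <- read_sim_config(js)
  expect_equal(cfg2$n_reps, cfg$n_reps)
})
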