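test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_individuals = 10000, n_variants = 1,
                    maf_range = c(0.5, 0.5), missing_rate = 0, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(mean(g$dosage) - 1), 0.02)
  expect_false(anyNA(g$dosage))

  cfg <- sim_config(n_individuals = 10000, n_variants = 1,
                    maf_range = c(0.3, 0.3), missing_rate = 0, seed = 2)
  g <- simulate_genotypes(cfg)
  counts <- table(factor(g$dosage, levels = 0:2))
  gof <- chisq.test(counts, p = c(0.49, 0.42, 0.09))
  expect_gt(gof$p.value, 0.001)
})

test_that("missingness and variant map obey the config", {
  cfg <- sim_config(n_individuals = 500, n_variants = 20,
                    missing_rate = 0.1, spacing_bp = 5000, seed = 3)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(mean(is.na(g$dosage)) - 0.1), 0.02)
  expect_equal(diff(g$variants$pos), rep(5000L, 19))
  expect_equal(unique(g$variants$chrom), "1")
})

test_that("allele-frequency estimator is unbiased", {
  cfg <- sim_config(n_individuals = 20000, n_variants = 5,
                    maf_range = c(0.2, 0.2), missing_rate = 0.05, seed = 4)
  g <- simulate_genotypes(cfg)
  maf_hat <- apply(g$dosage, 2, function(d) mean(d, na.rm = TRUE) / 2)
  expect_true(all(abs(maf_hat - 0.2) < 0.01))
})

test_that("ld_pairs induce high r2 proxies", {
  cfg <- sim_config(n_individuals = 4000, n_variants = 4, missing_rate = 0,
                    maf_range = c(0.3, 0.3), seed = 5,
                    ld_pairs = data.frame(source = "snp00001",
                                          target = "snp00002",
                                          flip_prob = 0.02))
  g <- simulate_genotypes(cfg)
  expect_gt(ld_r2(g$dosage[, 1], g$dosage[, 2]), 0.8)
  expect_lt(ld_r2(g$dosage[, 3], g$dosage[, 4]), 0.01)
})

test_that("covariates have the configured support and rates", {
  cfg <- sim_config(n_individuals = 50000, n_variants = 0,
                    male_fraction = 0.46, seed = 6)
  cov <- simulate_covariates(cfg)
  expect_gte(min(cov$age), 40)
  expect_lte(max(cov$age), 69)
  expect_lt(abs(mean(cov$sex) - 0.46), 0.01)
  expect_true(all(paste0("pc", 1:10) %in% names(cov)))
  cfg0 <- sim_config(n_individuals = 100, n_variants = 0, male_fraction = 0,
                     seed = 7)
  expect_true(all(simulate_covariates(cfg0)$sex == 0))
})

test_that("degenerate noise reduces the phenotype to its linear predictor", {
  cfg <- sim_config(n_individuals = 50, n_variants = 2, noise_sd = 1e-12,
                    mu = 0, age_effect = 1, sex_effect = 0, array_effect = 0,
                    pc_effects = 0, seed = 8)
  cohort <- simulate_cohort(cfg)
  expect_equal(cohort$phenotypes$pheno, as.numeric(cohort$phenotypes$age),
               tolerance = 1e-9)
})

test_that("constant per-allele effects are recovered in every stratum", {
  cfg <- sim_config(n_individuals = 20000, n_variants = 5, noise_sd = 1,
                    missing_rate = 0, seed = 9,
                    effects = effect_spec("snp00003", base_effect = 0.3,
                                          age_slope = 0))
  cohort <- simulate_cohort(cfg)
  strata <- assign_age_quartiles(cohort$phenotypes$age, 4)
  stats <- run_stratified_gwas(cohort$genotypes, cohort$phenotypes, strata)
  for (s in names(stats)) {
    row <- stats[[s]][stats[[s]]$snp == "snp00003", ]
    expect_lt(abs(row$beta - 0.3), 3 * row$se)
  }
})

test_that("an age slope produces stratum betas tracking stratum mean age", {
  cfg <- sim_config(n_individuals = 20000, n_variants = 5, noise_sd = 1,
                    missing_rate = 0, seed = 10,
                    effects = effect_spec("snp00002", base_effect = 0,
                                          age_slope = 0.02,
                                          reference_age = 55))
  cohort <- simulate_cohort(cfg)
  strata <- assign_age_quartiles(cohort$phenotypes$age, 4)
  stats <- run_stratified_gwas(cohort$genotypes, cohort$phenotypes, strata)
  betas <- vapply(stats, function(s) s$beta[s$snp == "snp00002"], 0)
  ses <- vapply(stats, function(s) s$se[s$snp == "snp00002"], 0)
  expected <- 0.02 * (strata$summary$age_mean - 55)
  expect_true(all(abs(betas - expected) < 3 * ses))
  expect_true(all(diff(betas) > 0))  # monotone beta-vs-age trend
})

test_that("phenotype variance decomposes into genetic, covariate and noise parts", {
  cfg <- sim_config(n_individuals = 50000, n_variants = 2, noise_sd = 2,
                    missing_rate = 0, maf_range = c(0.3, 0.3), seed = 11,
                    effects = effect_spec("snp00001", base_effect = 0.5))
  cohort <- simulate_cohort(cfg)
  age_var <- var(cohort$phenotypes$age)
  expected <- cfg$age_effect^2 * age_var +
    cfg$sex_effect^2 * 0.46 * 0.54 + cfg$array_effect^2 * 0.25 +
    sum(cfg$pc_effects^2) + 0.5^2 * 2 * 0.3 * 0.7 + cfg$noise_sd^2
  expect_lt(abs(var(cohort$phenotypes$pheno) - expected) / expected, 0.05)
})

test_that("truth table mirrors the planted effects and their variants exist", {
  expect_equal(nrow(truth_table(sim_config())), 0L)
  cfg <- sim_config(n_variants = 10,
                    effects = list(effect_spec("snp00001", 0.1, 0),
                                   effect_spec("snp00004", 0, 0.02),
                                   effect_spec("snp00009", 0, 0)))
  tt <- truth_table(cfg)
  expect_equal(tt$id, c("snp00001", "snp00004", "snp00009"))
  expect_equal(tt$causal, c(TRUE, TRUE, FALSE))
  g <- simulate_genotypes(cfg)
  expect_true(all(tt$id %in% g$variants$id))
})

test_that("composite traits follow their defining formulas", {
  ct <- derive_composite_traits(81, 1.8, 88.10, 103.06)
  expect_equal(ct$bmi, 25)
  expect_equal(ct$whr, 0.8548, tolerance = 1e-4)
  expect_equal(derive_composite_traits(70, 1.7, 90, 90)$whr, 1)
  expect_error(derive_composite_traits(70, 0, 90, 90), "height")
  expect_error(derive_composite_traits(70, 1.7, 90, 0), "hip")
})

test_that("write_dataset emits a round-trippable trio and is seed-deterministic", {
  cfg <- sim_config(n_individuals = 30, n_variants = 8, seed = 12,
                    effects = effect_spec("snp00002", 0.2, 0.01))
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(cohort, dir)
  g2 <- read_vcf(paths["vcf"])
  expect_identical(unname(g2$dosage), unname(cohort$genotypes$dosage))
  tab <- read_pheno_covar(paths["pheno"], "pheno", c("age", "sex"))
  expect_equal(tab$pheno, cohort$phenotypes$pheno, tolerance = 1e-9)
  tt <- read.table(paths["truth"], header = TRUE, sep = "\t")
  expect_equal(tt$id, "snp00002")
  # same seed, same dataset
  cohort2 <- simulate_cohort(cfg)
  expect_identical(cohort2$genotypes$dosage, cohort$genotypes$dosage)
  expect_equal(cohort2$phenotypes$pheno, cohort$phenotypes$pheno)
})
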