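test_that("Spearman correlation equals the rank-then-Pearson oracle", {
  expect_equal(spearman_correlation(1:10, 1:10), 1)
  expect_equal(spearman_correlation(1:10, 10:1), -1)
  expect_equal(spearman_correlation(c(1, 2, 2, 4), c(3, 1, 4, 4)),
               spearman_oracle(c(1, 2, 2, 4), c(3, 1, 4, 4)),
               tolerance = 1e-12)
  set.seed(71)
  for (rep in 1:10) {
    x <- sample(1:6, 30, TRUE)   # plenty of ties
    y <- x + rnorm(30)
    expect_equal(spearman_correlation(x, y), spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("differential t follows its formula and symmetries", {
  expect_equal(differential_t(0.3, 0.1, 0.3, 0.2), 0)
  # swap antisymmetry across a grid of r
  for (r in c(-0.5, 0, 0.3, 0.9)) {
    t12 <- differential_t(0.5, 0.1, -0.2, 0.15, r)
    t21 <- differential_t(-0.2, 0.15, 0.5, 0.1, r)
    expect_equal(t12, -t21, tolerance = 1e-12)
  }
  # direct arithmetic on a printed-scale example
  expect_equal(differential_t(-0.021, 0.043, -0.325, 0.040, 0),
               0.304 / sqrt(0.043^2 + 0.040^2), tolerance = 1e-12)
  expect_equal(differential_t(-0.021, 0.043, -0.325, 0.040, 0), 5.176,
               tolerance = 1e-4)
  # r = 0 reduces to the classical two-sample z
  expect_equal(differential_t(1, 0.2, 0.5, 0.3, 0),
               (1 - 0.5) / sqrt(0.2^2 + 0.3^2), tolerance = 1e-12)
  expect_error(differential_t(1, 0, 0, 1), "positive")
  expect_error(differential_t(1, 0.1, 0, 0.1, r = 1), "degenerate")
})

test_that("differential p-value is a stable standard-normal tail", {
  expect_equal(differential_pvalue(0), 1)
  expect_equal(differential_pvalue(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(differential_pvalue(5.176), 2.266e-7, tolerance = 1e-3)
  expect_equal(differential_pvalue(-5.176), differential_pvalue(5.176))
  expect_gt(differential_pvalue(37), 0)  # survival function keeps precision
  expect_equal(differential_pvalue(37), 2 * pnorm(37, lower.tail = FALSE))
})

test_that("p_diff is monotone decreasing in r for unequal betas", {
  rs <- seq(-0.9, 0.99, by = 0.05)
  ps <- differential_pvalue(vapply(rs, function(r)
    differential_t(0.4, 0.1, 0.1, 0.12, r), 0))
  expect_true(all(diff(ps) < 0))
})

test_that("bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 15), 0.05 / 15)
  expect_equal(round(bonferroni_threshold(0.05, 15), 5), 3.33e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("run_differential handles identical tables, tiers and group swaps", {
  s <- tiny_stats(sprintf("v%d", 1:5), beta = c(0.5, -0.2, 0.1, 0, 0.3),
                  se = rep(0.05, 5))
  d <- run_differential(s, s)
  expect_true(all(d$t == 0))
  expect_true(all(d$p_diff == 1))
  # a large standardized difference reaches the genome-wide tier
  s2 <- s; s2$beta <- s$beta - c(1, 0, 0.36, 0, 0)
  d2 <- run_differential(s, s2, r_override = 0)
  expect_equal(d2$tier[d2$snp == "v1"], "genome-wide")
  expect_equal(d2$tier[d2$snp == "v3"], "suggestive")
  expect_equal(d2$tier[d2$snp == "v2"], "none")
  # group-label symmetry: t negates, p_diff unchanged
  d21 <- run_differential(s2, s, r_override = 0)
  expect_equal(d21$t, -d2$t, tolerance = 1e-12)
  expect_equal(d21$p_diff, d2$p_diff, tolerance = 1e-12)
})

test_that("allele harmonization flips swapped records and drops mismatches", {
  s1 <- tiny_stats(c("a", "b", "c"), beta = c(0.4, 0.2, 0.1),
                   se = rep(0.1, 3))
  s2 <- tiny_stats(c("a", "b", "c"), beta = c(0.4, -0.2, 0.1),
                   se = rep(0.1, 3))
  s2$a1[2] <- "G"; s2$a2[2] <- "A"      # swapped alleles: flip beta
  s2$a1[3] <- "T"; s2$a2[3] <- "C"      # incompatible: exclude
  d <- run_differential(s1, s2, r_override = 0)
  expect_equal(d$snp, c("a", "b"))
  expect_equal(attr(d, "n_excluded"), 1L)
  expect_equal(d$t, c(0, 0))
})

test_that("pairwise correlation selects the least-correlated pair with age-gap tie-break", {
  set.seed(81)
  base <- rnorm(50)
  stats <- list(Q1 = tiny_stats(sprintf("v%d", 1:50), base, rep(0.1, 50)),
                Q2 = tiny_stats(sprintf("v%d", 1:50), base + rnorm(50, 0, 0.1),
                                rep(0.1, 50)),
                Q3 = tiny_stats(sprintf("v%d", 1:50), base + rnorm(50, 0, 0.4),
                                rep(0.1, 50)),
                Q4 = tiny_stats(sprintf("v%d", 1:50), rnorm(50), rep(0.1, 50)))
  rep_ <- pairwise_beta_correlation(stats)
  expect_true(isSymmetric(rep_$r_matrix))
  expect_true(all(abs(rep_$r_matrix) <= 1))
  expect_equal(sum(rep_$pairs$selected), 1L)
  # Q4 is independent noise, so the selected pair involves Q4
  expect_true("Q4" %in% rep_$selected)
  # exact tie: both pairs r = 1, widest gap wins
  tied <- list(Q1 = tiny_stats(c("x", "y", "z"), c(1, 2, 3), rep(0.1, 3)),
               Q2 = tiny_stats(c("x", "y", "z"), c(2, 4, 6), rep(0.1, 3)),
               Q3 = tiny_stats(c("x", "y", "z"), c(1, 2, 3), rep(0.1, 3)))
  expect_equal(pairwise_beta_correlation(tied)$selected, c("Q1", "Q3"))
})

test_that("shared true effects raise inter-stratum correlation", {
  set.seed(91)
  shared <- rnorm(100, 0, 0.5)
  noise1 <- rnorm(100, 0, 0.2); noise2 <- rnorm(100, 0, 0.2)
  null_r <- spearman_correlation(noise1, noise2)
  shared_r <- spearman_correlation(shared + noise1, shared + noise2)
  expect_gt(shared_r, null_r + 0.3)
})

test_that("null-simulation pairwise correlations are small and Q1-Q4 near-minimal", {
  cfg <- sim_config(n_individuals = 2400, n_variants = 120, seed = 15,
                    missing_rate = 0)
  cohort <- simulate_cohort(cfg)
  strata <- assign_age_quartiles(cohort$phenotypes$age, 4)
  stats <- run_stratified_gwas(cohort$genotypes, cohort$phenotypes, strata)
  rep_ <- pairwise_beta_correlation(stats)
  offdiag <- rep_$r_matrix[upper.tri(rep_$r_matrix)]
  expect_true(all(abs(offdiag) < 0.35))
  r14 <- rep_$r_matrix["Q1", "Q4"]
  expect_lte(min(rep_$pairs$r), r14)
  expect_lt(r14 - min(rep_$pairs$r), 0.35)
})
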