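# Synthetic-cohort generator: HWE genotypes, biobank-like covariates, and
# quantitative phenotypes whose per-allele effects vary linearly with age.

#' Specify an age-varying allelic effect
#'
#' The per-allele effect of the variant on the trait is
#' `base_effect + age_slope * (age - reference_age)` trait units per copy of
#' the effect allele, so `base_effect` is the effect at `reference_age` and
#' `age_slope` controls how fast the effect changes per year of age.
#'
#' @param id variant id the effect attaches to.
#' @param base_effect effect at `reference_age` (trait units per allele).
#' @param age_slope change in effect per year of age.
#' @param reference_age age (years) at which the effect equals `base_effect`.
#' @return A list of class `"effect_spec"`.
#' @export
#' @examples
#' effect_spec("snp00001", base_effect = 0, age_slope = 0.02)
effect_spec <- function(id, base_effect = 0, age_slope = 0, reference_age = 55) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(list(id = id, base_effect = base_effect, age_slope = age_slope,
                 reference_age = reference_age), class = "effect_spec")
}

#' Simulation configuration
#'
#' Defaults emulate a UK-Biobank-like cohort at configurable scale: integer
#' ages uniform on 40-69 years, a 46% male share, a balanced two-array
#' design, 10 standard-normal principal-component covariates, Hardy-Weinberg
#' genotypes at uniform MAFs, and a BMI-like trait scale (baseline 27,
#' +0.05 units/year of age, residual SD 4).
#'
#' @param n_individuals cohort size.
#' @param n_variants number of simulated variants.
#' @param maf_range range the per-variant minor allele frequency is drawn
#'   from, within (0, 0.5].
#' @param missing_rate per-entry probability a hard call is missing.
#' @param age_range inclusive integer age range (years).
#' @param age_weights optional per-age sampling weights (length
#'   `diff(age_range) + 1`) to skew the age distribution; uniform when NULL.
#' @param male_fraction P(sex = 1).
#' @param n_pcs number of principal-component covariates.
#' @param mu trait intercept.
#' @param age_effect,sex_effect,array_effect covariate effects on the trait.
#' @param pc_effects per-PC effects (recycled to `n_pcs`).
#' @param effects list of [effect_spec()] objects (the truth table).
#' @param noise_sd residual SD of the trait (> 0).
#' @param spacing_bp base-pair spacing between consecutive simulated variants
#'   on the single synthetic chromosome.
#' @param ld_pairs optional data.frame (`source`, `target`, `flip_prob`)
#'   inducing LD: the target variant's dosages start as a copy of the
#'   source's, and each entry is independently re-drawn from the target's own
#'   HWE distribution with probability `flip_prob` (small `flip_prob` means
#'   high r-squared).
#' @param seed master seed; each stage derives its own sub-seed via
#'   [derive_seed()].
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 2000, n_variants = 100,
                       maf_range = c(0.05, 0.5), missing_rate = 0.01,
                       age_range = c(40L, 69L), age_weights = NULL,
                       male_fraction = 0.46, n_pcs = 10,
                       mu = 27, age_effect = 0.05, sex_effect = 0.5,
                       array_effect = 0.1, pc_effects = 0.05,
                       effects = list(), noise_sd = 4,
                       spacing_bp = 5000L, ld_pairs = NULL, seed = 1L) {
  stopifnot(n_individuals >= 1, n_variants >= 0,
            length(maf_range) == 2L, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            length(age_range) == 2L, age_range[1] <= age_range[2],
            male_fraction >= 0, male_fraction <= 1,
            n_pcs >= 0, noise_sd > 0, spacing_bp >= 1)
  if (!is.null(age_weights))
    stopifnot(length(age_weights) == diff(age_range) + 1L, all(age_weights >= 0))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    if (e$reference_age < age_range[1] || e$reference_age > age_range[2])
      stop_domain("reference_age of effect for ", e$id,
                  " lies outside the cohort age range")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, missing_rate = missing_rate,
                 age_range = as.integer(age_range), age_weights = age_weights,
                 male_fraction = male_fraction, n_pcs = as.integer(n_pcs),
                 mu = mu, age_effect = age_effect, sex_effect = sex_effect,
                 array_effect = array_effect,
                 pc_effects = rep_len(pc_effects, n_pcs),
                 effects = effects, noise_sd = noise_sd,
                 spacing_bp = as.integer(spacing_bp), ld_pairs = ld_pairs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

variant_ids <- function(m) sprintf("snp%05d", seq_len(m))

#' Simulate Hardy-Weinberg genotypes
#'
#' Each variant's MAF is drawn uniformly from `config$maf_range`; dosages are
#' two independent allele draws (`Binomial(2, maf)`), i.e. exact HWE
#' proportions in expectation. Entries are masked missing with probability
#' `missing_rate`. Variants sit on one synthetic chromosome at fixed
#' `spacing_bp` intervals so clumping windows are meaningful. Optional
#' `ld_pairs` copy a source variant's dosages into a target with a per-entry
#' re-draw probability, giving tunable LD blocks.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()]; the drawn MAFs are attached as attribute
#'   `"maf"`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals; m <- config$n_variants
  set.seed(derive_seed(config$seed, "genotypes"))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  if (!is.null(config$ld_pairs)) {
    ids <- variant_ids(m)
    for (k in seq_len(nrow(config$ld_pairs))) {
      src <- match(config$ld_pairs$source[k], ids)
      tgt <- match(config$ld_pairs$target[k], ids)
      if (is.na(src) || is.na(tgt))
        stop_domain("ld_pairs references unknown variant id")
      redraw <- stats::runif(n) < config$ld_pairs$flip_prob[k]
      dos[, tgt] <- ifelse(redraw, stats::rbinom(n, 2L, maf[tgt]), dos[, src])
    }
  }
  if (config$missing_rate > 0)
    dos[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  rownames(dos) <- sprintf("id%06d", seq_len(n))
  g <- genotype_matrix(dos,
                       data.frame(id = variant_ids(m), chrom = "1",
                                  pos = 1L + (seq_len(m) - 1L) * config$spacing_bp,
                                  a1 = "A", a2 = "G", stringsAsFactors = FALSE))
  attr(g, "maf") <- maf
  g
}

#' Simulate covariates
#'
#' Ages are uniform integers on `age_range` (optionally reweighted by
#' `age_weights`), sex is Bernoulli(`male_fraction`), the genotyping-array
#' indicator Bernoulli(0.5), and PCs are standard normal.
#'
#' @param config a [sim_config()].
#' @return A data.frame with columns `id, age, sex, array, pc1..pcK`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  set.seed(derive_seed(config$seed, "covariates"))
  ages_support <- seq(config$age_range[1], config$age_range[2])
  age <- sample(ages_support, n, replace = TRUE, prob = config$age_weights)
  cov <- data.frame(id = sprintf("id%06d", seq_len(n)),
                    age = as.integer(age),
                    sex = stats::rbinom(n, 1L, config$male_fraction),
                    array = stats::rbinom(n, 1L, 0.5),
                    stringsAsFactors = FALSE)
  if (config$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n * config$n_pcs), nrow = n)
    colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))
    cov <- cbind(cov, pcs)
  }
  cov
}

#' Simulate a quantitative phenotype
#'
#' The generative model is
#' `y = mu + age_effect*age + sex_effect*sex + array_effect*array +
#'  sum_k pc_effects[k]*pc_k +
#'  sum_j g_j * (base_effect_j + age_slope_j * (age - reference_age_j)) +
#'  Normal(0, noise_sd^2)`.
#' Missing dosages contribute their variant's mean observed dosage, so
#' genotype missingness does not shift the phenotype mean.
#'
#' @param genotypes a `genotype_matrix`.
#' @param covariates data.frame from [simulate_covariates()].
#' @param config a [sim_config()].
#' @return Numeric phenotype vector, one value per individual.
#' @export
simulate_phenotype <- function(genotypes, covariates, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"),
            nrow(covariates) == n_individuals(genotypes))
  n <- nrow(covariates)
  set.seed(derive_seed(config$seed, "phenotype"))
  y <- config$mu + config$age_effect * covariates$age +
    config$sex_effect * covariates$sex +
    config$array_effect * covariates$array
  if (config$n_pcs > 0) {
    pcs <- as.matrix(covariates[paste0("pc", seq_len(config$n_pcs))])
    y <- y + drop(pcs %*% config$pc_effects)
  }
  for (e in config$effects) {
    j <- match(e$id, genotypes$variants$id)
    if (is.na(j)) stop_domain("effect references unknown variant: ", e$id)
    g <- genotypes$dosage[, j]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    y <- y + g * (e$base_effect + e$age_slope * (covariates$age - e$reference_age))
  }
  y + stats::rnorm(n, 0, config$noise_sd)
}

#' The effects actually used by the generator
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per planted effect
#'   (`id, base_effect, age_slope, reference_age, causal`).
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$effects))
    return(data.frame(id = character(0), base_effect = numeric(0),
                      age_slope = numeric(0), reference_age = numeric(0),
                      causal = logical(0)))
  data.frame(id = vapply(config$effects, `[[`, "", "id"),
             base_effect = vapply(config$effects, `[[`, 0, "base_effect"),
             age_slope = vapply(config$effects, `[[`, 0, "age_slope"),
             reference_age = vapply(config$effects, `[[`, 0, "reference_age"),
             causal = vapply(config$effects, function(e)
               e$base_effect != 0 || e$age_slope != 0, TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_covariates()] and [simulate_phenotype()] with the config's
#' derived sub-seeds.
#'
#' @param config a [sim_config()].
#' @return List with elements `genotypes` (a `genotype_matrix`), `phenotypes`
#'   (covariate data.frame plus a `pheno` column) and `truth`
#'   (the [truth_table()]).
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  cov <- simulate_covariates(config)
  cov$pheno <- simulate_phenotype(g, cov, config)
  list(genotypes = g, phenotypes = cov, truth = truth_table(config))
}

#' Derived anthropometric traits
#'
#' Body mass index is weight divided by squared height; waist-hip ratio is
#' waist circumference divided by hip circumference.
#'
#' @param weight body weight in kg.
#' @param height standing height in metres.
#' @param wc waist circumference (cm).
#' @param hc hip circumference (cm).
#' @return List with numeric vectors `bmi` (kg/m^2) and `whr` (unitless).
#' @export
#' @examples
#' derive_composite_traits(81, 1.8, 88.1, 103.06)
derive_composite_traits <- function(weight, height, wc, hc) {
  if (any(height <= 0, na.rm = TRUE)) stop_domain("height must be positive")
  if (any(hc <= 0, na.rm = TRUE)) stop_domain("hip circumference must be positive")
  list(bmi = weight / height^2, whr = wc / hc)
}

#' Write a simulated dataset to disk
#'
#' Emits the cohort in the package's interchange formats: a VCF of hard
#' calls, a PLINK-style phenotype/covariate table, and the truth table as
#' TSV.
#'
#' @param cohort list as returned by [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             pheno = file.path(out_dir, "pheno.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_vcf(cohort$genotypes, paths["vcf"])
  write_pheno_covar(cohort$phenotypes, paths["pheno"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
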