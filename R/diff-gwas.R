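#' Fit an age-stratified differential-effect GWAS
#'
#' The package's central model fit. The cohort is QC-filtered at the variant
#' level, split into `k` age strata, scanned with a covariate-adjusted
#' linear association model within each stratum, the least-correlated pair
#' of strata (by Spearman correlation of their beta vectors) is selected,
#' the per-variant difference in betas is tested with the
#' correlation-corrected t-statistic against a standard-normal reference,
#' and genome-wide significant variants are clumped into lead loci by LD and
#' distance.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes data.frame with columns `id`, the covariates and the
#'   phenotype; one row per genotyped individual.
#' @param phenotype name of the phenotype column.
#' @param covariates covariate column names for the within-stratum design;
#'   default `age, sex, array, pc1..pc10` (intersected with what exists).
#' @param k number of age strata.
#' @param pair either `"auto"` (select the least-correlated pair) or a
#'   character vector of two stratum labels, e.g. `c("Q1", "Q4")`.
#' @param qc a [qc_thresholds()], or NULL to skip variant QC.
#' @param r_override optional fixed inter-stratum correlation.
#' @param genomewide,suggestive significance thresholds on `p_diff`.
#' @param r2_threshold,merge_window clumping parameters (LD cutoff and
#'   lead-merge window in bp).
#' @return An object of class `"diff_gwas"`: a list with elements
#'   `qc_report`, `strata` (stratum assignment), `stats` (per-stratum
#'   summary statistics), `correlation` (pairwise correlation report),
#'   `pair`, `diff` (the differential table), `loci`, `params` and `call`.
#' @seealso [summary.diff_gwas()], [plot.diff_gwas()], [run_pipeline()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 400, n_variants = 30, seed = 7,
#'                   effects = effect_spec("snp00005", age_slope = 0.3))
#' cohort <- simulate_cohort(cfg)
#' fit <- diff_gwas(cohort$genotypes, cohort$phenotypes)
#' fit
#' head(coef(fit))
diff_gwas <- function(genotypes, phenotypes, phenotype = "pheno",
                      covariates = NULL, k = 4, pair = "auto",
                      qc = qc_thresholds(), r_override = NULL,
                      genomewide = 5e-8, suggestive = 1e-6,
                      r2_threshold = 0.1, merge_window = 250000) {
  cl <- match.call()
  stopifnot(inherits(genotypes, "genotype_matrix"),
            is.data.frame(phenotypes), "id" %in% names(phenotypes))
  if (!is.null(qc)) {
    qcres <- filter_snps(genotypes, qc)
    genotypes <- qcres$genotypes
    qc_report <- qcres$report
  } else qc_report <- NULL
  gid <- rownames(genotypes$dosage)
  if (!is.null(gid)) {
    idx <- match(gid, phenotypes$id)
    if (anyNA(idx)) stop_domain("phenotype table does not cover all genotyped ids")
    phenotypes <- phenotypes[idx, , drop = FALSE]
  }
  strata <- assign_age_quartiles(phenotypes$age, k = k)
  stats <- run_stratified_gwas(genotypes, phenotypes, strata,
                               phenotype = phenotype, covariates = covariates)
  correlation <- pairwise_beta_correlation(stats)
  if (identical(pair, "auto")) pair <- correlation$selected
  stopifnot(length(pair) == 2L, all(pair %in% names(stats)))
  diff <- run_differential(stats[[pair[1L]]], stats[[pair[2L]]],
                           r_override = r_override, genomewide = genomewide,
                           suggestive = suggestive)
  loci <- greedy_clump(diff, genotypes, p_threshold = genomewide,
                       r2_threshold = r2_threshold,
                       merge_window = merge_window)
  structure(list(qc_report = qc_report, strata = strata, stats = stats,
                 correlation = correlation, pair = pair, diff = diff,
                 loci = loci,
                 params = list(phenotype = phenotype, k = k,
                               genomewide = genomewide,
                               suggestive = suggestive,
                               r2_threshold = r2_threshold,
                               merge_window = merge_window),
                 call = cl),
            class = "diff_gwas")
}

#' @export
print.diff_gwas <- function(x, ...) {
  cat("Age-stratified differential-effect GWAS\n")
  cat("  strata:", paste(sprintf("%s (n=%d, %g-%g y)", x$strata$summary$stratum,
                                 x$strata$summary$n, x$strata$summary$age_min,
                                 x$strata$summary$age_max), collapse = ", "), "\n")
  cat("  variants tested:", nrow(x$diff), "\n")
  cat(sprintf("  compared pair: %s vs %s (Spearman r = %.4f)\n",
              x$pair[1], x$pair[2], attr(x$diff, "r")))
  cat("  genome-wide significant:", sum(x$diff$tier == "genome-wide", na.rm = TRUE),
      " suggestive:", sum(x$diff$tier == "suggestive", na.rm = TRUE), "\n")
  cat("  lead loci:", length(x$loci), "\n")
  invisible(x)
}

#' Summarize a differential-effect GWAS fit
#'
#' @param object a `"diff_gwas"` fit.
#' @param ... unused.
#' @return A list of class `"summary.diff_gwas"` with the stratum table,
#'   correlation matrix, tier counts, genomic-inflation factor of the
#'   differential p-values, and the lead-locus table.
#' @export
summary.diff_gwas <- function(object, ...) {
  p <- object$diff$p_diff
  structure(list(strata = object$strata$summary,
                 r_matrix = object$correlation$r_matrix,
                 pair = object$pair,
                 n_variants = nrow(object$diff),
                 tiers = table(factor(object$diff$tier,
                                      levels = c("genome-wide", "suggestive",
                                                 "none"))),
                 lambda = attr(qq_table(p[!is.na(p)]), "lambda"),
                 loci = as.data.frame(object$loci)),
            class = "summary.diff_gwas")
}

#' @export
print.summary.diff_gwas <- function(x, ...) {
  cat("Strata:\n"); print(x$strata, row.names = FALSE)
  cat("\nSpearman correlation of per-stratum betas:\n")
  print(round(x$r_matrix, 4))
  cat("\nCompared pair:", paste(x$pair, collapse = " vs "), "\n")
  cat("Variants tested:", x$n_variants,
      sprintf("  (genomic inflation lambda = %.3f)\n", x$lambda))
  print(x$tiers)
  cat("\nLead loci:\n")
  if (nrow(x$loci)) print(x$loci, row.names = FALSE) else cat("  none\n")
  invisible(x)
}

#' Per-stratum effect sizes of a fit
#'
#' @param object a `"diff_gwas"` fit.
#' @param ... unused.
#' @return Matrix of per-allele betas, variants x strata.
#' @export
coef.diff_gwas <- function(object, ...) {
  betas <- vapply(object$stats, `[[`, numeric(nrow(object$stats[[1]])), "beta")
  rownames(betas) <- object$stats[[1]]$snp
  betas
}

#' Manhattan or QQ plot of the differential p-values
#'
#' @param x a `"diff_gwas"` fit.
#' @param type `"manhattan"` or `"qq"`.
#' @param ... passed to [plot()].
#' @return The underlying plot table, invisibly.
#' @export
plot.diff_gwas <- function(x, type = c("manhattan", "qq"), ...) {
  type <- match.arg(type)
  if (type == "manhattan") {
    tab <- manhattan_table(x$diff)
    plot(tab$cumpos, tab$neglog10p, pch = 20,
         col = ifelse(match(tab$chrom, unique(tab$chrom)) %% 2, "grey30",
                      "steelblue"),
         xlab = "genomic position", ylab = expression(-log[10](p[diff])), ...)
    graphics::abline(h = attr(tab, "thresholds")["genomewide"], col = "red")
    graphics::abline(h = attr(tab, "thresholds")["suggestive"], col = "blue",
                     lty = 2)
  } else {
    p <- x$diff$p_diff
    tab <- qq_table(p[!is.na(p)])
    plot(tab$expected, tab$observed, pch = 20,
         xlab = expression(expected ~ -log[10](p)),
         ylab = expression(observed ~ -log[10](p)), ...)
    graphics::abline(0, 1, col = "red")
  }
  invisible(tab)
}
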