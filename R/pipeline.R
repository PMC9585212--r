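# File-based orchestration: YAML configuration in, TSV/VCF artifacts out.

#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()].
#' Every field mirrors a YAML key, so a config can equally be read from a
#' file with [read_pipeline_config()].
#'
#' @param out_dir output directory.
#' @param seed master seed; stage sub-seeds are derived with [derive_seed()].
#' @param simulate list of [sim_config()] arguments (or NULL to read inputs
#'   from `vcf`/`pheno` instead).
#' @param vcf,pheno input file paths when not simulating.
#' @param phenotype phenotype column name.
#' @param covariates covariate column names.
#' @param qc list with `max_missing_rate`, `min_maf`, `min_hwe_p`.
#' @param k number of age strata.
#' @param pair `"auto"` or two stratum labels.
#' @param genomewide,suggestive significance thresholds.
#' @param r2_threshold,merge_window clumping parameters.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = ".", seed = 1L, simulate = list(),
                            vcf = NULL, pheno = NULL, phenotype = "pheno",
                            covariates = NULL, qc = list(), k = 4,
                            pair = "auto", genomewide = 5e-8,
                            suggestive = 1e-6, r2_threshold = 0.1,
                            merge_window = 250000) {
  stopifnot(k >= 2, genomewide > 0, genomewide <= 1, suggestive > 0,
            suggestive <= 1, r2_threshold > 0, r2_threshold <= 1,
            merge_window >= 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, vcf = vcf, pheno = pheno,
                 phenotype = phenotype, covariates = covariates,
                 qc = qc, k = k, pair = pair, genomewide = genomewide,
                 suggestive = suggestive, r2_threshold = r2_threshold,
                 merge_window = merge_window),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_domain("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$simulate$effects))
    raw$simulate$effects <- lapply(raw$simulate$effects, function(e)
      do.call(effect_spec, e))
  do.call(pipeline_config, raw)
}

pipe_log <- function(stage, ...) {
  message(sprintf("[diffgwas:%s] %s", stage, paste0(...)))
}

#' Run the full pipeline and write its artifacts
#'
#' Executes simulate (or load) -> QC -> stratify -> per-stratum GWAS ->
#' correlation -> differential test -> clump -> report, logging record
#' counts per stage, and writes every intermediate table under
#' `config$out_dir`: the simulated dataset (VCF, phenotype table, truth
#' table), the QC report, the stratum assignment, one summary-statistics
#' TSV per stratum (`<trait>.<stratum>.assoc.tsv`), the correlation table,
#' the differential table, the locus/member tables and Manhattan/QQ tables.
#' Outputs are deterministic given the seed.
#'
#' @param config a `"pipeline_config"` or path to a YAML file.
#' @param out_dir,seed optional overrides of the config fields.
#' @return The fitted [diff_gwas()] object, invisibly; file paths in
#'   attribute `"paths"`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_domain("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  }
  if (is.null(config$vcf)) {
    cohort <- run_stage("simulate", {
      scfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
      simulate_cohort(scfg)
    })
    pipe_log("simulate", n_individuals(cohort$genotypes), " individuals, ",
             n_variants(cohort$genotypes), " variants, ",
             nrow(cohort$truth), " planted effects")
    paths <- c(paths, run_stage("simulate", write_dataset(cohort, config$out_dir)))
    genotypes <- cohort$genotypes
    pheno <- cohort$phenotypes
  } else {
    genotypes <- run_stage("load", read_vcf(config$vcf))
    pheno <- run_stage("load", read_pheno_covar(config$pheno,
                                                config$phenotype,
                                                config$covariates %||%
                                                  character(0)))
    pipe_log("load", n_individuals(genotypes), " individuals, ",
             n_variants(genotypes), " variants")
  }
  thresholds <- do.call(qc_thresholds, config$qc)
  fit <- run_stage("analysis", diff_gwas(
    genotypes, pheno, phenotype = config$phenotype,
    covariates = config$covariates, k = config$k, pair = config$pair,
    qc = thresholds, genomewide = config$genomewide,
    suggestive = config$suggestive, r2_threshold = config$r2_threshold,
    merge_window = config$merge_window))
  pipe_log("qc", attr(fit$qc_report, "n_out"), " of ",
           attr(fit$qc_report, "n_in"), " variants retained")
  pipe_log("gwas", "strata: ",
           paste(sprintf("%s n=%d", fit$strata$summary$stratum,
                         fit$strata$summary$n), collapse = ", "))
  pipe_log("diff", "pair ", paste(fit$pair, collapse = "/"), ", r=",
           sprintf("%.4f", attr(fit$diff, "r")), ", ",
           sum(fit$diff$tier == "genome-wide", na.rm = TRUE),
           " genome-wide significant")
  pipe_log("clump", length(fit$loci), " lead loci")
  report_paths <- run_stage("report", {
    od <- config$out_dir
    qc_path <- file.path(od, "qc_report.tsv")
    utils::write.table(fit$qc_report, qc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    strat_path <- file.path(od, "strata.tsv")
    utils::write.table(data.frame(id = pheno$id,
                                  stratum = fit$strata$stratum),
                       strat_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    assoc <- character(0)
    for (s in names(fit$stats)) {
      pth <- file.path(od, sprintf("%s.%s.assoc.tsv", config$phenotype, s))
      write_summary_stats(fit$stats[[s]], pth)
      assoc <- c(assoc, pth)
    }
    corr_path <- file.path(od, "correlation.tsv")
    utils::write.table(fit$correlation$pairs, corr_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    diff_path <- file.path(od, "diff.tsv")
    write_diff_table(fit$diff, diff_path)
    loci_path <- file.path(od, "loci.tsv")
    utils::write.table(as.data.frame(fit$loci), loci_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    members <- do.call(rbind, lapply(fit$loci, function(cl)
      data.frame(lead = cl$lead, id = cl$members$id, r2 = cl$members$r2,
                 stringsAsFactors = FALSE)))
    members_path <- file.path(od, "members.tsv")
    utils::write.table(members %||% data.frame(lead = character(0),
                                               id = character(0),
                                               r2 = numeric(0)),
                       members_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    man_path <- file.path(od, "manhattan.tsv")
    utils::write.table(manhattan_table(fit$diff), man_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    qq_path <- file.path(od, "qq.tsv")
    p <- fit$diff$p_diff
    utils::write.table(qq_table(p[!is.na(p)]), qq_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    c(qc = qc_path, strata = strat_path,
      setNames(assoc, paste0("assoc_", names(fit$stats))),
      correlation = corr_path, diff = diff_path, loci = loci_path,
      members = members_path, manhattan = man_path, qq = qq_path)
  })
  paths <- c(paths, report_paths)
  pipe_log("report", length(paths), " artifact files in ", config$out_dir)
  attr(fit, "paths") <- paths
  invisible(fit)
}
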