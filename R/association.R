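# Per-stratum, per-SNP linear-regression association engine.

#' Ordinary least squares with standard errors
#'
#' QR-based OLS returning coefficients, standard errors from
#' `sigma^2 * diag((X'X)^-1)` with `sigma^2 = RSS / (n - p)`, and the
#' residual degrees of freedom. Rank deficiency is an error naming the
#' aliased columns.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix including the intercept column.
#' @return List with `coefficients`, `se`, `df`, `residuals`, `rank`.
#' @export
#' @examples
#' x <- rnorm(50); y <- 1 + 2 * x + rnorm(50)
#' fit_ols(y, cbind(1, x))$coefficients
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p) stop_domain("insufficient data: ", n, " rows for ", p, " columns")
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) {
    piv <- fit$qr$pivot
    aliased <- piv[(fit$rank + 1L):p]
    nm <- colnames(X) %||% paste0("x", seq_len(p))
    stop_domain("collinear design: column(s) ",
                paste(nm[aliased], collapse = ", "), " are aliased")
  }
  R <- qr.R(fit$qr)
  unpiv <- order(fit$qr$pivot)
  V <- chol2inv(R)[unpiv, unpiv, drop = FALSE]
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(sigma2 * diag(V))
  names(se) <- names(fit$coefficients)
  list(coefficients = fit$coefficients, se = se, df = df,
       residuals = fit$residuals, rank = fit$rank)
}

#' Two-sided p-value from an effect and its standard error
#'
#' `p = 2 * S(|beta/se|)` where `S` is the upper tail of the t-distribution
#' with `df` residual degrees of freedom; the standard-normal limit is used
#' for `df >= 1e4` or infinite. Vectorized over `beta` and `se`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param df residual degrees of freedom (default `Inf` = normal).
#' @return p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' pvalue_from_beta_se(0.539, 0.154)        # a genome-scan scale example
#' pvalue_from_beta_se(1.959964, 1)         # 0.05
pvalue_from_beta_se <- function(beta, se, df = Inf) {
  if (any(se <= 0, na.rm = TRUE)) stop_domain("se must be positive")
  if (any(df <= 0)) stop_domain("df must be positive")
  z <- abs(beta / se)
  if (all(is.infinite(df)) || all(df >= 1e4)) 2 * stats::pnorm(-z)
  else 2 * stats::pt(-z, df)
}

# Lean per-variant OLS used by the scan: design has the dosage in column 2.
# Returns c(beta, se, stat, p, n) or NA row when monomorphic/underdetermined.
assoc_one <- function(design, y, ok) {
  Xc <- design[ok, , drop = FALSE]
  yc <- y[ok]
  n <- length(yc)
  g <- Xc[, 2L]
  if (n <= ncol(Xc) || min(g) == max(g))
    return(c(beta = NA_real_, se = NA_real_, stat = NA_real_, p = NA_real_,
             n = n))
  fit <- stats::lm.fit(Xc, yc)
  if (fit$rank < ncol(Xc))
    return(c(beta = NA_real_, se = NA_real_, stat = NA_real_, p = NA_real_,
             n = n))
  R <- qr.R(fit$qr)
  unpiv <- order(fit$qr$pivot)
  V <- chol2inv(R)[unpiv, unpiv, drop = FALSE]
  df <- n - ncol(Xc)
  sigma2 <- sum(fit$residuals^2) / df
  beta <- fit$coefficients[2L]
  se <- sqrt(sigma2 * V[2L, 2L])
  stat <- beta / se
  c(beta = unname(beta), se = se, stat = unname(stat),
    p = 2 * stats::pt(-abs(unname(stat)), df), n = n)
}

#' Single-variant association test
#'
#' Fits `phenotype ~ intercept + dosage + covariates` on the complete cases
#' (rows with non-missing dosage, phenotype and covariates) and returns the
#' per-allele effect with its standard error and two-sided t-test p-value.
#' A variant that is monomorphic after complete-case filtering yields a
#' flagged record (`beta`/`p` = NA), not an error.
#'
#' @param dosage dosage vector (0/1/2, NA = missing).
#' @param phenotype numeric phenotype vector aligned with `dosage`.
#' @param covariates numeric matrix or data.frame of covariates (may be
#'   NULL for the unadjusted model).
#' @return One-row data.frame `beta, se, stat, p, n`.
#' @export
snp_association <- function(dosage, phenotype, covariates = NULL) {
  n <- length(dosage)
  stopifnot(length(phenotype) == n)
  covm <- if (is.null(covariates)) matrix(numeric(0), n, 0)
          else as.matrix(covariates)
  design <- cbind(`(Intercept)` = 1, ADD = as.numeric(dosage), covm)
  ok <- !is.na(dosage) & !is.na(phenotype) & stats::complete.cases(covm)
  res <- assoc_one(design, phenotype, ok)
  data.frame(beta = res[["beta"]], se = res[["se"]], stat = res[["stat"]],
             p = res[["p"]], n = as.integer(res[["n"]]))
}

#' Stratified genome-wide association scan
#'
#' Runs the covariate-adjusted per-SNP linear association within each age
#' stratum. Age stays in the within-stratum design, so residual age trends
#' inside a stratum are adjusted for. Complete cases are determined per
#' variant (missing dosages drop only that variant's rows, as in standard
#' GWAS practice), and variants monomorphic within a stratum are emitted as
#' flagged rows so the per-stratum tables stay row-aligned.
#'
#' @param genotypes a `genotype_matrix` (post-QC).
#' @param phenotypes data.frame with columns `id`, the covariates and the
#'   phenotype; rows aligned with the genotype matrix rows by `id`.
#' @param strata a `"stratum_assignment"` from [assign_age_quartiles()], or
#'   a factor aligned with `phenotypes`.
#' @param phenotype name of the phenotype column (default `"pheno"`).
#' @param covariates character vector of covariate column names; default
#'   `age, sex, array, pc1..pc10` intersected with what is present.
#' @return Named list (one element per stratum, `Q1..Qk`) of
#'   summary-statistic data.frames with columns
#'   `chr, snp, bp, a1, a2, nmiss, beta, se, stat, p`.
#' @export
run_stratified_gwas <- function(genotypes, phenotypes, strata,
                                phenotype = "pheno", covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  stratum <- if (inherits(strata, "stratum_assignment")) strata$stratum
             else as.factor(strata)
  stopifnot(length(stratum) == nrow(phenotypes),
            nrow(phenotypes) == n_individuals(genotypes))
  if (is.null(covariates))
    covariates <- intersect(c("age", "sex", "array", paste0("pc", 1:10)),
                            names(phenotypes))
  absent <- setdiff(c(phenotype, covariates), names(phenotypes))
  if (length(absent))
    stop_domain("phenotype table lacks column(s): ",
                paste(absent, collapse = ", "))
  gid <- rownames(genotypes$dosage)
  if (!is.null(gid) && !identical(gid, phenotypes$id)) {
    idx <- match(gid, phenotypes$id)
    if (anyNA(idx)) stop_domain("phenotype table does not cover all genotyped ids")
    phenotypes <- phenotypes[idx, , drop = FALSE]
    stratum <- stratum[idx]
  }
  y_all <- phenotypes[[phenotype]]
  covm_all <- as.matrix(phenotypes[covariates])
  v <- genotypes$variants
  m <- n_variants(genotypes)
  out <- list()
  for (s in levels(stratum)) {
    rows <- which(stratum == s)
    p_design <- 2L + length(covariates)
    if (length(rows) < p_design + 2L)
      stop_domain("stratum ", s, " too small (", length(rows),
                  " individuals) for the design")
    y <- y_all[rows]
    design <- cbind(`(Intercept)` = 1, ADD = 0, covm_all[rows, , drop = FALSE])
    base_ok <- !is.na(y) & stats::complete.cases(covm_all[rows, , drop = FALSE])
    res <- matrix(NA_real_, nrow = m, ncol = 5L)
    for (j in seq_len(m)) {
      g <- genotypes$dosage[rows, j]
      design[, 2L] <- g
      res[j, ] <- assoc_one(design, y, base_ok & !is.na(g))
    }
    out[[s]] <- data.frame(chr = v$chrom, snp = v$id, bp = v$pos,
                           a1 = v$a1, a2 = v$a2,
                           nmiss = as.integer(res[, 5L]), beta = res[, 1L],
                           se = res[, 2L], stat = res[, 3L], p = res[, 4L],
                           stringsAsFactors = FALSE)
  }
  out
}
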