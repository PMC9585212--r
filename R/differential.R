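# The differential-effect machinery: Spearman correlation of per-stratum
# effect sizes, selection of the least-correlated stratum pair, and the
# correlation-corrected t-test on the difference in betas.

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' spearman_correlation(1:5, c(2, 1, 4, 3, 5))
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop_domain("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop_domain("missing values not allowed")
  if (min(x) == max(x) || min(y) == max(y))
    stop_domain("correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Pairwise correlation of per-stratum effect sizes
#'
#' Computes the Spearman correlation between the beta vectors of every pair
#' of strata over the variants with valid betas in both, and selects the
#' least-correlated pair. Ties are broken by the widest age gap (largest
#' stratum-index distance), then lexicographically.
#'
#' @param stats_list named list of per-stratum summary-statistic data.frames
#'   (as from [run_stratified_gwas()]), ordered youngest to oldest.
#' @return List of class `"correlation_report"`: `r_matrix`, `n_matrix`
#'   (shared variant counts), `pairs` (long-format data.frame with a
#'   `selected` flag), `selected` (character vector of the two stratum
#'   names).
#' @export
pairwise_beta_correlation <- function(stats_list) {
  k <- length(stats_list)
  stopifnot(k >= 2, !is.null(names(stats_list)))
  labs <- names(stats_list)
  rmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  nmat <- matrix(0L, k, k, dimnames = list(labs, labs))
  diag(rmat) <- 1
  pairs <- NULL
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    a <- stats_list[[i]]; b <- stats_list[[j]]
    shared <- intersect(a$snp[!is.na(a$beta)], b$snp[!is.na(b$beta)])
    if (length(shared) < 3)
      stop_domain("fewer than 3 shared variants between ", labs[i], " and ",
                  labs[j])
    r <- spearman_correlation(a$beta[match(shared, a$snp)],
                              b$beta[match(shared, b$snp)])
    rmat[i, j] <- rmat[j, i] <- r
    nmat[i, j] <- nmat[j, i] <- length(shared)
    pairs <- rbind(pairs, data.frame(group1 = labs[i], group2 = labs[j],
                                     gap = j - i, r = r,
                                     n_variants = length(shared),
                                     stringsAsFactors = FALSE))
  }
  # least-correlated pair; ties -> widest age gap, then lexicographic
  ord <- order(pairs$r, -pairs$gap, pairs$group1, pairs$group2)
  sel <- ord[1L]
  pairs$selected <- seq_len(nrow(pairs)) == sel
  structure(list(r_matrix = rmat, n_matrix = nmat, pairs = pairs,
                 selected = c(pairs$group1[sel], pairs$group2[sel])),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Spearman correlation of per-stratum betas:\n")
  print(round(x$r_matrix, 4))
  cat("selected pair (lowest r):", paste(x$selected, collapse = " vs "), "\n")
  invisible(x)
}

#' Correlation-corrected differential t-statistic
#'
#' `t = (b1 - b2) / sqrt(se1^2 + se2^2 - 2 * r * se1 * se2)`, where `r` is
#' the correlation between the two sets of effect estimates. With `r = 0`
#' this is the classical two-sample z-statistic for independent estimates;
#' positive `r` tightens the null variance of the difference.
#'
#' @param b1,se1 effect and standard error in group 1.
#' @param b2,se2 effect and standard error in group 2.
#' @param r inter-group effect-size correlation (scalar).
#' @return The differential statistic (vectorized over `b1, se1, b2, se2`).
#' @export
#' @examples
#' differential_t(-0.021, 0.043, -0.325, 0.040, r = 0)
differential_t <- function(b1, se1, b2, se2, r = 0) {
  if (any(se1 <= 0 | se2 <= 0, na.rm = TRUE)) stop_domain("standard errors must be positive")
  stopifnot(length(r) == 1L, r > -1, r <= 1)
  v <- se1^2 + se2^2 - 2 * r * se1 * se2
  if (any(v <= 0, na.rm = TRUE))
    stop_domain("degenerate variance: se1^2 + se2^2 - 2*r*se1*se2 <= 0")
  (b1 - b2) / sqrt(v)
}

#' Two-sided p-value of the differential statistic
#'
#' Standard-normal reference: `p = 2 * Phi(-|t|)`, computed through the
#' survival function so that extreme statistics keep full precision
#' (down to p ~ 1e-300).
#'
#' @param t differential statistic(s).
#' @return p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' differential_pvalue(5.176)
differential_pvalue <- function(t) {
  stopifnot(all(is.finite(t)))
  2 * stats::pnorm(abs(t), lower.tail = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 15)
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha <= 1)
  if (m < 1) stop_domain("number of tests must be >= 1")
  alpha / m
}

#' Differential-effect test between two strata
#'
#' Joins two per-stratum summary-statistic tables on variant id, harmonizes
#' alleles (a variant whose a1/a2 are swapped in group 2 has its beta sign
#' flipped; variants that neither match nor swap are excluded and counted),
#' computes the Spearman correlation `r` of the two beta vectors (unless
#' overridden), and tests each variant's difference in betas with the
#' correlation-corrected statistic. Significance tiers: `genome-wide`
#' (`p_diff < genomewide`), `suggestive` (`p_diff < suggestive`), else
#' `none`.
#'
#' @param stats1,stats2 summary-statistic data.frames for the two strata.
#' @param r_override optional scalar correlation to use instead of the
#'   estimated one.
#' @param genomewide,suggestive significance thresholds.
#' @return data.frame with columns `chr, snp, bp, a1, a2, beta1, se1, n1,
#'   beta2, se2, n2, r, t, p_diff, tier`; the number of unharmonizable
#'   variants is attached as attribute `"n_excluded"` and the correlation
#'   used as attribute `"r"`.
#' @export
run_differential <- function(stats1, stats2, r_override = NULL,
                             genomewide = 5e-8, suggestive = 1e-6) {
  shared <- intersect(stats1$snp, stats2$snp)
  if (!length(shared)) stop_domain("no shared variants between the strata")
  a <- stats1[match(shared, stats1$snp), ]
  b <- stats2[match(shared, stats2$snp), ]
  match_ok <- a$a1 == b$a1 & a$a2 == b$a2
  swapped <- a$a1 == b$a2 & a$a2 == b$a1
  excluded <- !(match_ok | swapped)
  b$beta[swapped] <- -b$beta[swapped]
  a <- a[!excluded, ]; b <- b[!excluded, ]
  valid <- !is.na(a$beta) & !is.na(b$beta)
  r <- if (!is.null(r_override)) r_override
       else spearman_correlation(a$beta[valid], b$beta[valid])
  # as differential_t(), but a zero difference with a degenerate (zero)
  # variance — identical inputs at r = 1 — is defined as t = 0
  v <- a$se^2 + b$se^2 - 2 * r * a$se * b$se
  delta <- a$beta - b$beta
  degen <- !is.na(v) & v <= 0
  if (any(degen & valid & delta != 0))
    stop_domain("degenerate variance with non-zero beta difference")
  t <- ifelse(degen, 0, delta / sqrt(v))
  t[!valid] <- NA_real_
  p <- ifelse(valid, 2 * stats::pnorm(abs(t), lower.tail = FALSE), NA_real_)
  tier <- rep("none", nrow(a))
  tier[!is.na(p) & p < suggestive] <- "suggestive"
  tier[!is.na(p) & p < genomewide] <- "genome-wide"
  out <- data.frame(chr = a$chr, snp = a$snp, bp = a$bp, a1 = a$a1, a2 = a$a2,
                    beta1 = a$beta, se1 = a$se, n1 = a$nmiss,
                    beta2 = b$beta, se2 = b$se, n2 = b$nmiss,
                    r = r, t = t, p_diff = p, tier = tier,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(excluded)
  attr(out, "r") <- r
  out
}
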