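# Variant quality control: call rate, minor allele frequency, exact
# Hardy-Weinberg test, and the combined SNP filter; plus age-quartile
# stratification of individuals.

#' QC thresholds
#'
#' A variant is removed when its missing call rate exceeds
#' `max_missing_rate`, its MAF is below `min_maf`, or its exact HWE test
#' p-value is below `min_hwe_p`. Boundary semantics are strict: removal at
#' rate > 0.05, MAF < 0.01, HWE p < 1e-6.
#'
#' @param max_missing_rate maximum tolerated missing-call fraction.
#' @param min_maf minimum minor allele frequency.
#' @param min_hwe_p minimum HWE exact-test p-value.
#' @return A list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(max_missing_rate = 0.05, min_maf = 0.01,
                          min_hwe_p = 1e-6) {
  stopifnot(max_missing_rate > 0, max_missing_rate <= 1,
            min_maf > 0, min_maf <= 1, min_hwe_p > 0, min_hwe_p <= 1)
  structure(list(max_missing_rate = max_missing_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p), class = "qc_thresholds")
}

#' Missing-call rate of a dosage vector
#'
#' @param dosage integer dosage vector (NA = missing).
#' @return Fraction of missing entries in `[0, 1]`.
#' @export
#' @examples
#' call_rate(c(0, 1, NA, 2))
call_rate <- function(dosage) {
  if (!length(dosage)) stop_domain("empty dosage column")
  mean(is.na(dosage))
}

#' Minor allele frequency of a dosage vector
#'
#' The allele-1 frequency is `sum(dosage) / (2 * n_nonmissing)`; the MAF is
#' the smaller of it and its complement.
#'
#' @param dosage integer dosage vector (NA = missing).
#' @return MAF in `[0, 0.5]`.
#' @export
#' @examples
#' minor_allele_freq(c(0, 0, 1))  # 1/6
minor_allele_freq <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (!length(d)) stop_domain("MAF undefined: all entries missing")
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

# Null probability of every possible heterozygote count given n genotypes
# and nA copies of allele A, conditional on the allele counts (the exact
# HWE sampling distribution). Computed by the standard two-sided recurrence
# from the distribution mode to avoid overflow at large n, then normalized.
# Returns list(het = supported counts, prob = their probabilities).
hwe_het_distribution <- function(n, nA) {
  nB <- 2L * n - nA
  rare <- min(nA, nB)
  if (rare == 0L) return(list(het = 0L, prob = 1))
  het <- seq.int(rare %% 2L, rare, by = 2L)
  # mode of the distribution, matched to the support's parity
  mid <- floor(nA * nB / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mid <- min(max(mid, het[1L]), het[length(het)])
  i0 <- match(mid, het)
  prob <- numeric(length(het))
  prob[i0] <- 1
  a <- (nA - het) / 2
  b <- (nB - het) / 2
  # step ratios P(h+2)/P(h) = 4*a*b / ((h+2)*(h+1)); vectorized cumprod both
  # ways from the mode keeps every factor <= ~1 so large n cannot overflow
  up <- 4 * a * b / ((het + 2) * (het + 1))
  if (i0 < length(het))
    prob[(i0 + 1L):length(het)] <- cumprod(up[i0:(length(het) - 1L)])
  if (i0 > 1L) {
    down <- 1 / up[(i0 - 1L):1L]
    prob[(i0 - 1L):1L] <- cumprod(down)
  }
  list(het = het, prob = prob / sum(prob))
}

# p-value for every possible observed heterozygote count of the (n, nA)
# distribution: sum of the probabilities of all tables no more probable than
# the observed one (with a small relative tolerance for ties at machine
# precision).
hwe_pvalues_for_distribution <- function(dist) {
  vapply(dist$prob, function(p_obs)
    min(1, sum(dist$prob[dist$prob <= p_obs * (1 + 1e-12)])), 0)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' The exact conditional test: given the observed allele counts, the p-value
#' is the total null probability of all heterozygote counts (of matching
#' parity) whose conditional probability does not exceed that of the
#' observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum >= 1).
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(100, 0, 0)   # monomorphic: 1
#' hwe_exact_test(57, 14, 50)  # strong heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop_domain("genotype counts must be non-negative")
  if (any(counts != round(counts))) stop_domain("genotype counts must be integers")
  n <- sum(counts)
  if (n < 1) stop_domain("at least one genotype required")
  nA <- 2 * n_AA + n_Aa
  dist <- hwe_het_distribution(as.integer(n), as.integer(nA))
  i <- match(n_Aa, dist$het)
  p_obs <- dist$prob[i]
  min(1, sum(dist$prob[dist$prob <= p_obs * (1 + 1e-12)]))
}

#' Apply SNP quality-control filters
#'
#' Removes variants whose missing rate exceeds `max_missing_rate`, whose MAF
#' is below `min_maf`, or whose exact HWE p-value is below `min_hwe_p`.
#' Survivor order is preserved. HWE is computed on the full cohort.
#'
#' @param genotypes a `genotype_matrix`.
#' @param thresholds a [qc_thresholds()].
#' @return List with elements `genotypes` (the filtered matrix) and `report`
#'   (data.frame `id, missing_rate, maf, hwe_p, pass, reasons` plus
#'   attributes `n_in`/`n_out`).
#' @export
filter_snps <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  m <- n_variants(genotypes)
  miss <- maf <- hwe <- numeric(m)
  for (j in seq_len(m)) {
    d <- genotypes$dosage[, j]
    miss[j] <- call_rate(d)
    dn <- d[!is.na(d)]
    if (!length(dn)) { maf[j] <- NA_real_; hwe[j] <- NA_real_; next }
    maf[j] <- minor_allele_freq(d)
    hwe[j] <- hwe_exact_test(sum(dn == 2L), sum(dn == 1L), sum(dn == 0L))
  }
  fail_miss <- miss > thresholds$max_missing_rate
  fail_maf <- is.na(maf) | maf < thresholds$min_maf
  fail_hwe <- !is.na(hwe) & hwe < thresholds$min_hwe_p
  pass <- !(fail_miss | fail_maf | fail_hwe)
  reasons <- vapply(seq_len(m), function(j)
    paste(c("missing_rate", "maf", "hwe")[c(fail_miss[j], fail_maf[j],
                                            fail_hwe[j])], collapse = ";"), "")
  report <- data.frame(id = genotypes$variants$id, missing_rate = miss,
                       maf = maf, hwe_p = hwe, pass = pass,
                       reasons = reasons, stringsAsFactors = FALSE)
  attr(report, "n_in") <- m
  attr(report, "n_out") <- sum(pass)
  list(genotypes = subset_variants(genotypes, genotypes$variants$id[pass]),
       report = report)
}

#' Assign individuals to age strata
#'
#' Splits the cohort into `k` age groups at the nearest-rank (type-1)
#' empirical quantiles of the age vector. Assignment is by age value, so all
#' individuals sharing an age land in the same stratum and group sizes are
#' only approximately equal. Strata are labelled `Q1` (youngest) to `Qk`
#' (oldest).
#'
#' @param ages integer age vector, named by individual id (names optional).
#' @param k number of strata (>= 2).
#' @return List of class `"stratum_assignment"`: `stratum` (factor aligned
#'   with `ages`), `summary` (per-stratum n, min/max/mean age), `cutpoints`.
#' @export
#' @examples
#' assign_age_quartiles(rep(1:8, each = 2), k = 4)$summary
assign_age_quartiles <- function(ages, k = 4) {
  stopifnot(k >= 2, is.numeric(ages))
  if (anyNA(ages)) stop_domain("ages contain missing values")
  if (length(unique(ages)) < k)
    stop_domain("stratification error: fewer than k distinct ages")
  srt <- sort(ages)
  n <- length(srt)
  # nearest-rank quantiles at i/k, i = 1..k-1
  cut_idx <- ceiling(seq_len(k - 1) * n / k)
  cuts <- srt[cut_idx]
  stratum_of <- function(a) 1L + sum(a > cuts)
  idx <- vapply(ages, stratum_of, 1L)
  labels <- paste0("Q", seq_len(k))
  stratum <- factor(labels[idx], levels = labels)
  if (any(tabulate(idx, k) == 0L))
    stop_domain("stratification error: empty stratum (heavily tied ages)")
  smry <- data.frame(stratum = labels,
                     n = as.integer(tabulate(idx, k)),
                     age_min = vapply(seq_len(k), function(i) min(ages[idx == i]), 0),
                     age_max = vapply(seq_len(k), function(i) max(ages[idx == i]), 0),
                     age_mean = vapply(seq_len(k), function(i) mean(ages[idx == i]), 0),
                     stringsAsFactors = FALSE)
  structure(list(stratum = stratum, summary = smry, cutpoints = cuts),
            class = "stratum_assignment")
}
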