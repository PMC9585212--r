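# LD computation, greedy clumping of differential results into lead loci,
# and plot-ready Manhattan/QQ tables.

#' Linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of the two dosage vectors over the
#' pairwise-complete individuals.
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
#' @examples
#' g <- rbinom(100, 2, 0.4)
#' ld_r2(g, 2 - g)  # perfect negative LD: 1
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) stop_domain("fewer than 3 shared non-missing individuals")
  if (min(g1[ok]) == max(g1[ok]) || min(g2[ok]) == max(g2[ok]))
    stop_domain("LD undefined for a constant dosage column")
  stats::cor(g1[ok], g2[ok])^2
}

#' Greedy LD clumping of differential results
#'
#' Stage 1: among variants with `p_diff < p_threshold`, repeatedly take the
#' most significant remaining variant as a lead and absorb every remaining
#' variant with `r^2 >= r2_threshold` to it. Stage 2: leads on the same
#' chromosome whose positions are within `merge_window` of each other are
#' merged into one locus, keeping the most significant lead. Surviving leads
#' are therefore pairwise in low LD and farther than `merge_window` apart
#' (or on different chromosomes). Ties in `p_diff` are broken by variant id
#' so the output is invariant to input row order.
#'
#' @param diff differential-result data.frame (from [run_differential()]).
#' @param genotypes a `genotype_matrix` supplying the dosages used for LD.
#' @param p_threshold significance cutoff for clump membership.
#' @param r2_threshold LD cutoff: a variant joins a lead at
#'   `r^2 >= r2_threshold`.
#' @param merge_window base-pair window for merging nearby leads.
#' @return List of loci of class `"locus_list"`; each locus is a list with
#'   `lead, chrom, start, end, p_diff, members` (data.frame `id, r2`). The
#'   number of significant variants missing from the genotypes is attached
#'   as attribute `"n_missing_genotype"`.
#' @export
greedy_clump <- function(diff, genotypes, p_threshold = 5e-8,
                         r2_threshold = 0.1, merge_window = 250000) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  sig <- diff[!is.na(diff$p_diff) & diff$p_diff < p_threshold, , drop = FALSE]
  in_geno <- sig$snp %in% genotypes$variants$id
  n_missing <- sum(!in_geno)
  sig <- sig[in_geno, , drop = FALSE]
  sig <- sig[order(sig$p_diff, sig$snp), , drop = FALSE]
  col_of <- match(sig$snp, genotypes$variants$id)
  # stage 1: greedy LD clumps
  clumps <- list()
  remaining <- seq_len(nrow(sig))
  while (length(remaining)) {
    lead <- remaining[1L]
    rest <- remaining[-1L]
    g_lead <- genotypes$dosage[, col_of[lead]]
    r2 <- vapply(rest, function(i)
      tryCatch(ld_r2(g_lead, genotypes$dosage[, col_of[i]]),
               error = function(e) 0), 0)
    absorbed <- rest[r2 >= r2_threshold]
    members <- data.frame(id = sig$snp[c(lead, absorbed)],
                          r2 = c(1, r2[r2 >= r2_threshold]),
                          stringsAsFactors = FALSE)
    clumps[[length(clumps) + 1L]] <- list(
      lead = sig$snp[lead], chrom = sig$chr[lead], pos = sig$bp[lead],
      p_diff = sig$p_diff[lead], members = members)
    remaining <- setdiff(rest, absorbed)
  }
  # stage 2: merge leads on one chromosome within the window
  merged <- list()
  todo <- clumps  # already in ascending p_diff order
  while (length(todo)) {
    best <- todo[[1L]]
    todo <- todo[-1L]
    near <- vapply(todo, function(cl)
      cl$chrom == best$chrom && abs(cl$pos - best$pos) <= merge_window, TRUE)
    for (cl in todo[near]) best$members <- rbind(best$members, cl$members)
    todo <- todo[!near]
    merged[[length(merged) + 1L]] <- best
  }
  loci <- lapply(merged, function(cl) {
    pos <- genotypes$variants$pos[match(cl$members$id, genotypes$variants$id)]
    list(lead = cl$lead, chrom = cl$chrom, start = min(pos), end = max(pos),
         p_diff = cl$p_diff, members = cl$members)
  })
  structure(loci, class = "locus_list", n_missing_genotype = n_missing)
}

#' @export
print.locus_list <- function(x, ...) {
  cat(length(x), "locus/loci\n")
  for (cl in x)
    cat(sprintf("  %s  chr%s:%d-%d  p_diff=%.3g  members=%d\n", cl$lead,
                cl$chrom, cl$start, cl$end, cl$p_diff, nrow(cl$members)))
  invisible(x)
}

#' @export
as.data.frame.locus_list <- function(x, ...) {
  if (!length(x))
    return(data.frame(lead = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), p_diff = numeric(0)))
  data.frame(lead = vapply(x, `[[`, "", "lead"),
             chrom = vapply(x, `[[`, "", "chrom"),
             start = vapply(x, function(cl) as.integer(cl$start), 0L),
             end = vapply(x, function(cl) as.integer(cl$end), 0L),
             n_members = vapply(x, function(cl) nrow(cl$members), 0L),
             p_diff = vapply(x, `[[`, 0, "p_diff"),
             stringsAsFactors = FALSE)
}

#' Manhattan plot table
#'
#' Builds the plot-ready table for a Manhattan plot: rows sorted by
#' (chromosome, position) with a strictly increasing genome-wide cumulative
#' coordinate and `-log10(p)`. Threshold lines at `5e-8` (genome-wide) and
#' `1e-6` (suggestive) are attached as attribute `"thresholds"` on the
#' `-log10` scale.
#'
#' @param results data.frame with columns `chr`, `bp` and the p-value column.
#' @param p_col name of the p-value column (default `"p_diff"`).
#' @return data.frame `chrom, pos, cumpos, neglog10p`.
#' @export
manhattan_table <- function(results, p_col = "p_diff") {
  p <- results[[p_col]]
  if (is.null(p)) stop_domain("no column ", p_col)
  keep <- !is.na(p)
  p <- p[keep]
  if (any(p <= 0 | p > 1)) stop_domain("p-values must lie in (0, 1]")
  chrom <- as.character(results$chr[keep])
  pos <- results$bp[keep]
  lev <- chrom_order(chrom)
  ord <- order(match(chrom, lev), pos)
  chrom <- chrom[ord]; pos <- pos[ord]; p <- p[ord]
  offsets <- c(0, cumsum(vapply(lev, function(cr) max(pos[chrom == cr]), 0)))
  cumpos <- pos + offsets[match(chrom, lev)]
  out <- data.frame(chrom = chrom, pos = pos, cumpos = cumpos,
                    neglog10p = -log10(p), stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(genomewide = -log10(5e-8),
                               suggestive = -log10(1e-6))
  out
}

#' QQ plot table and genomic-inflation factor
#'
#' Pairs the sorted observed p-values with uniform expected quantiles
#' `i/(n+1)` on the `-log10` scale, and computes the genomic-inflation
#' factor `lambda = median(chisq_1(p)) / qchisq(0.5, 1)` (the median
#' 1-df chi-square quantile of the observed p-values over its null median,
#' 0.4549).
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return data.frame `expected, observed` (`-log10` scale, one row per
#'   p-value, most significant first) with the inflation factor attached as
#'   attribute `"lambda"`.
#' @export
qq_table <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop_domain("no p-values")
  if (any(p <= 0 | p > 1)) stop_domain("p-values must lie in (0, 1]")
  n <- length(p)
  obs <- sort(p)
  out <- data.frame(expected = -log10(seq_len(n) / (n + 1)),
                    observed = -log10(obs))
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  attr(out, "lambda") <- stats::median(chisq) / stats::qchisq(0.5, 1)
  out
}
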