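#' Construct a genotype matrix
#'
#' The package's genotype container: an individuals x variants matrix of
#' additive dosages (copies of the effect allele `a1`, coded 0/1/2, `NA` for
#' missing hard calls) together with per-variant metadata. Variants are kept
#' sorted by (chromosome, position); the dosage coding is never flipped
#' internally — `a1` is the ALT allele of the source VCF regardless of its
#' frequency.
#'
#' @param dosage integer matrix (individuals x variants) with entries in
#'   `{0, 1, 2, NA}`. Row names are individual ids, column names variant ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `a1`, `a2`;
#'   one row per column of `dosage`, in the same order.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `dosage` and `variants`.
#' @export
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, NA), 2, 2,
#'          dimnames = list(c("i1", "i2"), c("v1", "v2"))),
#'   data.frame(id = c("v1", "v2"), chrom = "1", pos = c(100L, 200L),
#'              a1 = c("A", "T"), a2 = c("G", "C"))
#' )
#' n_variants(g)
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  required <- c("id", "chrom", "pos", "a1", "a2")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols))
    stop_domain("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(variants) != ncol(dosage))
    stop_domain("variant table has ", nrow(variants), " rows but dosage has ",
                ncol(dosage), " columns")
  if (anyDuplicated(variants$id))
    stop_domain("duplicated variant ids: ",
                paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (any(variants$pos < 1)) stop_domain("variant positions must be >= 1")
  if (any(variants$a1 == variants$a2)) stop_domain("a1 and a2 must differ")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop_domain("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  colnames(dosage) <- variants$id
  # canonical variant order: (chrom, pos)
  ord <- order(match(variants$chrom, chrom_order(variants$chrom)), variants$pos)
  variants <- variants[ord, required, drop = FALSE]
  rownames(variants) <- NULL
  structure(list(dosage = dosage[, ord, drop = FALSE], variants = variants),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_variants <- function(x) ncol(x$dosage)

#' @rdname genotype_matrix
#' @export
n_individuals <- function(x) nrow(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_individuals(x), "individuals x",
      n_variants(x), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

# subset variants by id, preserving order of the container
subset_variants <- function(x, ids) {
  keep <- x$variants$id %in% ids
  genotype_matrix(x$dosage[, keep, drop = FALSE],
                  x$variants[keep, , drop = FALSE])
}
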