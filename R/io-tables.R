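# Readers/writers for PLINK-style phenotype/covariate tables and the TSV
# summary-statistic dialects used throughout the pipeline.

#' Read a PLINK-style phenotype/covariate table
#'
#' Reads a whitespace-delimited table with a header line. Both the two-column
#' id dialect (`FID IID ...`) and a single leading id column are accepted;
#' the individual id is `IID` when present, otherwise the first column.
#' Column matching is case-insensitive. `NA` marks missing values. Rows with
#' a missing phenotype or any missing requested covariate are flagged in the
#' logical column `.complete` for downstream complete-case exclusion — they
#' are not dropped here.
#'
#' @param path file path.
#' @param phenotype_name name of the phenotype column.
#' @param covariate_names character vector of covariate column names.
#' @return A data.frame with columns `id`, the requested columns (lower-case
#'   names), any remaining columns, and `.complete`.
#' @export
read_pheno_covar <- function(path, phenotype_name, covariate_names = character(0)) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "-9"), check.names = FALSE)
  names(tab) <- tolower(names(tab))
  wanted <- tolower(c(phenotype_name, covariate_names))
  absent <- setdiff(wanted, names(tab))
  if (length(absent))
    stop_domain("column(s) not found: ", paste(absent, collapse = ", "),
                "; available: ", paste(names(tab), collapse = ", "))
  id <- if ("iid" %in% names(tab)) as.character(tab$iid) else as.character(tab[[1L]])
  if (anyDuplicated(id))
    stop_domain("duplicated individual ids: ",
                paste(unique(id[duplicated(id)]), collapse = ", "))
  out <- cbind(data.frame(id = id, stringsAsFactors = FALSE),
               tab[setdiff(names(tab), c("fid", "iid"))])
  out$.complete <- stats::complete.cases(out[wanted])
  out
}

#' Write a phenotype/covariate table
#'
#' Writes the `FID IID` dialect consumed by [read_pheno_covar()] (FID is set
#' equal to IID). Missing values are written as `NA`.
#'
#' @param pheno data.frame with an `id` column; any `.complete` column is
#'   dropped on write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pheno_covar <- function(pheno, path) {
  stopifnot(is.data.frame(pheno), "id" %in% names(pheno))
  body <- pheno[setdiff(names(pheno), c("id", ".complete"))]
  out <- cbind(FID = pheno$id, IID = pheno$id, body)
  names(out) <- toupper(names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical summary-statistics column set (PLINK .assoc.linear dialect, TSV)
SUMSTATS_COLS <- c("CHR", "SNP", "BP", "A1", "A2", "NMISS", "BETA", "SE",
                   "STAT", "P")

#' Write per-stratum association results
#'
#' Serializes association records to a TSV in a PLINK `.assoc.linear`-style
#' dialect with columns `CHR SNP BP A1 A2 NMISS BETA SE STAT P`. Effect
#' sizes are written with 10 significant digits and p-values in scientific
#' notation with 7 significant digits, so a write/read round trip preserves
#' values to printed precision.
#'
#' @param stats data.frame of association records (lower-case column names
#'   `chr, snp, bp, a1, a2, nmiss, beta, se, stat, p`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  need <- tolower(SUMSTATS_COLS)
  absent <- setdiff(need, names(stats))
  if (length(absent))
    stop_domain("summary stats lack column(s): ", paste(absent, collapse = ", "))
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
  fmt_p <- function(x) ifelse(is.na(x), "NA", sprintf("%.6e", x))
  out <- data.frame(CHR = stats$chr, SNP = stats$snp, BP = stats$bp,
                    A1 = stats$a1, A2 = stats$a2, NMISS = stats$nmiss,
                    BETA = fmt_num(stats$beta), SE = fmt_num(stats$se),
                    STAT = fmt_num(stats$stat), P = fmt_p(stats$p),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-stratum association results
#'
#' @param path TSV written by [write_summary_stats()] (or any file in the
#'   same dialect).
#' @return data.frame with lower-case columns
#'   `chr, snp, bp, a1, a2, nmiss, beta, se, stat, p`.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = "character")
  unknown <- setdiff(names(tab), SUMSTATS_COLS)
  if (length(unknown))
    stop_domain("unknown summary-stats column(s): ",
                paste(unknown, collapse = ", "))
  absent <- setdiff(SUMSTATS_COLS, names(tab))
  if (length(absent))
    stop_domain("summary stats file lacks column(s): ",
                paste(absent, collapse = ", "))
  num <- function(col) {
    x <- tab[[col]]
    bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
    if (length(bad))
      stop_domain("non-numeric ", col, " at data row ", bad[1L], ": ", x[bad[1L]])
    as.numeric(x)
  }
  data.frame(chr = tab$CHR, snp = tab$SNP, bp = as.integer(num("BP")),
             a1 = tab$A1, a2 = tab$A2, nmiss = as.integer(num("NMISS")),
             beta = num("BETA"), se = num("SE"), stat = num("STAT"),
             p = num("P"), stringsAsFactors = FALSE)
}

#' Write / read a differential-result table
#'
#' TSV dialect with columns
#' `CHR SNP BP A1 A2 BETA1 SE1 N1 BETA2 SE2 N2 R T P_DIFF TIER`.
#'
#' @param diff data.frame as returned by [run_differential()].
#' @param path file path.
#' @return `path` (write) or the parsed data.frame (read).
#' @export
write_diff_table <- function(diff, path) {
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
  fmt_p <- function(x) ifelse(is.na(x), "NA", sprintf("%.6e", x))
  out <- data.frame(CHR = diff$chr, SNP = diff$snp, BP = diff$bp,
                    A1 = diff$a1, A2 = diff$a2,
                    BETA1 = fmt_num(diff$beta1), SE1 = fmt_num(diff$se1),
                    N1 = diff$n1,
                    BETA2 = fmt_num(diff$beta2), SE2 = fmt_num(diff$se2),
                    N2 = diff$n2, R = fmt_num(diff$r), T = fmt_num(diff$t),
                    P_DIFF = fmt_p(diff$p_diff), TIER = diff$tier,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diff_table
#' @export
read_diff_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  data.frame(chr = as.character(tab$CHR), snp = tab$SNP, bp = as.integer(tab$BP),
             a1 = tab$A1, a2 = tab$A2, beta1 = tab$BETA1, se1 = tab$SE1,
             n1 = as.integer(tab$N1), beta2 = tab$BETA2, se2 = tab$SE2,
             n2 = as.integer(tab$N2), r = tab$R, t = tab$T,
             p_diff = tab$P_DIFF, tier = tab$TIER, stringsAsFactors = FALSE)
}
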