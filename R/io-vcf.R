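#' Read genotypes from a VCF file
#'
#' Parses a VCF v4.x file with per-sample GT fields into a
#' [genotype_matrix()]. Dosage counts copies of the ALT allele (`a1` = ALT,
#' `a2` = REF); missing calls (`./.` or `.`) become `NA`. Only biallelic
#' records are supported; multi-allelic records must be split upstream
#' (e.g. `bcftools norm -m-`).
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_domain("VCF not found: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "##fileformat=VCF"))
    stop_domain("parse error at line 1 of ", path,
                ": missing ##fileformat=VCF header")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) && any(grepl(",", fix$ALT, fixed = TRUE)))
    stop_domain("unsupported multi-allelic record(s): ",
                paste(utils::head(fix$ID[grepl(",", fix$ALT, fixed = TRUE)], 5L),
                      collapse = ", "))
  samples <- colnames(v@gt)[-1L]
  if (nrow(fix) == 0L) {
    return(genotype_matrix(
      matrix(integer(0), nrow = length(samples), ncol = 0L,
             dimnames = list(samples, NULL)),
      data.frame(id = character(0), chrom = character(0), pos = integer(0),
                 a1 = character(0), a2 = character(0))))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # additive coding: number of ALT alleles in the call; decode each distinct
  # GT string once rather than per cell
  alt_count <- function(cell) {
    if (is.na(cell)) return(NA_integer_)
    alleles <- strsplit(cell, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    bad <- !alleles %in% c("0", "1")
    if (any(bad)) stop_domain("unsupported allele code in GT: ", cell)
    sum(alleles == "1")
  }
  codes <- unique(as.vector(gt))
  decoded <- vapply(codes, alt_count, integer(1))
  dos <- matrix(decoded[match(as.vector(gt), codes)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  genotype_matrix(t(dos),
                  data.frame(id = ids, chrom = fix$CHROM,
                             pos = as.integer(fix$POS),
                             a1 = fix$ALT, a2 = fix$REF,
                             stringsAsFactors = FALSE))
}

#' Write genotypes to a VCF file
#'
#' Emits a plain-text VCF v4.2 with one diploid GT per sample: dosage 0 ->
#' `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`. REF is `a2`, ALT is `a1`,
#' matching the coding used by [read_vcf()] so that write-then-read is an
#' identity.
#'
#' @param x a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  samples <- rownames(x$dosage)
  if (is.null(samples)) samples <- paste0("sample", seq_len(n_individuals(x)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=diffgwas",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- character(n_variants(x))
  for (j in seq_len(n_variants(x))) {
    d <- x$dosage[, j]
    calls <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    v <- x$variants[j, ]
    lines[j] <- paste(c(v$chrom, v$pos, v$id, v$a2, v$a1, ".", "PASS", ".",
                        "GT", calls), collapse = "\t")
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_domain("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(path)
}
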