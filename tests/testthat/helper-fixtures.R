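# Small fixture builders used across test files.

tiny_genotypes <- function(dosages, chrom = "1", pos = NULL,
                           ids = NULL, samples = NULL) {
  dos <- as.matrix(dosages)
  m <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  if (is.null(samples)) samples <- sprintf("i%03d", seq_len(nrow(dos)))
  rownames(dos) <- samples
  genotype_matrix(dos, data.frame(id = ids, chrom = rep_len(chrom, m),
                                  pos = pos, a1 = rep_len("A", m),
                                  a2 = rep_len("G", m),
                                  stringsAsFactors = FALSE))
}

# minimal summary-statistics table
tiny_stats <- function(snp, beta, se, chrom = "1", bp = NULL,
                       a1 = "A", a2 = "G", n = 100L) {
  m <- length(snp)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  data.frame(chr = rep_len(chrom, m), snp = snp, bp = bp,
             a1 = rep_len(a1, m), a2 = rep_len(a2, m),
             nmiss = rep_len(n, m), beta = beta, se = se,
             stat = beta / se, p = 2 * pnorm(-abs(beta / se)),
             stringsAsFactors = FALSE)
}
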