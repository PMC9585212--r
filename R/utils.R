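# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and the stage name, so each stage is reproducible in isolation and
#' inserting a new stage does not perturb the streams of the others.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"genotypes"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(42, "genotypes")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 2147483647
  as.integer((abs(master) + h) %% 2147483647)
}

stop_domain <- function(...) stop(..., call. = FALSE)

# natural chromosome ordering: numeric labels first in numeric order,
# then non-numeric labels alphabetically (X, Y, MT, ...)
chrom_order <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), num, u)]
}
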