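# Independent oracles used to check the implementation by a different route.

# HWE exact test by direct enumeration: closed-form log-probability of every
# heterozygote count with the observed allele counts, via lgamma (the
# implementation uses a mode-anchored recurrence instead).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n - nA
  rare <- min(nA, nB)
  het <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((nB - het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, het)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# same enumeration, returning the p-value for every possible observed
# heterozygote count of the (n, nA) configuration
hwe_oracle_all <- function(n, nA) {
  nB <- 2 * n - nA
  rare <- min(nA, nB)
  het <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((nB - het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  vapply(prob, function(p_obs)
    min(1, sum(prob[prob <= p_obs * (1 + 1e-12)])), 0)
}

# OLS by explicit normal equations (the implementation uses QR)
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  list(coefficients = drop(beta), se = sqrt(sigma2 * diag(solve(XtX))),
       df = df)
}

# Spearman by explicit rank-then-Pearson
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive clumping oracle for fixtures with clean block structure:
# all-pairs r2 on significant variants, connected components under
# (r2 >= r2_threshold) OR (same chromosome AND within merge_window), lead =
# smallest p_diff per component.
clump_oracle <- function(diff, genotypes, p_threshold = 5e-8,
                         r2_threshold = 0.1, merge_window = 250000) {
  sig <- diff[!is.na(diff$p_diff) & diff$p_diff < p_threshold, , drop = FALSE]
  m <- nrow(sig)
  if (!m) return(list())
  col <- match(sig$snp, genotypes$variants$id)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    r2 <- tryCatch(ld_r2(genotypes$dosage[, col[i]],
                         genotypes$dosage[, col[j]]), error = function(e) 0)
    near <- sig$chr[i] == sig$chr[j] && abs(sig$bp[i] - sig$bp[j]) <= merge_window
    adj[i, j] <- r2 >= r2_threshold || near
  }
  # transitive closure -> components
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) for (j in seq_len(m)) if (adj[i, j] && comp[j] != comp[i]) {
      comp[comp == comp[j]] <- comp[i]; changed <- TRUE
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    lead <- idx[order(sig$p_diff[idx], sig$snp[idx])][1]
    list(lead = sig$snp[lead], members = sort(sig$snp[idx]))
  })
}
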