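test_that("ld_r2 captures perfect, negative and absent LD", {
  set.seed(101)
  g <- rbinom(200, 2, 0.4)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)
  g1 <- rbinom(10000, 2, 0.3); g2 <- rbinom(10000, 2, 0.3)
  expect_lt(ld_r2(g1, g2), 0.01)
  expect_error(ld_r2(rep(1, 100), g[1:100]), "constant")
  expect_error(ld_r2(c(0, NA, NA, 1), c(NA, 0, 1, NA)), "fewer than 3")
})

make_diff <- function(geno, p) {
  v <- geno$variants
  data.frame(chr = v$chrom, snp = v$id, bp = v$pos, a1 = v$a1, a2 = v$a2,
             beta1 = 1, se1 = 0.1, n1 = 100L, beta2 = 0, se2 = 0.1,
             n2 = 100L, r = 0, t = qnorm(p / 2, lower.tail = FALSE),
             p_diff = p, tier = ifelse(p < 5e-8, "genome-wide", "none"),
             stringsAsFactors = FALSE)
}

test_that("greedy clumping merges LD partners and splits distant signals", {
  set.seed(111)
  n <- 500
  a <- rbinom(n, 2, 0.3)
  b <- a; flip <- runif(n) < 0.02
  b[flip] <- rbinom(sum(flip), 2, 0.3)      # near-perfect LD with a
  c_ <- rbinom(n, 2, 0.3)                   # independent, 1 Mb away
  geno <- tiny_genotypes(cbind(a, b, c_), pos = c(100L, 200L, 1100200L),
                         ids = c("a", "b", "c"))
  diff <- make_diff(geno, p = c(1e-9, 1e-10, 1e-12))
  loci <- greedy_clump(diff, geno)
  expect_length(loci, 2)
  leads <- vapply(loci, `[[`, "", "lead")
  expect_setequal(leads, c("b", "c"))      # b beats a on p_diff
  ab <- loci[[which(leads == "b")]]
  expect_setequal(ab$members$id, c("a", "b"))
  # single significant variant -> a single self-locus
  solo <- greedy_clump(make_diff(geno, p = c(1e-9, 0.5, 0.5)), geno)
  expect_length(solo, 1)
  expect_equal(solo[[1]]$members$id, "a")
})

test_that("nearby independent leads merge by distance; clumps partition the significant set", {
  set.seed(121)
  n <- 400
  geno <- tiny_genotypes(matrix(rbinom(n * 6, 2, 0.3), n),
                         pos = c(1L, 100000L, 200000L, 1000000L, 2000000L,
                                 2200000L))
  p <- c(1e-9, 1e-10, 1e-11, 1e-9, 1e-9, 1e-12)
  diff <- make_diff(geno, p)
  loci <- greedy_clump(diff, geno, merge_window = 250000)
  members <- unlist(lapply(loci, function(cl) cl$members$id))
  expect_setequal(members, diff$snp)              # partition: every sig variant
  expect_equal(anyDuplicated(members), 0L)        # ...exactly once
  # v1-v3 merge by distance, v4 alone, v5-v6 merge
  expect_length(loci, 3)
})

test_that("clumping is invariant to input row order and matches the exhaustive oracle", {
  set.seed(131)
  n <- 600
  block <- function(m, flip = 0.02) {
    src <- rbinom(n, 2, 0.3)
    sapply(seq_len(m), function(i) {
      out <- src; redraw <- runif(n) < flip
      out[redraw] <- rbinom(sum(redraw), 2, 0.3); out
    })
  }
  dos <- cbind(block(3), block(2), block(4))
  geno <- tiny_genotypes(dos, pos = c(1e3, 2e3, 3e3, 2e6, 2.001e6,
                                      5e6, 5.001e6, 5.002e6, 5.003e6))
  p <- c(1e-9, 1e-12, 1e-10, 1e-9, 1e-11, 1e-15, 1e-9, 1e-10, 1e-8)
  diff <- make_diff(geno, p)
  loci <- greedy_clump(diff, geno)
  orc <- clump_oracle(diff, geno)
  expect_equal(length(loci), length(orc))
  got <- lapply(loci, function(cl) list(lead = cl$lead,
                                        members = sort(cl$members$id)))
  key <- vapply(got, `[[`, "", "lead")
  okey <- vapply(orc, `[[`, "", "lead")
  expect_setequal(key, okey)
  for (i in seq_along(got))
    expect_equal(got[[i]]$members, orc[[match(key[i], okey)]]$members)
  # row order invariance
  shuf <- diff[sample(nrow(diff)), ]
  loci2 <- greedy_clump(shuf, geno)
  expect_equal(as.data.frame(loci2), as.data.frame(loci))
})

test_that("raising r2_threshold or merge_window never increases locus count", {
  set.seed(141)
  n <- 500
  dos <- matrix(rbinom(n * 8, 2, 0.3), n)
  dos[, 2] <- dos[, 1]; dos[, 5] <- ifelse(runif(n) < 0.3,
                                           rbinom(n, 2, 0.3), dos[, 4])
  geno <- tiny_genotypes(dos, pos = as.integer(seq(1, 8) * 1e5))
  diff <- make_diff(geno, p = 10^-runif(8, 8.1, 15))
  n_loci <- function(r2, win) length(greedy_clump(diff, geno,
                                                  r2_threshold = r2,
                                                  merge_window = win))
  expect_gte(n_loci(0.5, 1e5), n_loci(0.1, 1e5))
  expect_gte(n_loci(0.5, 1e5), n_loci(0.5, 5e5))
})

test_that("manhattan table has increasing cumulative coordinates across chromosomes", {
  d <- data.frame(chr = c("2", "1", "1", "10"), bp = c(500L, 100L, 900L, 50L),
                  p_diff = c(1e-3, 5e-8, 0.2, 1))
  tab <- manhattan_table(d)
  expect_equal(tab$chrom, c("1", "1", "2", "10"))
  expect_true(all(diff(tab$cumpos) > 0))
  expect_equal(tab$neglog10p[1], -log10(5e-8), tolerance = 1e-12)
  expect_equal(unname(attr(tab, "thresholds")["genomewide"]), 7.30103,
               tolerance = 1e-5)
  expect_error(manhattan_table(data.frame(chr = "1", bp = 1L, p_diff = 0)),
               "0, 1")
})

test_that("qq table pairs sorted quantiles and lambda is calibrated under the null", {
  set.seed(151)
  p <- runif(10000)
  tab <- qq_table(p)
  expect_equal(nrow(tab), 10000)
  expect_true(all(diff(tab$observed) <= 0))
  expect_lt(abs(attr(tab, "lambda") - 1), 0.05)
  one <- qq_table(0.5)
  expect_equal(nrow(one), 1)
  expect_equal(qq_table(rep(1, 5))$observed, rep(0, 5))
  expect_error(qq_table(numeric(0)), "no p-values")
})
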