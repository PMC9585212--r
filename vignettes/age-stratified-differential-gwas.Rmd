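---
title: "Age-stratified GWAS and the correlation-corrected differential effect test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stratified GWAS and the correlation-corrected differential effect test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genetic effects on quantitative traits — obesity-related anthropometrics are
the motivating case — need not be constant over the lifespan. A variant can
be neutral at 45 and deleterious at 65, or reverse sign altogether.
A single pooled genome-wide association study (GWAS) averages over age and
can miss such variants entirely, because an effect that moves from `-b` to
`+b` across the age range averages to roughly zero.

`diffgwas` implements the stratified-comparison design for detecting these
age-dependent effects in a single cohort:

1. split the cohort into `k` age strata (quartiles by default);
2. run an ordinary covariate-adjusted linear GWAS within each stratum;
3. pick the pair of strata whose per-variant effect sizes are least
   correlated (in practice the youngest and oldest);
4. test each variant's difference in effect sizes with a
   correlation-corrected t-statistic;
5. clump genome-wide significant variants into independent lead loci using
   LD and distance rules.

## The model

Within stratum `s`, for each variant `j`, the association engine fits

```
y_i = b0 + b_js * g_ij + c' x_i + e_i
```

by OLS, where `g_ij` is the additive dosage (0/1/2 copies of the effect
allele) and `x_i` the covariates: age (still adjusted for *within* each
stratum, since strata span several years), sex, genotyping-array indicator
and ten principal components. This yields per-stratum estimates `b_js` with
standard errors `SE_js`; two-sided p-values use the t-distribution with the
residual degrees of freedom (numerically the normal at biobank-scale n).

For a chosen pair of strata the differential statistic for variant `j` is

```
t_j = (b_j1 - b_j2) / sqrt(SE_j1^2 + SE_j2^2 - 2 r SE_j1 SE_j2)
```

where `r` is the Spearman correlation between the two strata's beta
vectors, computed over all QC-passing variants shared by the pair. `r`
absorbs the correlation that shared sampling and polygenic signal induce
between the two estimates of the same variant: if the strata largely agree
(`r` near 1), a given difference in betas is more surprising and the null
variance shrinks accordingly. A single scalar `r` applies to every variant,
as the formula implies. Two-sided p-values (`P_diff`) come from the
standard normal; variants are tiered at `5e-8` (genome-wide) and `1e-6`
(suggestive).

Design decisions a reader should know, with the reasoning:

* **Normal reference for `t_j`.** With strata of hundreds to tens of
  thousands of individuals, the t and normal references are
  indistinguishable; the normal survival function also stays accurate to
  `p ~ 1e-300`, which matters at genome-scan significance levels.
* **`r` is the signed Spearman correlation of raw betas** over all shared
  QC-passing variants — not absolute values, not a pruned subset. It is
  configurable (`r_override`) for sensitivity analyses.
* **Pair selection** is the least-correlated pair; exact ties go to the
  widest stratum-index gap (so a tie between adjacent pairs and the
  youngest/oldest pair resolves to the latter), then lexicographic order.
* **Allele harmonization** between stratum tables: exact a1/a2 match, else
  swap-and-flip of the beta sign, else exclusion with a logged count.
  Strand-ambiguous (A/T, C/G) variants are not specially removed because
  both tables come from one genotype source.

## Variant QC and stratification

QC precedes stratification and runs on the full cohort. A variant is
removed when any of the following holds (strict inequalities):

| metric | rule | default |
|---|---|---|
| missing call rate | `> max_missing_rate` | 0.05 |
| minor allele frequency | `< min_maf` | 0.01 |
| exact HWE test p | `< min_hwe_p` | 1e-6 |

The Hardy-Weinberg test is the exact conditional test: conditional on the
observed allele counts, the p-value sums the probabilities of all
heterozygote counts (of matching parity) no more probable than the observed
one. It is computed by a mode-anchored recurrence with `cumprod`, which is
overflow-safe at any cohort size; ties in the inclusion rule use a `1e-12`
relative tolerance so the result does not depend on floating-point
tie-breaking.

Age strata use nearest-rank (type-1) empirical quantiles of the age vector,
and individuals are assigned by age *value*, so everyone sharing an age
lands in one stratum. With integer ages the groups are therefore only
approximately equal — exactly the behaviour seen in real biobank quartiles
— and fewer than `k` distinct ages is an error.

## Clumping

Lead loci are built in two stages from the variants with
`P_diff < 5e-8`:

1. **LD clumping.** Iterating in ascending `P_diff` (ties broken by
   variant id, making the output order-invariant), the best remaining
   variant becomes a lead and absorbs every remaining significant variant
   with `r^2 >= 0.1` to it. LD is the squared Pearson correlation of
   dosages over pairwise-complete individuals, computed from the analysis
   genotypes themselves (an external reference panel can be supplied as a
   VCF and converted with `read_vcf()`).
2. **Distance merging.** Leads on one chromosome within 250 kb of each
   other merge into one locus, keeping the most significant lead.
   Surviving leads are pairwise in low LD and more than 250 kb apart.

The intermediate "independent significant SNP" tier that some annotation
platforms insert at `r^2 < 0.6` is omitted: it does not change lead or
locus identity when leads are already required to be pairwise at
`r^2 < 0.1`.

## The synthetic-cohort generator

No individual-level biobank data ships with (or is needed by) the package.
`sim_config()` / `simulate_cohort()` generate cohorts carrying exactly the
statistical structure the analysis assumes:

* genotypes: per-variant MAF uniform on `maf_range`, dosages as two
  independent allele draws (exact HWE), entries masked missing with
  probability `missing_rate`; one synthetic chromosome with 5 kb spacing so
  a 250 kb clump window spans 50 variants; optional LD blocks made by
  copying a source variant's dosages with a per-entry re-draw probability;
* covariates: integer ages uniform on 40-69 years (an `age_weights`
  parameter can skew the distribution; the default is uniform, which does
  not replicate the unequal quartile widths of a real recruitment curve),
  sex Bernoulli(0.46) to echo the slight female excess of volunteer
  cohorts, array Bernoulli(0.5), PCs standard normal;
* phenotype: linear covariate effects plus, for each planted variant,
  a per-allele effect `a_j + c_j (age - reference_age)` — linear in age
  because quartile-wise effect estimates in published data show monotone
  trends and linearity is the minimal model consistent with them — plus
  Gaussian noise. Defaults are BMI-like (baseline 27, +0.05 units/year,
  residual SD 4). Missing dosages contribute their variant's mean observed
  dosage, so missingness does not shift the phenotype mean (a documented
  generator choice; the *analysis* never imputes, it drops incomplete rows
  per variant).

`truth_table()` returns exactly the planted effects, enabling recovery
tests. One master seed drives everything; each stage derives a documented
sub-seed from the stage name (`derive_seed()`), so stages are reproducible
in isolation and adding a stage does not perturb the others.

What passing tests on these cohorts does *not* show: robustness to
realistic LD (the generator's LD is block-copying, not coalescent),
population structure beyond Gaussian PCs, relatedness, non-linear age
profiles, or phenotype measurement artefacts. Results on real data depend
on upstream sample QC that is out of scope here.

## Numerical choices and degenerate inputs

* OLS via QR (`lm.fit`); standard errors from `chol2inv` of the R factor.
  Rank-deficient designs raise an error naming the aliased columns.
* Variants monomorphic within a stratum (or with fewer complete cases than
  design columns) yield flagged records (`beta = NA`) rather than errors,
  keeping per-stratum tables row-aligned.
* In `run_differential()`, a zero beta difference with zero corrected
  variance (identical inputs at `r = 1`) is defined as `t = 0`; a non-zero
  difference with non-positive variance is an error.
* Summary statistics serialize to TSV with 10 significant digits (p-values
  in scientific notation, 7 significant digits): lossless to printed
  precision and round-trippable, unlike space-aligned report formats.

## Simulation-study sizes

The packaged calibration and power studies (run by the test suite and by
`scripts/acceptance.R`) use cohorts of 4,000 individuals: 20,000 null
variants for type-I-error calibration of `P_diff` (the empirical
`P_diff < 0.05` rate and a Kolmogorov-Smirnov test against uniformity),
and 20 replicates of 500 variants with one planted age-slope variant for
power. The planted slope is sized analytically so the expected differential
|t| is 6 at that n, MAF 0.3 and residual SD 4. A useful closed form: with
expected statistic `m`, the probability of clearing the genome-wide
threshold `z = 5.45` is approximately `pnorm(m - z)` — about 0.71 at
`m = 6` — so single-replicate significance is expected, not guaranteed, at
this effect size.

## Limitations

* The differential test compares exactly two strata; a trend test across
  all `k` strata would use more information for monotone profiles.
* A single scalar `r` assumes the inter-stratum correlation is shared
  across variants; variants with extreme effects contribute to, but may
  not follow, the global rank correlation.
* Stratified designs lose power relative to an explicit gene-age
  interaction model when the interaction truly is linear; they are robust
  when it is not.
* Hard-call genotypes only (VCF GT); dosage/imputation formats (BGEN,
  PLINK binary) are out of scope.
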