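---
title: "Grading cumulative evidence across genetic association meta-analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading cumulative evidence across genetic association meta-analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasynopsis)
```

# The problem

Field synopses collect every published association between the variants of a
candidate gene and a panel of diseases and phenotypes, pool the study-level
estimates, and ask a harder question than any single meta-analysis: *how
credible is each pooled signal once heterogeneity, small-study bias and the
prior odds of a true association are taken into account?* `metasynopsis`
implements that workflow end to end for study-level records of the kind an
extraction sheet produces — an odds ratio with its confidence interval, raw
genotype counts, or per-genotype means for a quantitative trait — and grades
every significant pooled association on the combined Venice-criteria / FPRP
scale.

# Effect harmonization

All binary-outcome effects are expressed per copy of a designated (minor)
effect allele on the log odds-ratio scale; quantitative traits are expressed
as standardized mean differences (SMD) under co-dominant contrasts
(heterozygote, and minor homozygote, each against the wild-type homozygote).
Three converters feed the common `(theta, se)` representation:

* `theta_from_ratio_ci()` back-derives `se = (ln U - ln L) / (2 z)` from a
  reported ratio CI. The normal quantile is kept at full double precision
  (1.959964 at the 95% level) so a CI rebuilt from `(theta, se)` reproduces
  the inputs to six decimals.
* `additive_or_from_counts()` collapses genotype counts to allele counts
  (two per minor homozygote, one per heterozygote) and forms the
  cross-product OR with `se = sqrt(1/a + 1/b + 1/c + 1/d)`, adding the 0.5
  continuity correction to all four cells whenever one is empty. The
  allele-count table is the per-allele reading of an additive model; no
  dominant or recessive contrasts are offered.
* `smd_from_group_stats()` is Cohen's d with the n-weighted pooled SD. The
  Hedges small-sample correction exists behind `hedges = TRUE` but is off by
  default, matching the plain SMD convention of the synopsis literature.

Records carrying only a p-value are retained for bookkeeping but marked
non-poolable. Allele reorientation (`orient_to_effect_allele()`) negates
the coefficient, takes reciprocals of ratio bounds (swapping them),
reverses genotype and group-statistics columns, and is an involution; which
allele is "the" effect allele per variant is configuration, not inference —
recomputing minor-allele frequency by ancestry is out of scope.

# Pooling and the model switch

`fixed_effect_pool()` is the inverse-variance estimator; heterogeneity is
quantified by Cochran's Q on fixed-effect weights and
`I2 = max(0, (Q - df)/Q) * 100`. The between-study variance is the
DerSimonian–Laird method-of-moments value
`tau2 = max(0, (Q - df)/C)`, `C = sum(w) - sum(w^2)/sum(w)`, and
`random_effects_pool()` re-weights by `1/(se^2 + tau2)`. `select_and_pool()`
applies the synopsis rule: random effects when `I2 >= 50` (inclusive at the
boundary), fixed effects below. Pooled p-values are Wald-normal two-sided —
no Knapp–Hartung adjustment — because the synopsis convention reports
Wald-style CIs. Datasets need at least three studies to be eligible for a
main meta-analysis; smaller ones are retained but flagged. A single
pre-pooled record (for example a GWAS consortium estimate) passes through
labelled `not_pooled` with no heterogeneity statistics.

# Bias screens and sensitivity analyses

`egger_test()` regresses the standardized effect `theta/se` on precision
`1/se` by OLS and tests the intercept (t, k−2 df): under a common true
effect the line passes through the origin exactly, a property the test
suite asserts. `begg_test()` rank-correlates the fixed-effect standardized
deviates with the study variances; the Kendall statistic uses the tau-b tie
correction, an exact permutation null (computed from the Mahonian
inversion-count distribution) for k ≤ 8 without ties, and the tie-corrected
normal approximation otherwise. Both screens are read at the two-tailed
0.10 level conventional for bias tests. When every deviate is exactly zero
(a strictly constant effect) the correlation carries no information; tau is
reported as 0 with p = 1 rather than as an ill-defined ratio.

`sensitivity_suite()` re-pools each leave-one-out subset, the subset
without the first positive report, and the subset without studies whose
control genotypes violate Hardy–Weinberg equilibrium at 0.05 (threshold
configurable — the synopsis convention records HWE but not an exclusion
cutoff). An association is *robust* when every evaluable re-analysis stays
significant with an unchanged direction; arms reduced below two studies are
marked not-evaluable and excluded from the verdict rather than counted
either way.

# Hardy–Weinberg testing

The chi-square test (1 df, no continuity correction) is the default for
samples of 200 or more; below that an exact conditional test enumerates
heterozygote counts given the allele counts. The exact test orders the
sample space by the chi-square statistic — making it the small-sample
version of the asymptotic test — and reports both the conservative p
(full boundary mass) and the mid-p variant. On discrete support the exact p
moves in steps; at a total of 500 the step can reach ~0.04–0.09, so exact
and asymptotic p-values agree closely *on average* (mid-p mean absolute
difference ~0.015 in the test suite) but individual samples can differ by
a few hundredths. That lattice effect is inherent to conditioning, not a
numerical defect.

# Evidence grading

Venice letters grade three criteria, each configurable via
`venice_thresholds()`:

| criterion | A | B | C |
|---|---|---|---|
| amount of evidence (minor alleles among cases + controls) | > 1000 | 100–1000 | < 100 |
| replication (heterogeneity) | I2 < 25% with ≥ 3 datasets | 25–50% | > 50% |
| protection from bias | screens clean and robust | incomplete information | Egger or Begg p < 0.10, or not robust |

All-A is strong, all A/B moderate, any C weak; a criterion with missing
inputs renders as `-` and blocks both the all-A and the any-C routes.

The false-positive report probability is
`FPRP = alpha (1 - pi) / (alpha (1 - pi) + power * pi)` with power the
two-sided Wald probability of detecting a target odds ratio at level
`alpha` (the far-tail term is included). Defaults: prior `pi = 0.05`,
target OR 1.2 — reciprocal for protective effects, which leaves the power
unchanged since only `|ln OR1|` enters. The observed `alpha` is normally
the pooled p-value; `alpha_source = "ci_implied"` instead recomputes it
from the CI-derived `z = |ln OR|/SE`, which matters when the printed p has
been rounded. FPRP below 0.05 is strong, up to 0.20 moderate, above weak;
boundary values fall to the less-noteworthy side because the category
definitions are open intervals. The final cumulative evidence is the
Venice category shifted up one level when FPRP evidence is strong, down
one when weak, saturating at the ends.

Replaying the 41 graded rows of the packaged pooled tables through this
combination reproduces 39 of the 41 printed labels; the two exceptions
(one atrial-fibrillation row graded B-C with FPRP 0.026 but printed Weak,
and one fibrinogen row graded AAA with FPRP 0.150 but printed Moderate)
are preserved in the fixtures as printed and treated as known anomalies of
the source table rather than matched.

# Phenome-wide scan and LD pruning

`phewas_scan()` filters a phenotype summary table at the Bonferroni
threshold `fwer/m` (0.05/778 = 6.43e-5 for the packaged panel) and sorts
ascending by p. `ld_prune()` builds the graph with an edge wherever
`r2 > cutoff` — strictly, so a cutoff of exactly the block correlation
dissolves the block — and returns connected components in input order, the
first member (or a preferred variant) as representative. Both stages are
offline: the r-squared matrix and summary tables are supplied, never
queried.

# The synthetic generator

`simulate_binary_meta()` draws, per study, a true effect
`theta_i ~ N(theta, tau2)`, control genotypes multinomially in
Hardy–Weinberg proportions at the configured minor-allele frequency, and
case genotypes from the HWE weights tilted by `exp(theta_i)` per
minor-allele copy — the logistic-consistent counterpart of the per-allele
OR the pipeline estimates, so the generative OR converges to `exp(theta_i)`
as n grows (checked at n = 10^6 within 1%). Study sizes are drawn
log-uniformly within the configured range, reflecting that real
collections mix candidate-gene studies of a few hundred subjects with
GWAS-scale samples. Defaults: k = 10, maf = 0.30, sizes 200–2000 per arm.

`inject_small_study_bias()` models publication selection: small studies
(top tercile of SE) whose draw is not one-sided significant in the
generating direction are redrawn, with probability `gamma`, until a
"publishable" draw appears, keeping sizes and true effects. This is a
suppression model — it biases the small-study stratum upward and produces
funnel asymmetry — not a model of p-hacking within studies.

Simulation study sizes used by the test suite: 2,000 null replicates at
k = 10 for type-I calibration (observed ≈ 0.05); 500 replicates at k = 20,
theta = 0.2, tau2 = 0.03 for recovery (both means within ±0.01 of truth);
500 replicate pairs at k = 20 with sizes 50–5000 for the Egger operating
characteristics (power ≈ 0.78 under full suppression, size ≈ 0.08–0.11
clean). The generator emulates sampling noise, between-study heterogeneity
and selective publication; it does not emulate linkage disequilibrium
between variants, population stratification, genotyping error, or
covariate-adjusted estimates, so passing calibration here does not certify
behaviour under confounding.

# Numerical and design choices

* The 95% normal quantile is 1.959964 everywhere, never 1.96.
* Underflowed pooled p-values (Wald z beyond ~38) are floored at 1e-300
  before entering the FPRP, whose `alpha` must be positive.
* Grading runs only for associations significant at 0.05 from eligible
  (k ≥ 3) datasets; non-significant associations keep their meta block
  only.
* The pipeline is deterministic given inputs and configuration; report
  JSON serialization is byte-stable.
* Thresholds live in one `synopsis_config()` object (YAML-loadable):
  significance 0.05, bias screens 0.10, model switch at I2 = 50, HWE
  exclusion 0.05, FPRP prior 0.05 and target OR 1.2, categories split at
  0.05/0.20.

# Known limitations

* Venice amount-of-evidence needs genotype counts or a configured
  minor-allele frequency; without either the letter is `unavailable`.
* The SMD path emits co-dominant contrasts separately and does not pool
  heterozygote with homozygote contrasts.
* No meta-regression, ancestry subgrouping, cumulative meta-analysis,
  trim-and-fill, or Bayesian alternatives to the FPRP.
* The packaged pooled tables transcribe printed, rounded values; two of
  their FPRP entries and two cumulative labels are not reproducible from
  the printed inputs under any convention tested and are flagged rather
  than forced.
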