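# metasynopsis

Field-synopsis meta-analysis of genetic association studies, with
cumulative-evidence grading.

Candidate-gene literatures accumulate dozens of partially overlapping
association studies per variant–outcome pair. A field synopsis pools each
pair, then asks how much the pooled signal should be believed.
`metasynopsis` implements that workflow for study-level records (odds
ratios with confidence intervals, raw genotype counts, or per-genotype
means):

* **Effect harmonization** — per-allele (additive) log odds ratios from any
  of the three record forms, standardized mean differences for
  quantitative traits, allele reorientation to a designated effect allele,
  and Hardy–Weinberg testing in controls (chi-square and exact).
* **Pooling** — inverse-variance fixed effects and DerSimonian–Laird
  random effects with Cochran's Q, I², and τ²:
  θ̂ = Σwθ/Σw, τ̂² = max(0, (Q − df)/C), C = Σw − Σw²/Σw, switching to
  random effects when I² ≥ 50%.
* **Bias and sensitivity** — Egger's regression intercept and Begg's
  rank-correlation tests (exact permutation null for small k), plus
  leave-one-out, first-positive-report, and HWE-exclusion re-analyses.
* **Evidence grading** — Venice-criteria letters (amount, replication,
  protection from bias), the false-positive report probability
  FPRP = α(1−π) / (α(1−π) + (1−β)π) with Wald power against a target OR,
  and the combination rule (upgrade on strong FPRP evidence, downgrade on
  weak).
* **Phenome-wide stage** — Bonferroni scanning of phenotype summary tables
  and greedy r²-based LD pruning of variant panels.
* **Synthetic data** — a generator for case–control and quantitative study
  collections under an additive allele model with HWE controls,
  between-study heterogeneity, and optional small-study suppression bias,
  used to calibrate every stage.

## Worked example

```r
library(metasynopsis)

# simulate 8 case-control studies of a protective variant and run the
# whole pipeline on them
ds <- simulate_binary_meta(sim_config(k = 8, theta = -0.25, tau2 = 0.005,
                                      seed = 101,
                                      n_cases_range = c(300, 5000),
                                      n_controls_range = c(300, 5000)))
reports <- run_pipeline(as_study_table(ds))
reports[[1]]
```

```
rsSIM / simulated outcome (k = 8)
fixed-effects pool of 8 studies: OR = 0.814 (0.781, 0.849), p = 3.14e-22
  Q = 9.657 (df 7, p = 0.209), I2 = 27.5%, tau2 = 0.001481
cumulative evidence: strong (Venice moderate, FPRP strong)
```

The pooled OR of 0.814 recovers the generating effect exp(−0.25) = 0.779
within sampling error; moderate heterogeneity (I² = 27.5%) keeps the fixed
effects model; the association is significant, survives all sensitivity
arms, grades `ABA` on the Venice letters (replication B for the mid-range
I²), and its FPRP of ~4.4e-20 upgrades the final cumulative evidence to
strong.

Replaying the packaged pooled tables (one row per published meta-analysis)
counts the significant associations and regrades them:

```r
t1 <- load_pooled_table("table1")   # disease outcomes
count_significant(t1)
#>       n_total n_significant
#>            27            21
replay <- replay_cumulative(dplyr::bind_rows(t1, load_pooled_table("table2")))
sum(replay$matches_printed)         # 39 of 41 printed labels reproduced
```

The `analysis/` directory holds four narrative drivers that exercise the
package the same way — `01_simulate_calibration.R` (type-I error,
parameter recovery, Egger operating characteristics),
`02_replay_pooled_tables.R` (significance counts, FPRP recomputation,
evidence replay), `03_pipeline_demo.R` (end-to-end run on a synthetic
multi-outcome collection), `04_phewas_ld.R` (LD pruning and the
phenome-wide Bonferroni scan) — each writing its tables under `results/`.

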