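# reometa

Rank-based gene-pair risk classification and occult-metastasis
reclassification for tumor expression cohorts.

## What it does, and for whom

Clinically "nonmetastatic" early-stage lung adenocarcinoma is a
contaminated label: imaging misses small metastases, and those occult
cases blur every metastatic-vs-nonmetastatic contrast computed from
primary-tumor molecular data. `reometa` is for computational oncologists
who want to (1) classify *individual* samples by within-sample relative
expression orderings (REOs) of signature gene pairs — a rank-only rule
that needs no cohort normalization and survives any monotone per-sample
transform, hence transfers across microarray and RNA-seq platforms — and
(2) use those calls to re-define metastasis states before downstream
contrasts.

For a signature of ordered pairs $(G_a, G_b)$, the within-sample event
$E_a > E_b$ is a high-risk vote and $E_a < E_b$ a low-risk vote. A
`voting_rule(k, n)` labels a sample low risk iff at least $k$ of the $n$
pairs vote low: the majority rule uses $k=\lceil(n+1)/2\rceil$ (5 of 9),
the strict rule $k = 7$ of 9. `calibrate_threshold()` picks $k$ so the
high-risk fraction of a calibration cohort lands nearest an expected
relapse interval (default 35–50%). Reclassification keeps a sample
nonmetastatic only if it is clinically nonmetastatic *and* low risk.

Downstream, the package provides Kaplan–Meier / log-rank / Cox (Efron
ties) / Harrell C-index survival evaluation and 5-year event rates;
CV-filtered pooled-t differential expression with Benjamini–Hochberg
control; direction-concordance binomial tests; proliferation scoring;
hypergeometric gene-set enrichment; mutation and copy-number lesion
frequency, burden and expression–dosage (Spearman) analyses; and
driver-network construction linking recurrent lesions to differentially
expressed targets through a directed regulator network. A seeded
synthetic-cohort generator (`generate_cohort()`) emulates the assumed
statistical structure — latent metastasis state, occult label noise,
informative pair orderings, risk-dependent survival, planted lesions and
a planted driver — so the whole pipeline is testable offline.

## Worked example

```r
library(reometa)

co <- generate_cohort(cohort_params(seed = 7))      # synthetic cohort
calls <- classify_samples(co$expr, co$signature, voting_rule(7, 9))
head(calls, 3)
#>   sample_id evaluable_pairs high_votes low_votes tie_votes effective_k label
#> 1     S0001               9          9         0         0           7  high
#> 2     S0002               9          7         2         0           7  high
#> 3     S0003               9          4         5         0           7  high

risk_met_table(calls, co$clinical)
#>               high low
#> metastatic     132   2
#> nonmetastatic  164 102
fisher_association(risk_met_table(calls, co$clinical))$p
#> [1] 4.08e-19

surv <- build_survival_data(co$clinical, calls, "os")
cmp <- survival_comparison(surv)
#> HR 1.39, CI 0.97-1.98, logrank p 0.0686, C 0.543
#> 5-yr event rate high 0.63 low 0.56
```

Reading the output: sample S0003 has 5 low votes — low risk under the
majority rule (5 ≥ 5) but high risk under the strict 7/9 rule (5 < 7).
High-risk calls are strongly enriched among clinically metastatic samples
(Fisher p ≈ 4e-19), and the high-risk group trends toward worse overall
survival (hazard ratio 1.39 with a CI touching 1 on this seed — the
strict rule trades specificity for sensitivity, so its survival split is
noisier than its metastasis association).

A one-command run of every stage against files on disk:

```r
paths <- write_cohort(co, "cohort")
run_pipeline(pipeline_config(
  expr = "cohort/expression.tsv", clinical = "cohort/clinical.tsv",
  signature = "cohort/signature.tsv", maf = "cohort/mutations.maf",
  cna = "cohort/cna.tsv", region_map = "cohort/region_map.tsv",
  edges = "cohort/edges.tsv", gmt = "cohort/sets.gmt",
  out_dir = "out", k = 7))
```

writes risk calls, reclassified labels, DE tables, lesion tests, the
driver network, a `summary.json` and a `manifest.json` recording every
threshold. The same stages are scriptable via
`Rscript -e 'reometa::reometa_cli()' <simulate|classify|calibrate|run> ...`.

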