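# stainclass

Scoring and diagnostic evaluation of EGFR mutation-specific
immunohistochemistry (IHC) in lung adenocarcinoma.

Mutation-specific antibodies against the two classical activating EGFR
mutations — the exon-21 point mutation **L858R** and the exon-19
**E746-A750 deletion** — allow routine pathology labs to screen tumors for
EGFR-TKI-sensitising mutations without sequencing. Each antibody is read as
an intensity grade *I* ∈ {0,1,2,3} and a percentage *P* of stained tumor
cells, summarized by the quickscore **Q = P × I** (0–300). The catch:
wild-type tumors with high total-EGFR expression show weak nonspecific
staining with the mutation-specific antibodies, so the conventional
positivity rule (more than 10% of cells at 1+ or more) produces false
positives that track total-EGFR level.

`stainclass` implements the scoring method that corrects for this: a binary
logistic model combines the mutation-marker score with the total-EGFR score
into a predicted mutation probability

&nbsp;&nbsp;&nbsp;&nbsp;p̂ = logit⁻¹(β₀ + β₁·Q<sub>marker</sub> + β₂·Q<sub>total</sub>),&nbsp;&nbsp;&nbsp;&nbsp;typically β₂ < 0,

classified at the ROC vertex minimizing (1−sens)² + (1−spec)² and evaluated
against DNA-sequencing truth. The package is aimed at biostatisticians and
molecular-pathology researchers comparing IHC scoring schemes.

What's inside:

* **IHC scoring** — `quickscore()`, the conventional `intensity_positive()`
  rule, pan-cytokeratin quality gating.
* **Score combination** — `fit_logistic()` (IRLS with step-halving,
  separation detection, optional Firth fallback), `build_features()` for
  the six scoring schemes per target, `predict_probability()`.
* **ROC toolkit** — `roc_curve()` (empirical, Mann–Whitney AUC),
  `optimal_cutoff()` (closest-to-corner), `paired_auc_test()` (DeLong test
  for correlated AUCs), `auc_ci_delong()`.
* **Diagnostic metrics** — `diagnostic_metrics()` with an exact mode and a
  `"printed"` mode reproducing one-decimal clinical-table arithmetic,
  `pearson_chi2()`, `fisher_exact()`, `categorical_test()`, `wilson_ci()`.
* **Outcome analysis** — `km_estimate()`, `logrank_test()`, `cox_fit()`
  (Efron ties), `outcome_analysis()` for TKI response and
  progression-free survival by IHC status.
* **Synthetic cohorts** — `sim_config()` / `simulate_cohort()` /
  `simulate_outcomes()`: a seeded generator whose defaults reproduce the
  study conditions (genotype mix, cross-reactive staining driven by
  total-EGFR level, response-rate and PFS contrasts), so the whole
  pipeline is testable without patient data.
* **Pipeline** — `read_cohort()` / `write_cohort()` (validated TSV with a
  60% tumor-content enrollment gate), `run_pipeline()`, `write_report()`,
  plus a thin command-line wrapper in `inst/cli/stainclass.R`.

## Worked example

```r
library(stainclass)

quickscore(2, 40)
#> [1] 80

# diagnostic metrics from a 2x2 table of IHC calls vs sequencing truth
diagnostic_metrics(confusion_table(38, 23, 5, 77), "printed")
#> sensitivity 88.4%  specificity 77.0%  PPV 62.3%  NPV 93.9%  LR+ 3.843  LR- 0.151  accuracy 80.4% [printed]

# a full synthetic study: simulate, enroll, score, evaluate
cfg <- sim_config(seed = 7)
cohort <- simulate_outcomes(simulate_cohort(cfg), cfg)
enrolled <- cohort[cohort$tumor_content >= 60, ]
report <- run_pipeline(enrolled)
report
#> stainclass report: 143 patients
#>                                         scheme   auc sensitivity specificity accuracy
#>                                L858R intensity 0.896        89.1        81.4     83.9
#>                                   L858R qscore 0.920        91.3        86.6     88.1
#>         L858R intensity + total EGFR intensity 0.910        84.8        89.7     88.1
#>            L858R qscore + total EGFR intensity 0.922        89.1        92.8     91.6
#>            L858R intensity + total EGFR qscore 0.934        84.8        89.7     88.1
#>               L858R qscore + total EGFR qscore 0.949        91.3        92.8     92.3
#>                         delE746-A750 intensity 0.935        91.4        95.4     94.4
#>                            delE746-A750 qscore 0.935        91.4        95.4     94.4
#>  delE746-A750 intensity + total EGFR intensity 0.949        91.4        95.4     94.4
#>     delE746-A750 qscore + total EGFR intensity 0.946        91.4        95.4     94.4
#>     delE746-A750 intensity + total EGFR qscore 0.956        91.4        98.1     96.5
#>        delE746-A750 qscore + total EGFR qscore 0.952        91.4        96.3     95.1
#> L858R: best scheme 'L858R qscore + total EGFR qscore'; vs intensity-only AUC 0.949 vs 0.896 (p = 0.00538)
#> delE746-A750: best scheme 'delE746-A750 intensity + total EGFR qscore'; vs intensity-only AUC 0.956 vs 0.935 (p = 0.123)
#> TKI outcomes (n = 31): response 71.4% vs 40.0% (p = 0.127); log-rank p = 0.0169
```

Reading the output: each row is one scoring scheme with its AUC and the
diagnostic metrics at its closest-to-corner cutoff (printed-rounding
convention). On this seed the combined L858R model (Q score + total-EGFR
Q score) lifts the AUC from 0.896 (intensity alone) to 0.949, and the
DeLong paired test on the same 143 patients gives p = 0.005 — the
total-EGFR correction is doing real work. Among the 31 simulated
TKI-treated patients, IHC-positive tumors respond more often and progress
later (log-rank p = 0.017).

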