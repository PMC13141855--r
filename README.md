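# eadiag

Phenotype-based differentiation of episodic ataxia type 1 (EA1, *KCNA1*)
from type 2 (EA2, *CACNA1A*), for clinical researchers and methodologists
working on rare paroxysmal movement disorders. EA2 responds to
acetazolamide and 4-aminopyridine while EA1 does not, so a presumptive
clinical diagnosis matters wherever genetic testing is unavailable.

The package implements the full analysis pipeline around that question:

- a **curated case model** with tri-state (present / absent / unknown)
  semantics — unknown never counts as absent, so every feature has its own
  complete-case denominator — with lossless CSV/JSON serialisation and a
  shipped column schema;
- **feature engineering**: ordinal binning of attack duration (brief
  ≤ 10 min, intermediate ≤ 60 min, prolonged < 1 day, protracted ≥ 1 day)
  and frequency (daily / weekly / monthly / rare, 30-day month), a trigger
  taxonomy with an editable synonym dictionary, and any-of composites such
  as interictal peripheral muscular signs;
- **variant annotation**: ACMG-based diagnostic gating, LoF / GoF /
  unknown functional grouping, and the haploinsufficient vs
  non-haploinsufficient split used for genotype–phenotype comparison;
- **diagnostic accuracy statistics** per feature. For a binary feature the
  ROC has a single operating point and

  AUC = (sensitivity + specificity) / 2,

  with Hanley–McNeil confidence intervals, chi-square / Fisher association
  tests (Fisher when an expected count is < 5 or an observed cell is 0),
  ordinal ROC curves by cumulative threshold, and drug-response
  comparisons;
- **feature selection** (significant, AUC CI above 0.5, specificity
  > 90%, expert exclusions) and a **sequential rule-based classifier**
  with skip-on-missing semantics, an indeterminate outcome, per-case
  traces, and config-file override of the rule set;
- a **synthetic cohort generator** (independent group-conditional
  Bernoulli features, categorical attack metrics, log-normal onset age,
  per-feature missingness) plus a deterministic **core prevalence
  fixture** that reproduces every published group-level count.

## Worked example

```r
library(eadiag)

core <- core_prevalence_fixture()
core
#> <ea_cohort "core-fixture": 370 cases (EA1 94, EA2 276, unlabeled 0)>

tbl <- format_accuracy_table(accuracy_table(core))
tbl[tbl$feature %in% c("trigger_kinesigenic", "brief_attacks",
                       "interictal_nystagmus",
                       "peripheral_muscular_interictal"), ]
#>                         feature target_gene   n sensitivity_pct specificity_pct   auc          ci p_value  test_used
#>             trigger_kinesigenic       KCNA1 193            68.4            94.7 0.815 0.751-0.880  <0.001 chi_square
#>                   brief_attacks       KCNA1 264            75.3            94.0 0.846 0.790-0.903  <0.001 chi_square
#>            interictal_nystagmus     CACNA1A 326            63.4            98.8 0.811 0.763-0.858  <0.001 chi_square
#>  peripheral_muscular_interictal       KCNA1 326            82.5            99.2 0.908 0.864-0.953  <0.001 chi_square
```

Reading the rows: among the 264 cases with known attack duration, brief
attacks flag EA1 with 75.3% sensitivity and 94.0% specificity (AUC 0.846);
interictal nystagmus flags EA2 with 98.8% specificity. Feature selection
keeps the 13 high-specificity discriminators, and the default sequential
rule set classifies a fully observed synthetic cohort at those operating
points with high EA2 sensitivity and a low wrong-label rate:

```r
sel <- select_features(accuracy_table(core))
nrow(sel)
#> [1] 13

spec <- default_cohort_spec(n_ea1 = 300, n_ea2 = 300, missingness = FALSE)
evaluate_classifier(generate_cohort(spec, seed = 7))
#> <classifier evaluation: n=600>
#>      assigned
#> truth EA1 EA2 indeterminate
#>   EA1 297   3             0
#>   EA2  20 273             7
#> sensitivity: EA1 0.990, EA2 0.910
#> wrong-label rate 0.038, indeterminate rate 0.012
```

A thin command-line wrapper over the same functions ships in
`inst/cli/eadiag.R` (subcommands `summarize`, `accuracy`, `classify`,
`simulate`, `fixture`).

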