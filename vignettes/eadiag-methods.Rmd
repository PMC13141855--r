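---
title: "Distinguishing episodic ataxia types 1 and 2: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing episodic ataxia types 1 and 2: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Episodic ataxia type 1 (EA1, pathogenic *KCNA1* variants affecting the
Kv1.1 potassium channel) and type 2 (EA2, pathogenic *CACNA1A* variants
affecting the Cav2.1 calcium channel) are the two most common genetic
episodic ataxias. The distinction matters clinically — EA2 usually responds
to acetazolamide or 4-aminopyridine, EA1 to sodium-channel blockers — but
molecular confirmation is often unavailable in limited-resource settings.
`eadiag` implements a phenotype-based pipeline for this differential: a
curated per-subject case model, feature engineering of attack metrics and
triggers, per-feature diagnostic-accuracy statistics, ROC/AUC-based feature
selection, and a sequential rule-based classifier, together with a
synthetic cohort generator so the whole pipeline is testable without any
patient-level download.

## Case records and tri-state semantics

Published case reports omit data constantly, and treating "not reported" as
"absent" inflates specificity. Every symptom, trigger and sign is therefore
tri-state: present (1), absent (0), or unknown (empty/`NA`). Unknown drops
the case from that feature's denominator; it is never counted as absent.
Consequently each feature has its own evaluable `N`, and all accuracy
statistics are complete-case per feature. Diagnosis may be unknown at the
record level (the classifier's target use case is exactly the
genotype-unknown patient), but accuracy computations reject unlabeled
cases.

Subject uniqueness is keyed on `(source_ref, subject_id)` so cohorts merged
from several publications cannot collide. The flat CSV dialect (one column
per feature, tri-states as `1`/`0`/empty) and the nested JSON dialect are
documented in `inst/extdata/cohort_schema.yaml`; round trips are lossless,
and writing is a fixed point (write–read–write is byte-identical).

## Feature engineering

Attack duration is binned as brief (<= 10 min), intermediate (> 10 and
<= 60 min), prolonged (> 1 h and < 1 day), protracted (>= 1 day); the
boundary semantics follow the source inequalities literally, so 10 min is
brief, 60 min intermediate, 1440 min protracted. Frequency uses a fixed
30-day month and 7-day week, giving cut points at 30, 30/7 and 1 attacks
per month for daily/weekly/monthly/rare; the calendar convention is a
package choice that makes binning deterministic, since the source defines
the categories only through per-day/week/month inequalities. A reported
range collapses to its maximum and a reported mean to itself
(`collapse_range()`), mirroring the curation rule for extracted values.

Trigger labels map through an editable YAML synonym dictionary onto
kinesigenic / exercise-induced / non-kinesigenic categories, with the
thirteen non-kinesigenic subtypes (alcohol ... excitement, plus "other").
Unmatched labels fall back to non-kinesigenic/other with a warning rather
than failing, because curation vocabularies evolve. Exercise-induced is its
own category and counts toward neither the kinesigenic nor non-kinesigenic
columns; the source totals do not resolve this either way, and keeping the
categories disjoint is the conservative reading.

`peripheral_muscular_interictal` is an any-of composite over clinical
myokymia, neuromyotonia, EMG myokymia and other stated peripheral muscular
signs: present if any component is present, unknown only if all components
are unknown. The composite is defined this way because its published
sensitivity (82.5%) exceeds every individual component's, which is only
possible for a union. The classifier helpers
`trigger_kinesigenic_or_startle` and `duration_prolonged_or_protracted` use
the same any-of convention.

## Variant annotation

Only pathogenic or likely pathogenic variants are diagnostic; VUS, benign,
likely benign and unmappable legacy variants exclude the case, as do
*CACNA1A* repeat expansions (SCA6, a different disease mechanism).
Functional grouping is rule-based: truncating effects (nonsense,
frameshift, out-of-frame deletion, splice with predicted premature stop)
with predicted nonsense-mediated decay are LoF through haploinsufficiency;
any variant with a decreased-function study is LoF (non-haploinsufficient
unless the truncating rule also applies), with dominant-negative missense
variants flagged but grouped LoF; increased-function studies give GoF;
everything else predicted to be translated is "unknown". NMD prediction is
a curator-supplied input flag, not computed — deriving it would need
transcript coordinates and genome resources that are out of scope — and a
splice variant with an unset flag stays "unknown" by design. The
genotype–phenotype split contrasts haploinsufficient carriers against all
other diagnostic-variant carriers.

## Statistics

For a binary feature the ROC curve has one interior operating point and the
AUC reduces to (sensitivity + specificity)/2; the package computes it that
way and the identity with the explicit three-point trapezoid is
property-tested. Ordinal features get one cumulative threshold per
category level, oriented by which end of the scale favors the target gene,
with trapezoidal AUC. AUC confidence intervals use the Hanley–McNeil
standard error with a normal interval clipped to [0, 1]; the source does
not state its CI method (SPSS defaults to a nonparametric SE), so interval
*containment and width*, not exact bounds, are the comparable quantities.

Association tests follow the Pearson chi-square (no continuity correction,
matching SPSS "Pearson Chi-Square" reporting) with a switch to the
two-sided Fisher exact test when any expected cell count is below 5 *or*
any observed cell is zero. The zero-cell clause is deliberate: the source
reports Fisher precisely for its zero-cell comparisons (startle,
menstruation) whose expected counts are all above 5, so the textbook
expected-count rule alone would not reproduce its test choices. It also
reports Fisher for a few small-but-nonzero tables (caffeine, heat, anxiety)
that no simple rule captures; for those the package reports the chi-square
and does not claim to match the test label. Continuous variables gate on
Shapiro–Wilk (alpha 0.05) per group: both normal gives Welch's t-test,
otherwise Mann–Whitney. The Fisher path is verified against a
hypergeometric tail enumeration written from the probability mass
definition for every 2x2 table with N <= 30, and the Mann–Whitney path
against exhaustive permutation for group sizes up to 8.

Presentation rounding is half-up: percentages to one decimal, AUC to three,
matching the source tables. One edge is worth recording: the interictal
any-ataxia specificity implied by the back-solved counts is 73/80 = 91.25%,
which strict half-up rounding prints as 91.3 while the source prints 91.2;
the AUC (0.672) agrees exactly, so the counts are retained as-is.

## Feature selection and the classifier

Selection keeps features that are significant at alpha = 0.05 *and* whose
AUC confidence interval lies entirely above 0.5, then applies the
specificity floor (> 90%), then removes the expert-consensus exclusions —
ictal fatigue and gastrointestinal symptoms, dropped in the source for
being too subjective/heterogeneous to extract reliably. Survivors are
ranked by descending specificity (ties: descending sensitivity, then name),
making the output invariant to input order. On the reconstructed core
accuracy table this retains 13 features.

The published management flowchart's exact branch topology is not printed
in the text, only its ingredients and its sequential, specificity-first
logic. The shipped `default_ruleset()` is therefore a documented
reconstruction — seven present-state rules ordered by specificity
evidence: brief attacks -> EA1; interictal peripheral muscular signs ->
EA1; interictal nystagmus -> EA2; ictal headache -> EA2; kinesigenic or
startle trigger -> EA1; interictal ataxia -> EA2; prolonged-or-protracted
duration -> EA2 — and the rule set is fully overridable from a YAML/JSON
file, so a reader with the figure can encode it exactly. A rule whose
feature is unknown is skipped and recorded; a case matching nothing is
indeterminate, a first-class outcome (decision support, not forced
choice), and sensitivity computations count indeterminate as a miss.
`first_match` is the default conflict policy; `specificity_weighted_vote`
is provided for sensitivity analysis of the rule-order assumption. The
published test-cohort figure (87.5% EA2 sensitivity, 21/24) depends on
supplementary case-level data and the unprinted topology, so it is not
desk-reproducible; the package instead anchors the classifier with an
operating-point property — on synthetic cohorts at the core marginals with
no missingness (300 cases per group), EA2 sensitivity stays at or above
0.80 and the wrong-label rate at or below 0.10 across 20 seeds — and the
evaluation helper reproduces the 21/24 = 87.5% arithmetic on a cohort
constructed to that outcome.

## The synthetic generator and the core fixture

`generate_cohort()` emulates exactly the structure the source states:
group-conditional independent Bernoulli presence/absence at the published
prevalences, four-level categorical duration and frequency at the
published category proportions (with a raw value drawn uniformly inside
the drawn category's interval, protracted capped at 7 days; the intervals
sit strictly inside the bins so a rounded value always re-bins to its
category), right-skewed log-normal age of onset moment-matched on the log
scale to the published median and IQR, and per-feature missingness at the
published rates. Feature independence within group is the default because
only marginals are published; inventing correlation silently would
misrepresent the data, so co-occurrence is opt-in via `correlation_plan`.
What the generator does *not* model: publication/reporting bias, curation
error, within-patient symptom correlation, and secular trends — so a
passing pipeline test demonstrates correctness of the computations under
the stated marginal structure, not clinical validity on real cohorts.

`core_prevalence_fixture()` is different: a deterministic, sampling-free
370-case cohort whose marginal counts equal every published group-level
count. Trigger, duration, frequency, drug-response and demographic counts
are printed directly in the source; the ictal/interictal sign counts are
not printed as fractions but are uniquely back-solvable from each row's
evaluable N, sensitivity and specificity (for example the interictal
block solves to 80 evaluable EA1 and 246 EA2; nystagmus 156/246 vs 1/80).
Every back-solved table reproduces the printed
sensitivity/specificity/AUC triple. Two documented source inconsistencies
are resolved in favour of the self-consistent accuracy table: startle
38/77 (the body text's 39/77 contradicts its own 49.4%), and the
kinesigenic EA2 denominator 114 (N = 193 minus 79; the body text's /115
contradicts N). The EA1 missing-duration count is 13 (94 minus 81
evaluable); the printed 22 is arithmetically impossible. The sex table
stores the printed counts (58/94 vs 111/276), whose chi-square p is
0.0003; the printed p = 0.003 matches the printed 44% rather than the
printed count. Within-case co-occurrence in the fixture is arbitrary
(presence packed into low-index cases) but fixed and bit-stable, so only
marginal statistics — which is all the downstream analyses use — are
meaningful on it.

The ordinal duration ROC on the fixture's four category counts gives AUC
0.874; the source figure prints 0.88 (95% CI 0.822–0.929), plausibly
computed on continuous durations that the printed tables do not provide.
Both values are documented; the categorical 0.874 is the testable surface.

## Problem sizes and numerical choices

Parameter-recovery checks run at 5000 cases per group, where three
binomial standard errors separate every published prevalence from its
neighbours; classifier operating-point checks use 20 seeds of 300 cases
per group, sized so that the binomial noise on a rate near 0.88 is about
0.02. The Fisher oracle sweep enumerates all 46k tables with N <= 30.
Age-at-report is generated but never anchored (the published group SDs are
identical to the digit, likely a typo, so the column is treated as
unreliable). Degenerate inputs are handled explicitly: zero-margin tables
give p = 1 with a warning, single-level ordinals give a flat ROC with AUC
0.5, all-missing features raise a classed degenerate-table error, and
`accuracy_table()` omits such features with a warning rather than failing
the run.

## Known limitations

The fixture's per-case co-occurrence is synthetic, so any analysis that
conditions on more than one feature at a time (including the classifier)
is only meaningful on generated cohorts, not on the fixture. The default
rule set is a reconstruction, not the published figure. The generator's
independence assumption is optimistic for the classifier: real EA1
features co-occur (myokymia with kinesigenic triggers), which would, if
anything, make sequential classification easier, so the operating-point
envelope is a conservative floor only under the stated marginals. Aura is
collected in the schema but ignored by the analyses, mirroring the source,
which collects it and reports no statistic for it.
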