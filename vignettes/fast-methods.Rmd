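---
title: "FAST: scoring model, validation machinery and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAST: scoring model, validation machinery and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastscore)
```

## The scoring model

The Fluid Assessment Scoring Tool (FAST) grades ten bedside indicators of
fluid accumulation — four laboratory/chart values (BUN trend, urine specific
gravity, net fluid balance, weight change), urine output, four physical
findings (fontanelle, eyes, liver edge, skin edema) and chest imaging — each
on an ordinal 0–3 severity scale, and sums them. With every variable
measurable the total spans 0–30; in practice several variables are
structurally unmeasurable (closed fontanelles in older children; urine
output on diuretics or in renal failure) and the total simply omits them.
The score is a screening aid for fluid **overload**: every variable is
oriented so that higher means more fluid, and observations in the opposite
physiological direction — rising BUN, concentrated urine, net-negative
balance, weight loss — score 0 rather than negative. Oliguria
(< 1 mL/kg/h off diuretics) is flagged with a warning because it sits
outside the rubric's normal band while still not indicating overload.

### Bin boundaries

The published bins are printed as integer ranges with seams that are
ambiguous in continuous data ("15% to 25%" followed by "26% to 50%";
"1 to 2 cm" followed by "2 to 3 cm"). We fix a single convention:
continuous half-open bins whose shared edge belongs to the more severe side,
i.e. \[15, 26) → 1 and \[26, 50\] → 2 for the BUN decrease, \[1, 2) / \[2, 3\]
for the liver edge, \[7, 11) / \[11, 15\] for weight gain, \[15, 30) /
\[30, 50\] for fluid balance, and (3, 3.5\] / (3.5, 4\] for urine output.
This is deterministic, monotone in each variable, and leaves no unmapped
value in the physiologic range — properties the test suite checks by dense
grid. The "severe" urine-specific-gravity bin (< 1.000) is kept verbatim for
completeness although urine cannot physically reach it; with this rubric the
variable effectively contributes 0–2 points.

### Missing data

Missing subscores are omitted from the sum with no reweighting; the
accumulated score of the remaining variables is taken to stand in for the
lost one. Encounters missing more than two variables are marked invalid and
excluded from all downstream analysis. We deliberately provide no
imputation: the tool is designed to be robust to one or two absent
variables, and imputing ordinal severity grades would manufacture precision.
The analysis unit is the *encounter*, not the patient — multiple encounters
per patient enter independently with no clustering adjustment, mirroring how
the score was developed.

## Validation machinery

### Cut-point table

For each integer cut $c$, the rule "FAST $\ge c$ predicts overload" is
compared against the binary high-TFC reference label: sensitivity is the
positive-class survivor function $P(\text{score} \ge c \mid \text{TFC high})$,
specificity is $P(\text{score} < c \mid \text{TFC normal})$, and the
correctly-classified column is exact accuracy $(TP + TN)/N$. Sensitivity
and specificity carry exact binomial (Clopper–Pearson) 95% intervals —
`binom.test`'s intervals — which reproduce the interval style of the
development study (72/78 → 92%, 84%–97%). The numeric value of the binary
"high TFC" threshold is never part of the model: the label is an input, with
`label_tfc()` as a configurable helper.

### Reconstruction of the development dataset

Because the score is integer-valued, the published cut-point table is
sufficient to reconstruct the full score-by-label dataset: the sensitivity
column is the positive-class survivor function and $1-$specificity the
negative-class one, so differencing adjacent rows and multiplying by the
class sizes (78 and 40) recovers the per-score counts exactly. Scores above
the last printed cut are lumped at that cut (8), which cannot affect any
tabulated quantity. `fast_fixture()` performs this reconstruction, checks
that the rounded counts sum exactly to the class sizes, and the suite
verifies the round trip: re-tabulating the reconstructed data reproduces all
27 published percentage cells at two-decimal precision, and the pooled
distribution has median 4 with IQR (2, 6).

### AUC and cross-validation

`empirical_auc()` is the pair-counting AUC — the probability a random
TFC-high encounter outscores a random TFC-normal one, ties credited ½ —
computed via midranks, and the suite checks its exact equality with the
trapezoidal area of the ROC polygon and with a brute-force double loop. A
dichotomized rule $1\{\text{score} \ge c\}$ has AUC
$(\text{sens} + \text{spec})/2$.

The cross-validation design deserves comment because the procedure it
mimics is underspecified in most score-development reports. The score is a
*fixed* rule — there is nothing to refit per fold — so k-fold
cross-validation here measures the sampling variability of the operating
characteristics: folds are stratified by label (class proportions preserved;
remainders distributed by the seeded shuffle), each held-out fold
contributes the AUC of its own encounters (dichotomized at the chosen cut,
or rank-based for the continuous score), and fold AUCs are averaged. A fold
that happens to contain a single class has no defined AUC and is dropped
with a warning — at 10 folds on 118 encounters with 40 negatives this does
not occur, but it can in small simulated cohorts. The seed is mandatory;
the full procedure is reproducible from it. Percentile intervals are taken
across repeat means (across folds when `n_repeats = 1`); we offer the
percentile interval only and do not claim it as the method behind any
published interval, which is unstated. With 200+ repeats at 10 folds the
grand mean of the ≥3-dichotomized AUC on the reconstructed dataset is
0.799 — consistent with the published 0.79 and inside its 0.72–0.88
interval — and the suite checks concentration of the repeated mean at
$(\text{sens}+\text{spec})/2$ within ±0.03.

### Cut-point selection

Three policies are exposed. `balanced` (the development study's) minimizes
$|\text{sens} - \text{spec}|$, breaking ties toward higher accuracy and then
the lower cut; on the reconstructed data it selects ≥4 (79.49% vs 80.00%).
`max_accuracy` selects ≥3 (83.90%, the column maximum). `youden` maximizes
$J = \text{sens} + \text{spec} - 1$ and also selects ≥3 here, by a 0.003
margin over ≥4 — a reminder that at this sample size the two candidate cuts
are near-equivalent, which is exactly why both were reported.

### Outcome comparisons

`mann_whitney()` implements the rank-sum test in the reporting convention of
clinical tables: $U$ by midranks, tie-corrected normal approximation
$z$, the statistic reported as $\chi^2 = z^2$ with 1 df, and a two-sided
$p$. For combined $n \le 12$ the $p$-value switches to exact enumeration of
all relabelings (fraction with $|U - E U|$ at least the observed); the
enumeration agrees with `wilcox.test(exact = TRUE)` on tie-free data. The
normal approximation is *not* exact at small $n$: full enumeration over
every tie-free configuration with combined $n \le 10$ bounds the two-sided
discrepancy at 0.237, which is why the exact mode exists and is the default
there. `compare_outcomes()` joins scores to outcome records on
`encounter_id`, splits below/at-or-above the cut, and reports medians with
Tukey-hinge (median-of-halves) IQRs — the quartile rule is fixed and
documented because reports rarely state theirs. Charts violating
ventilator ≤ PICU ≤ hospital days draw a warning, not an error, since real
charts can.

## The synthetic cohort generator

`generate_cohort()` draws a latent two-state cohort: each encounter is
fluid-overloaded with probability 0.66 (the development prevalence), the six
numeric rubric variables follow state-conditional normal distributions, the
four categorical ones state-conditional multinomials over their severity
levels, and unmeasurability enters both structurally (60% closed
fontanelles, 30% on diuretics/renal failure) and as random per-variable
missingness (5%). The TFC reference is Gaussian per state (means 30/54, sd
8/10) thresholded at 40 into the binary label, so label noise relative to
the latent state is part of the model. Outcomes are negative-binomial day
counts built cumulatively (ventilator, + PICU increment, + hospital
increment; dispersion 1.5) so the ordering constraint holds by
construction, with means placing medians in the 8–20-day range typical of
this population.

The default emissions were calibrated once so that the class-conditional
FAST totals resemble the reconstructed development data (label-conditional
means ≈ 2.1 and 5.3 against 2.03 and 4.97; pooled median 4, IQR 2–6; AUC
≈ 0.84 at large n) and then frozen. They are *illustrative*: the real
per-variable distributions are unreported, and the generator makes no
attempt to model within-patient correlation, longitudinal trajectories, or
the joint dependence of variables beyond the shared latent state. Passing
tests on synthetic cohorts therefore demonstrates that the pipeline's
statistics behave correctly under a known truth (prevalence recovery,
missingness arithmetic, AUC limits under separation, small-sample bias of
operating characteristics), not that the score performs at any particular
level in real patients.

`recover_operating_characteristics()` quantifies the small-sample question
directly: against ground truth from a large Monte-Carlo cohort under the
same parameters, sensitivity/specificity estimates at the study's n = 118
are nearly unbiased but carry RMSE of several percentage points — the
variability that motivates external validation at larger sample sizes.

## Numerical and interface choices

Problem sizes in the shipped tests are chosen for a fast default run:
1,000-dataset AUC-equivalence sweeps at n ≤ 30, 200-dataset enumeration
checks at combined n ≤ 10, 1,000 null replicates for the type-I check at 60
encounters, 200 cohort replicates for prevalence recovery, and a 50,000-row
oracle with 60 replicates for the bias harness. Percentages render at two
decimals throughout, matching the published table layout. CSV is the
interchange format: empty cells are missing values, categorical levels are
the lowercase identifiers documented in `compute_fast()`, and every random
operation takes an explicit seed, so all pipeline artifacts regenerate
byte-identically. Free-context columns (boluses, blood products, dialysis)
pass through unscored. Known limitations: no age-specific rubric variants,
no imputation, no DeLong-type AUC comparison intervals, and no modelling of
repeated encounters within patients.
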