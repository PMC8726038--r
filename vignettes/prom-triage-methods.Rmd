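---
title: "Methods: PRO-based triage of hip arthroplasty follow-up"
author: "promtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRO-based triage of hip arthroplasty follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promtriage)
```

## The problem

Total hip arthroplasty (THA) patients are routinely seen about six weeks
after surgery. Most are recovering well and need no physical or X-ray
examination, so their consultation could happen by video; a minority
need to be in the hospital. Since many orthopedic services already collect
patient-reported outcome measures (PROMs) at fixed timepoints, a natural
triage signal is already available: a patient whose 3-month questionnaire
reports substantial pain or walking limitation is the patient a surgeon
wants in the clinic.

`promtriage` implements that idea as a tested pipeline with four parts:

1. **Instruments** — scoring, validation and direction recoding for the
   standard PROM set (NRS pain at rest and during activity, EQ-5D-3L with
   EQ VAS, Oxford Hip Score, HOOS-PS, and an anchor question).
2. **Clinimetric item selection** — a six-stage procedure reducing a
   candidate set of threshold questions to the items that actually carry
   signal.
3. **Triage engine** — threshold criteria applied disjunctively per
   patient, plus cohort-level allocation summaries and a rate comparison.
4. **Synthetic cohorts** — a latent-Gaussian ordinal simulator supplying
   cohorts with the structure the analysis assumes, so the entire pipeline
   is testable without patient-level data (none is publicly deposited).

## Instruments and conventions

Item ranges and directions follow the published instruments: NRS 0 (no
pain) to 10 (severe pain); EQ-5D-3L dimensions 1 (no problems) to 3
(extreme problems); EQ VAS 0–100 (higher better); OHS items 0–4 and total
0–48 (higher better); HOOS-PS items 0–4 summarized linearly on 0–100
(higher worse); anchor 1–7 (higher better). Two conventions matter
downstream:

* **Direction recoding.** Homogeneity analysis needs all items on a common
  direction. A higher-is-worse item is reflected within its range,
  `min + max − value`, which is an involution and preserves the range.
* **Complete-case totals.** An instrument total is `NA` unless every item
  is present. The official OHS rule (mean-impute up to two missing items)
  is available as `score_ohs_total(..., impute = TRUE)` but is off by
  default: per-item complete-case accounting keeps every denominator
  explicit and matches how per-question analyses are reported. The HOOS-PS
  nomogram transformation is deliberately not implemented — the linear
  0–100 rescaling is only used for baseline comparison, never by the
  triage rule.

## The triage engine

A rule is an ordered set of criteria, each `item, comparator, cutoff,
group`, with the comparator always pointing to the worse side of the item
(`>=` for higher-worse, `<=` for higher-better). Two rules ship as package
data: the nine-question candidate set assembled by clinical and research
expert panels (pain criteria: NRS rest/activity ≥ 4, EQ-5D-3L question 4
≥ 3, OHS questions 1 and 10 ≤ 1, OHS questions 8 and 12 ≤ 2; crutches
criteria: EQ-5D-3L question 1 ≥ 3, OHS question 6 ≤ 2), and the six-question
final tool that survives selection.

**Combination policy.** A patient is allocated to hospital when *any*
criterion is crossed. The source study does not state a combination rule
explicitly; disjunction matches its clinical intent — the panels wanted to
see every patient who might need a physical examination, accepting liberal
hospital criteria. A conjunction-within-group variant
(`policy = "group_all"`) is available for sensitivity analysis.

**Missing data at triage.** A missing rule item is treated as not crossed
but flagged in the outcome. A patient with *no* observed rule item is
`UNALLOCATABLE`: reported separately, counted to hospital under the
conservative operational default, and always excluded from the allocation
proportion (the proportion's denominator is patients with at least one
observed item).

**Rate comparison.** `compare_rates()` builds the 2×2
hospital/video-by-cohort table and applies Pearson's chi-square, falling
back to Fisher's exact test when any expected count is below 5. For 2×2
chi-square both the uncorrected and the Yates continuity-corrected
statistics are reported: statistical packages differ in their default, the
two can straddle conventional rounding boundaries (on the allocation table
with margins 201/502 vs 150/313 they give p ≈ 0.166 and p ≈ 0.187), and
reporting both makes the choice visible rather than silent.

## The six-stage selection procedure

`run_selection()` applies, in order, on the training cohort:

1. **Distribution** (3-month scores): an item whose first quartile, median
   and third quartile coincide shows no distinction between patients and
   is removed (`DEGENERATE_DISTRIBUTION`).
2. **Floor effect**: more than 15% of respondents at the worst score
   (direction-aware) removes the item (`FLOOR_EFFECT`). The inequality is
   strict: exactly 15% does not flag.
3. **Responsiveness**: Wilcoxon signed rank on paired preoperative vs
   3-month scores; an item with p > 0.05 cannot separate recovery from
   non-recovery and is removed (`NOT_RESPONSIVE`).
4. **Patient journey**: patients observed at 3 and 12 months are split by
   whether their 3-month score crossed the item's threshold; if the
   worse-at-3-months group "scores well" at 12 months the item's alarm
   carries no prognostic information and it is removed (`JOURNEY_FLAG`).
5. **Correlation pruning**: among surviving items, Spearman correlations
   (pairwise-complete, average ranks) at or above the cutoff define
   redundant sets (connected components); exactly one item per set is
   kept, the rest are removed (`CORRELATION_PRUNED`).
6. **Homogeneity**: within each clinical criteria group (pain, crutches),
   Cronbach's α with "scale if item deleted" on common-direction scores;
   an item whose deletion raises α above both the group's α and 0.7 does
   not fit its group and is removed (`HOMOGENEITY`). A two-item group is
   never reduced — a single remaining item has no internal consistency to
   measure.

Each removal records the earliest stage that fired, so reasons are
exclusive and ordered; re-running the procedure on the retained rule makes
no further removals. The stage order itself (distribution → floor →
responsiveness → journey → correlation → homogeneity) is a design choice:
the qualities are listed in this order in the clinimetric literature the
procedure follows, and running correlation pruning late means redundancy is
resolved among otherwise-valid items only.

### Design decisions worth knowing about

**Correlation cutoff: two shipped profiles.** The stated redundancy
criterion is r ≥ 0.7, but the observed removals in the source analysis
occurred at r = 0.659 and −0.676 — below 0.7 and consistent with the
0.6 presentation cutoff used in its correlation table. Rather than
silently resolving the discrepancy, both profiles ship:
`stated_profile()` (cutoff 0.7) and `paper_profile()` (cutoff 0.6 with a
keep-list preferring NRS pain during activity, encoding the expert
panels' choice). The profile is recorded in every report.

**Keep policy inside a redundant set.** Default: keep the item with the
largest absolute responsiveness effect (matched-pairs rank-biserial
correlation from stage 3), ties broken lexicographically. The original
choice was made by experts, not by an algorithm, which is why an explicit
keep-list reproduces it deterministically.

**Journey flag policy.** The journey criterion is qualitative ("scored
well later"). Two operationalizations are provided. The default,
`"relative"`, flags an item only when the worse-at-3-months group's
12-month median is *strictly better* than the better group's — i.e., the
trajectories actually swapped and the 3-month alarm was noise. The
alternative, `"threshold"`, flags when the worse group's 12-month median
no longer crosses the threshold. The threshold variant is much stricter
than it looks: in a well-recovering THA population almost every worse
group improves past its threshold by 12 months while remaining clearly
worse than the comparison group, so the variant would flag nearly every
item and contradicts how the criterion was actually applied (items whose
worse groups improved past their thresholds, yet stayed worse than their
comparison groups, were all retained). It ships as a sensitivity option;
the relative policy is the default. Whatever the policy, no verdict is
computed when either group has fewer than five patients — the group median
is then uninformative, and the flag is left `NA` with a warning field.

**Quartile method.** Quartiles use linear interpolation between order
statistics (R's type 7). Commercial packages often use the weighted-average
variant (type 6); the method is a `selection_config()` field and is
recorded in every distribution summary, because degeneracy judgments can
differ between methods on coarse ordinal scales.

**Deletion policies.** Correlations use pairwise-complete observations;
Cronbach's α uses listwise-complete rows. This mirrors the per-question
denominators of PROM datasets, where each item has its own missingness.

## Statistical primitives

* **Wilcoxon signed rank (responsiveness).** Zero differences are
  discarded. With ≤ 25 nonzero pairs the *exact* tie-aware null
  distribution of the positive-rank sum is computed by dynamic programming
  over doubled average ranks (doubling makes tied half-ranks integral);
  the two-sided p doubles the smaller tail. Beyond 25 pairs the normal
  approximation with continuity and tie correction is used. Base R's
  `wilcox.test()` offers no exact path under ties, which is why the exact
  branch is implemented here and cross-checked in the tests against full
  2^n enumeration.
* **Spearman correlation.** `stats::cor(method = "spearman")` on
  pairwise-complete pairs; p-values from the t approximation
  `t = ρ√((n−2)/(1−ρ²))`. A constant column yields an undefined ρ,
  reported as `NA` and never flagged.
* **Cronbach's α.** `α = k/(k−1)(1 − Σs²ᵢ / s²ₜ)` with sample variances;
  zero total variance is undefined and reported as `NA`.
* **Continuous cohort comparison.** Shapiro–Wilk at α = 0.05 on each
  sample decides between a t test (Welch by default; pooled available)
  and Mann-Whitney U (normal approximation with tie correction).
  Zero-variance samples count as non-normal.
* **Percentages** are rounded half-away-from-zero to one decimal, and
  reports carry the exact fraction alongside the rendering.

## The synthetic cohort generator

No patient-level data accompanies the source analysis, so the generator is
a first-class module, not a test fixture. It emulates:

* a two-cohort THA population (training n = 746, surgery 2016–2017; test
  n = 482, surgery 2018), ages ~66, BMI ~26, ASA I ≈ 55%;
* near-complete preoperative response and > 90% postoperative response
  (per-timepoint nonresponse 0.1% / 5% / 7%, per-item skip 0.3%);
* strong preoperative-to-3-month improvement and slight further
  improvement by 12 months;
* inter-item correlation with a per-patient random effect inducing
  3-to-12-month tracking;
* a ≈ 30% rate of crossing at least one final-tool threshold at 3 months.

**Model.** For patient *p*, item *i*, timepoint *t*, the latent severity is
`z_pit = λᵢ(μ_t + u_p) + ε_pit`, with `u_p ~ N(0, τ²)` (τ = 1),
`ε ~ N(0, 1)` correlated across items by a residual correlation matrix,
and `μ_PRE = 2.2, μ_M3 = 0, μ_M12 = −0.25`. Item cutpoints are placed at
the latent quantiles of specified 3-month severity-level probabilities, so
3-month marginals are controlled directly regardless of τ, and
preoperative/12-month marginals follow from the μ shifts. Severity maps to
the raw score respecting item direction. A latent-Gaussian-with-cutpoints
model was chosen because every selection stage (degeneracy, floor,
Spearman, α, journey tracking) has tunable, analyzable behavior under it.

**Calibration.** `calibrate_crossing_rate()` finds a scalar shift of the
3-month cutpoints matching a target crossing probability, by bisection on
a common-random-numbers Monte-Carlo sample (the empirical rate is then a
monotone step function of the shift). Monte-Carlo size should be chosen so
that the sampling error is small relative to the tolerance one cares
about; the default 5000 gives a standard error of about 0.0065 at a rate
of 0.3, and the parameter-recovery checks in the test suite use 50,000.

**The engineered paper-like fixture.** `make_paperlike_fixture()` deviates
from the base configuration in exactly the ways that give every selection
stage a known outcome: OHS question 10's 3-month severity mass (87% at the
best level) makes its quartiles collapse; residual correlations of 0.5
between NRS activity and each of NRS rest and OHS question 1 put those two
pairs (and only those) above the 0.6 cutoff on the observed ordinal scale
(≈ 0.63–0.72 at n ≈ 700, with all other pairs below ≈ 0.5); all items are
responsive by construction of the μ shift; no item has a 3-month floor
above 15%; and τ = 1 tracking keeps worse-at-3-months groups worse at 12
months. Under `paper_profile()` the procedure therefore removes exactly
{NRS rest, OHS question 1, OHS question 10} — one degenerate-distribution
removal, two correlation prunings — and retains the six final-tool items.

**What the generator does not emulate.** Real PROM data has structured
missingness (paper vs digital administration, reminder effects), floor and
ceiling behavior that varies by item wording, non-Gaussian latent
trajectories (bimodal recovery, complications), and demographic
confounding of outcomes. Passing tests on synthetic cohorts therefore
demonstrate that the *procedure* behaves as specified under its own
assumptions, not that the selected items or the ≈ 30%/70% split would
reproduce on another hospital's data.

## Problem sizes and determinism

Everything is deterministic given a seed: generation, calibration,
selection, triage. The test suite works at the study's own scale where it
matters (746/482-patient fixtures for selection replication) and at
reduced scale elsewhere: parameter recovery uses 100 replicate cohorts of
n = 1000 per target rate; the null-calibration check of the allocation
comparison uses 1000 simulated cohort pairs of n = 400. These sizes give
Monte-Carlo standard errors several times smaller than the tolerances they
are checked against.

## Known limitations

* EQ-5D-3L index values are value-set dependent and out of scope; only raw
  dimension scores and the EQ VAS are modelled.
* The expert-panel process that produced the candidate questions and
  thresholds is configuration data here, not something the package can
  re-derive.
* The package evaluates allocation behavior, not clinical safety:
  sensitivity/specificity of the tool against clinician judgment requires
  prospective data that does not exist yet.
* The journey stage's strictness is essentially untested by real data (no
  item was ever removed for journey reasons in the source analysis), so
  its two policies should be read as bracketing reasonable behavior.
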