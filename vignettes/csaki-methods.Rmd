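---
title: "Methods: full-KDIGO AKI detection on fused EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-KDIGO AKI detection on fused EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csaki)
```

## The problem

Acute kidney injury (AKI) after cardiac surgery is defined by the KDIGO
consensus through three criteria — serum creatinine dynamics, sustained low
urine output, and initiation of renal replacement therapy — but most
retrospective analyses can only apply the creatinine part, because hourly
urine output lives in a different hospital system (the ICU patient data
management system, PDMS) than the surgical and outcome data (the hospital
information system, HIS). `csaki` implements the complete chain: linkage
and fusion of the two sources, full-KDIGO staging on the harmonized
time series, and the downstream outcome analyses. A synthetic-cohort
generator with a ground-truth ledger closes the loop so that every claim
the package makes about itself is checked by executable tests.

## Fusion model

**Linkage.** Both extracts share a unique patient identifier. Duplicate
identifiers within the HIS patient table are a hard data error.

**Surgery-to-ICU mapping.** The PDMS extract carries no explicit admission
table (as is typical of observation-level exports), so ICU stays are
reconstructed from the documentation itself: a patient's observation
timestamps are clustered, and a gap longer than `stay_gap_h` (default 24 h)
starts a new stay; the stay interval is [first, last] observation. Each
surgery is then mapped to the *earliest* stay whose admission falls in
`(surgery end, surgery end + icu_window_h]`. The mapping window defaults to
48 h — wide enough for delayed ICU admission after an intermediate-care
detour, narrow enough not to capture readmissions — and is configurable
because the clinically correct value is site-specific. Surgeries without a
qualifying stay are flagged unmapped and excluded from staging, and
observations outside the mapped stay are discarded.

**Redundancy resolution.** Clinical parameters are often recorded by
several source processes of different quality (e.g. an ICU scale vs. an
admission interview for body weight). When the same parameter/timestamp
pair appears from several processes, the value with the best (numerically
lowest) `quality_rank` wins; rank ties are broken by the lexicographically
smallest process name. Resolution is therefore deterministic and
independent of row order, which the test suite checks by shuffling.

**Computability filter.** An episode is analyzable iff at least one
criterion family can be evaluated: ≥ 2 urine observations, or ≥ 1 serum
creatinine, or ≥ 1 dialysis record (a disjunction — one computable family
suffices). Excluded episodes carry the list of failed criteria, and the
filter emits the cohort-flow counts (raw → linked → ICU-mapped →
computable). No imputation is performed anywhere in the package; missing
bins and parameters stay missing.

## Staging semantics

**Urine output.** Volumes (mL) are summed onto an hourly grid — bin *t*
covers `(t-1, t]` hours since surgery end — and divided by body weight
(latest weight at or before the bin end; before the first weight, the
first available weight is back-filled, since a weight is required for
normalization). Unobserved bins are *gaps*, never zeros: a missing
collection is not anuria. At every bin the engine evaluates **all
contiguous gap-free windows ending there**; stage 1/2 require a window of
≥ 6/≥ 12 h with mean rate < 0.5 mL/kg/h, stage 3 a window of ≥ 24 h with
mean < 0.3 mL/kg/h or ≥ 12 h of anuria. Stages are cumulative (a stage-3
window also satisfies the stage-1 and stage-2 conditions). Events are
emitted at the first bin where each stage's condition first holds; the
event time is the *end* of the qualifying window, i.e. detection time.

The KDIGO text does not fix whether "< 0.5 mL/kg/h for 6 h" means the mean
over the window or every single hour. The default is the windowed **mean**
(`uo_window_mode = "mean"`), which is the stricter-incidence, more common
automated reading; `"all"` (every hourly rate below threshold) is
implemented and selectable. Both are exercised in the tests.

**Creatinine.** At each measurement, (a) the absolute rule: value minus
the minimum of all measurements in a rolling 48 h lookback (plus the
baseline while the lookback still reaches surgery) ≥ 0.3 mg/dL → stage 1;
(b) the ratio rules within 7 days of surgery end: 1.5–1.9× baseline →
stage 1, 2.0–2.9× → stage 2, ≥ 3.0× or an absolute value ≥ 4.0 mg/dL →
stage 3. The stage at a time point is the maximum satisfied band. The
baseline is the preoperative creatinine when available (the natural
reading, since risk tables report preoperative values), otherwise the
first post-operative measurement; the provenance is recorded. With no
creatinine anywhere the criterion is skipped — that is an exclusion
question, not an error.

**Dialysis.** Any session is stage 3, at the start of the first session.

**Combination.** `first_time` is the earliest event over all criteria;
`first_stage` the highest stage among events at exactly that time;
`max_stage` the highest stage overall, `max_time` the earliest time it is
reached. The triggering criterion is that of the first event; ties at an
identical timestamp are broken by a fixed priority, default creatinine >
urine > dialysis. The priority is arbitrary (the sources give no rule) but
deterministic and configurable, and only matters for attribution, never
for staging.

## Numerical choices

* Strict thresholds stay strict under floating point: window means are
  compared against `0.5 - 1e-9` and `0.3 - 1e-9`, because 24 bins of
  exactly 0.3 already sum to slightly less than 7.2 in binary arithmetic.
  A rate of exactly 0.5 mL/kg/h therefore never stages.
* The inclusive creatinine delta is guarded the other way:
  `rise >= 0.3 - 1e-9`, so a rise of exactly 0.3 mg/dL qualifies.
* Logistic regression is fit by IRLS with convergence `|Δdeviance| <
  1e-8`, at most 100 iterations; weights are floored at `1e-10`.
  Non-convergence and separation (fitted probabilities collapsing to 0/1
  on data points, or runaway coefficients) are flagged on the result and
  suppress the Wald intervals — never silent. Wald (not
  profile-likelihood) intervals match the `OR [95% CI]` convention of the
  clinical literature.
* The Pearson chi-square carries no continuity correction; a zero
  expected count is a degenerate-table error. Its asymptotic p is
  validated against the permutation null (`r2dtable`) via the *mid-p*
  (the observed atom counts half), which is the quantity a continuous
  approximation targets on a discrete null.
* The Wilcoxon rank-sum test uses the tie-corrected normal approximation,
  two-sided, without continuity correction; identical samples give p = 1.
* Kaplan–Meier and the log-rank test are delegated to the `survival`
  package; survival time is days from surgery end to in-hospital death,
  censored at discharge. With no events or a single stratum the log-rank
  is reported `NA`, not 0.
* The power simulation calibrates the model intercept so the *marginal*
  mortality matches the requested rate given prevalence and odds ratio
  (solved by `uniroot` to 1e-12), then tests the exposure Wald term. For
  one binary covariate the logistic Wald statistic equals the closed-form
  `log(ad/bc)/sqrt(1/a+1/b+1/c+1/d)`, which is what each replicate
  computes; replicates with an empty cell cannot reject.

## The synthetic cohort: what it emulates, and what not

The generator's defaults state one fixed world, calibrated to the margins
of a large published cardiac-surgery cohort (n = 8564): maximum-stage
probabilities `(none, 1, 2, 3) = (2530, 1695, 3256, 1083)/8564` (overall
AKI incidence 70.5%), per-stage mortality `22/2530, 26/1695, 59/3256,
268/1083` encoded as a logistic intercept plus per-stage log-odds
increments, the nine-procedure case mix with an "Other" remainder,
detection attribution urine/creatinine/dialysis = 0.868/0.121/0.011 (the
dialysis share concentrated on stage-3 patients at the conditional
probability that preserves the margin), and a derangement-onset
distribution (lognormal, median 12 h, clamped to 4–36 h) that puts the
median first-stage detection near 18 h post-operatively. Where the
sources state no value the defaults are fixed once at clinically
plausible levels and documented here: 2% of patients emitted with
insufficient computable data, 50% weight redundancy across sources,
preoperative creatinine lognormal with median ≈ 0.95 mg/dL clipped to
[0.5, 1.9].

**Construction by inversion.** For a target stage *s*, the oliguric block
is drawn inside bands that keep a provable safety margin to the
neighbouring thresholds under the windowed-mean semantics: stage 1 at
0.35–0.45 mL/kg/h for 6–9 h (9 h is the maximum for which no 12-h window
mixing normal-rate hours can dip below 0.5), stage 2 the same band for
12–20 h (a mean below 0.3 is impossible when every rate is ≥ 0.35), stage
3 at 0.15–0.25 for 26–32 h. Creatinine-detected episodes jump to 1.7× /
min(2.4×, 3.9 mg/dL) / 3.5× baseline; benign measurement noise elsewhere
is capped at ±0.06 mg/dL so the 0.3 delta rule cannot fire accidentally.
Consequently the detector must reproduce the ledger's maximum stage on
*every* computable episode — the inversion test requires 100% agreement,
not a correlation. Nominal first-stage times in the ledger are the
construction values (onset + 6 h on the urine route); windows straddling
the onset can legally detect a cumulative lower stage up to ~3 h earlier,
so tests pin the maximum stage, not the first-detection hour.

What the generator does **not** emulate: creatinine kinetics beyond
threshold crossings, hemodynamics, vasopressors, transfusions, fluid
balance, inter-criterion correlation within a patient, and any joint
procedure × stage structure beyond the margins (the sources publish only
margins). Covariates (age, BMI, EuroSCORE II, comorbidity count) are
weakly stage-associated so that descriptive tables behave plausibly, but
their effect sizes are not calibrated to anything. A green inversion test
therefore establishes that the detector implements the stated staging
semantics exactly — it does not establish performance on real, messy
physiology, where observation patterns (gap structure, charting delays)
differ.

## Degenerate inputs

Empty event lists yield a "no AKI" assessment, not an error. A cohort
with no AKI at all produces a zero-incidence summary, `NA` attribution
fractions, an intercept-only mortality model (constant columns are
dropped from the design), and an `NA` power result. Empty strata in rate
tables report `NA` percentages, never 0. The computability filter is
total and idempotent.

## Known limitations

* ICU stays are reconstructed from observation gaps; genuinely contiguous
  back-to-back stays would merge. Real deployments with an admission table
  should map from it directly.
* The windowed-mean urine semantics is a documented choice, not a ground
  truth; incidence is sensitive to it (the `"all"` mode is strictly less
  sensitive).
* Wald intervals undercover near separation; the separation flag is a
  coarse guard, not a replacement for penalized fits.
* The power simulation's exposure definition (binary AKI vs. none) is one
  of several possible readings of a "post hoc power for the main
  regression"; other readings (per-stage exposure, different tests) give
  different numbers, which is why no published power figure is used as an
  acceptance value.
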