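# csaki

Detection and outcome analysis of **cardiac surgery-associated acute kidney
injury (CSA-AKI)** from fused electronic health records.

AKI after cardiac surgery is common but systematically under-recognized,
because most studies apply only the serum-creatinine part of the KDIGO
consensus definition. When the *full* criteria — creatinine **and** urine
output **and** renal replacement therapy — are applied to dense ICU
time-series data, reported incidences reach 60–70%, and even stage 1 AKI
carries prognostic weight. Doing this at cohort scale requires linking two
hospital systems that do not interoperate: the hospital information system
(HIS: demographics, comorbidities, surgeries, discharge outcome) and the
ICU patient data management system (PDMS: timestamped creatinine, hourly
urine volumes, body weight, dialysis sessions).

`csaki` implements that pipeline end to end for epidemiologists and
intensive-care data scientists:

* **fusion** — patient-identifier linkage, mapping of each surgery to the
  earliest ICU stay within a configurable window (default 48 h), resolution
  of redundantly collected parameters by source quality rank, and the
  computability exclusions (an episode is analyzable iff it has ≥ 2 urine
  observations, or ≥ 1 creatinine, or ≥ 1 dialysis record), reported as a
  cohort-flow;
* **kdigo** — full KDIGO staging on the harmonized series. Urine output:
  stage 1 = mean rate < 0.5 mL/kg/h sustained ≥ 6 h, stage 2 = < 0.5
  sustained ≥ 12 h, stage 3 = < 0.3 sustained ≥ 24 h or anuria ≥ 12 h,
  evaluated over *all contiguous gap-free windows* (gaps break windows; no
  imputation). Creatinine: rise ≥ 0.3 mg/dL within a rolling 48 h, or
  1.5–1.9× / 2.0–2.9× / ≥ 3.0× baseline (or ≥ 4.0 mg/dL) within 7 days.
  Any dialysis session is stage 3. Output per episode: first stage and
  time, maximum stage and time, and the triggering criterion;
* **stats** — stratified AKI/mortality rate tables, Pearson chi-square,
  tie-corrected Wilcoxon rank-sum, Kaplan–Meier/log-rank survival,
  logistic regression (IRLS, Wald CIs `exp(β ± 1.96·SE)`) for first and
  maximum AKI stage, and a simulation-based post hoc power calculation;
* **synth** — a seeded generator that emits the two-source extracts plus a
  ground-truth ledger, built by *inverting* the detector: each emitted
  series satisfies the KDIGO condition for exactly its target stage, so
  detector output must equal the ledger. Every downstream stage is thereby
  testable without any patient data.

## Worked example

```r
library(csaki)

spec  <- cohort_spec(n_patients = 500, seed = 42)   # defaults mirror a large
sim   <- generate_cohort(spec)                      # published cohort's margins
fused <- fuse_cohort(sim$his, sim$pdms)
fused
#> Fused cohort
#>   raw        500
#>   linked     500
#>   icu_mapped 500
#>   computable 489
#>   final      489

det <- assess_cohort(fused)
```

489 of 500 synthetic patients pass the computability filter (the default
spec emits 2% with insufficient data). The cohort summary prints:

```
AKI incidence: 69.9% (342 of 489)
first AKI stage after median 17 [14; 22] h post-operatively
max stage after median 22 [18; 29] h
criterion attribution: urine 87.4%, creatinine 12.0%, dialysis 0.6%
```

i.e. roughly seven in ten episodes develop AKI, detected mostly through the
urine-output criterion within the first post-operative day — the structure
the generator is calibrated to. The detector inverts the ground-truth
ledger exactly:

```r
m <- merge(det$assessments, sim$ground_truth, by = "patient_id")
mean(m$max_stage == m$true_max_stage)
#> [1] 1
```

Fitting the mortality model on a larger ledger recovers the simulated
stage–mortality gradient (odds ratios vs. no AKI):

```r
gt <- generate_ground_truth(cohort_spec(n_patients = 5000, seed = 7))
gt$aki_stage <- factor(gt$true_max_stage, 0:3,
                       c("none", "stage1", "stage2", "stage3"))
logistic_fit(death ~ aki_stage, gt)
#>               term estimate     se    or ci_lo ci_hi      z  p_value
#> 1:     (Intercept)  -4.8040 0.2899  0.01  0.00  0.01 -16.57 1.08e-61
#> 2: aki_stagestage1   0.5741 0.3956  1.78  0.82  3.86   1.45 1.47e-01
#> 3: aki_stagestage2   0.5983 0.3468  1.82  0.92  3.59   1.73 8.45e-02
#> 4: aki_stagestage3   3.6075 0.3046 36.87 20.30 66.98  11.84 2.29e-32
```

Stage 3 carries a massively elevated death odds (the simulated stage-3
mortality is ~25% against ~0.9% without AKI); the stage 1/2 increments are
positive but need more than 5000 patients to clear significance — which is
exactly how the real cohort behaves for the maximum-stage encoding.

Feeding *published* contingency counts straight into the rate table
reproduces the printed percentages (the "golden-counts" mode):

```r
rt <- rate_table_from_counts(
  data.table::fread(system.file("extdata", "reference_counts.csv",
                                package = "csaki")))
round(rt[rt$stratum == "All", aki_pct], 1)   #> 70.5
```

The full pipeline (simulate → fuse → detect → analyze, with all report
files and a run manifest) is one call, or one shell command:

```r
run_pipeline(run_config(spec = spec, out_dir = "out", seed = 42))
```

```sh
Rscript inst/cli/csaki run --n 500 --seed 42 --out out
```

## Documentation

The methods vignette (`vignettes/csaki-methods.Rmd`) describes the staging
semantics, the synthetic-data model and its limits, numerical choices and
design decisions.
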