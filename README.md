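# qtcds

Evaluation pipeline for interruptive clinical decision support (CDS) alerts
against drug-induced long-QT syndrome (diLQTS).

## The problem

Hospital EHR systems deploy interruptive point-of-order alerts for ten
QT-prolonging culprit medications (ondansetron, haloperidol, azithromycin,
levofloxacin, escitalopram, citalopram, sotalol, droperidol, methadone,
hydroxychloroquine). The alert fires when a patient with **any prior ECG
showing a Bazett-corrected QTc ≥ 500 ms** has one of these drugs ordered.
Whether such a rule actually prevents diLQTS — not merely flags high-risk
patients — is an empirical question that requires the whole system to be
evaluated: alert logic, provider responses, downstream ordering and
administration behavior, and clinical outcomes, with proper handling of
repeated hospitalizations per patient.

`qtcds` implements that evaluation as a tested, reusable pipeline for
biostatisticians and clinical informaticists. Because the motivating EHR
data are access-restricted, the package ships a fully synthetic EHR
generator with a ground-truth effect registry, so every stage is testable
end to end and parameter recovery can be verified against known truth.

## What's inside

| Stage | Functions |
|---|---|
| QTc computation | `qtc_bazett()`, `qtc_adjusted_fridericia()` (QTc = (QT − max(0, QRS − 100)) / RR^(1/3)), `derive_qtc()` |
| Outcome adjudication | `aggregate_qtc()` (pre/post-exposure windows), `adjudicate_dilqts()` (max post QTc ≥ 500 ms or rise > 60 ms) |
| Alert & compliance | `fire_alert_rule()`, `classify_action()` (comply = "Remove single order"), `classify_compliance()` (48 h order / 72 h administration rules with four missingness recodes), `classify_cds_era()`, `build_index_events()` |
| Comorbidity clusters | `build_vocabulary()` (top-500 diagnoses/medications), `encode_features()`, `kmeans_hamming()` (binary-mode K-means), `elbow_scan()`, `assign_clusters()` |
| Cohort summaries | `smd()`, `cluster_or()` (population-standardized measures), `response_table()`, `era_table()`, `compare_groups()` |
| Marginal models | `gee_fit()` (logistic/Poisson GEE, exchangeable within-patient correlation, sandwich SEs), `wald_joint_test()`, `predict_margins()`, `fit_marginal()`, `run_analysis_suite()` |
| Synthetic EHR | `generator_config()`, `generate_ehr()`, `write_bundle()`, `read_bundle()` |

The statistical core is a marginal (population-averaged) regression fit by
generalized estimating equations: for outcome \(y_{ij}\) of encounter *j*
in patient *i*,

    g(E[y_ij | x_ij]) = x_ij' beta,   Corr(y_ij, y_ik) = alpha  (exchangeable)

with `g` the logit (diLQTS, mortality) or log link (hospital days,
quasi-Poisson), `alpha` estimated by moments, and robust sandwich standard
errors. Effects are reported as odds ratios / incidence-rate ratios with
95% CIs and predictive margins by marginal standardization.

## Worked example

```r
library(qtcds)

cfg <- generator_config(n_patients = 5000, seed = 42)   # stated-world defaults
ds  <- generate_ehr(cfg)                                # 9-table EHR bundle + truth
ev  <- build_index_events(ds$bundle)                    # one row per (encounter, drug)

mean(ev$alert_fired)   # 0.082  -> ~8.2% of index orders trigger the alert
mean(ev$dilqts)        # 0.083  -> ~8.3% adjudicated diLQTS

fit <- gee_fit(dilqts ~ alert_fired, ev, id = "patient_id", family = "binomial")
print(fit)
#> Marginal binomial GEE (exchangeable), 8634 obs in 5000 clusters
#> alpha = 0.03027  phi = 0.9993
#>                 estimate robust_se    exp  lower  upper        z p
#> (Intercept)      -2.4992    0.0432 0.0821 0.0755 0.0894 -57.9071 0
#> alert_firedTRUE   0.8991    0.1149 2.4573 1.9618 3.0779   7.8249 0

predict_margins(fit, list(alert_fired = TRUE))$margin    # 0.168
predict_margins(fit, list(alert_fired = FALSE))$margin   # 0.076
ds$ground_truth$true_crude_or_alert_dilqts               # 2.197 (known truth)
```

The alert identifies high-risk orders: diLQTS probability 16.8% when the
alert fires versus 7.6% when it does not (crude OR 2.46, 95% CI 1.96–3.08
at this sample size; the generator's configured conditional OR is 2.28 and
its implied crude estimand 2.20, inside the CI). Population-standardized
summary measures work directly from printed table cells:

```r
smd(62.73, 59.19, 17.94)    # 0.197 -> age SMD +0.20 for a cluster
cluster_or(67.36, 19.66)    # 8.43  -> ICU odds ratio for a cluster
```

## Command line

A thin CLI over the same functions (see `inst/cli/qtcds`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "qtcds", package = "qtcds"))')
Rscript $CLI simulate  --n-patients 2000 --seed 1 --out bundle
Rscript $CLI cohort    --data bundle --out index_events.csv
Rscript $CLI cluster   --data bundle --events index_events.csv --k 4 --seed 42 --out clusters.csv
Rscript $CLI summarize --events index_events.csv --clusters clusters.csv --out tables
Rscript $CLI model     --events index_events.csv --clusters clusters.csv --suite alert --out report
```

## Scope notes

The package evaluates the CDS *system*; it does not reimplement the EHR
vendor's alert plumbing, waveform-level QT measurement, torsade-de-pointes
event modeling, or causal-inference corrections (propensity scores,
interrupted time series) — era contrasts are reported with an explicit
calendar-time confounding caveat. See the methods vignette
(`vignettes/qtcds-methods.Rmd`) for the model, generator design, numerical
conventions, and known limitations.
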