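---
title: "qtcds: methods, design choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qtcds: methods, design choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## 1. The evaluation problem

An interruptive EHR alert fires at order entry of one of ten QT-prolonging
medications whenever the patient has any prior ECG with a Bazett-corrected
QTc of at least 500 ms. Evaluating whether this system prevents
drug-induced long-QT syndrome (diLQTS) requires following the full causal
chain — alert firing, the provider's in-alert action, the downstream
signed order and drug administration, the post-exposure ECG — across
repeated hospitalizations of the same patients. `qtcds` implements each
link as a separately tested operation and ties them together over flat
EHR-like tables.

The analysis unit is the **index event**: one (encounter, culprit
medication) pair, anchored at the first order of that medication in that
hospitalization. A patient contributes one event per medication per
encounter, and arbitrarily many encounters.

## 2. QTc, adjudication, and timing conventions

Two corrections are used with deliberately different roles:

* **Bazett**, `QT / sqrt(RR)`, is what the bedside carts store and is the
  quantity the *alert rule* thresholds at 500 ms.
* **QRS-adjusted Fridericia**, `(QT - max(0, QRS - 100)) / RR^(1/3)`, is
  the *analysis* correction used for the pre/post aggregates and the
  diLQTS definition. The printed expression is parsed as
  subtract-the-QRS-excess-then-rate-correct: that is the established
  wide-complex adjustment, it reduces to plain Fridericia for QRS ≤ 100
  ms, and it makes QTc = QT at RR = 1 s — the convention every QTc formula
  shares. QT and QRS are in milliseconds, RR in seconds.

**diLQTS** is adjudicated per index event as: maximum post-exposure QTc
≥ 500 ms (inclusive — "a QTc of ≥500") **or** a rise of more than 60 ms
(strict — "over 60") above the pre-exposure maximum. A missing
post-exposure window leaves the adjudication *missing*, not negative; a
missing baseline disables the rise clause only.

Window conventions:

* Pre-exposure aggregates cover **all** ECGs strictly before the index
  order, across the patient's full history — matching the alert rule's
  "any prior ECG". An encounter-scoped variant is available
  (`pre_scope = "encounter"`) because the source description is ambiguous
  on this point.
* The post-exposure window is half-open, `(anchor, anchor + w]`, anchored
  at the later of order and alert time, with `w` defaulting to 1 hour.
  One hour is implausibly short for diLQTS surveillance (it is, however,
  what the source states), so `post_window_h` is an explicit parameter
  rather than a constant.
* Covariates (demographics, location flags, labs) are timed at the
  *earlier* of alert and order; labs must fall within ±24 h or are
  treated as missing, and their signed offset-hours enter the models.
* Mortality windows (3/6/12 months) use calendar-month arithmetic from
  the admission date with end-of-month clamping; the source gives no
  day-count convention, and calendar months are the least surprising
  reading of "within 3 months of the index encounter beginning".

## 3. Compliance and the four recode rules

The in-alert action dichotomizes as comply ("Remove single order") versus
ignore (cancel / acknowledge-override / accept). Downstream compliance is
absence of a signed order within 48 h and absence of administration within
72 h of the alert. Four discrepancy classes are recoded to missing, in a
fixed precedence so every event gets exactly one reason:
order signed > 48 h after the alert; administration > 72 h after the
alert; a signed order with no administration record; an administration
with no signed order. An administration preceding its alert without an
order falls into the last class; with an order it raises a data-integrity
warning. Percentages in the response tables use denominators that exclude
missing in-alert responses (action column) and the recoded classes
(order/administration columns), which is the only reading that makes the
published percentage arithmetic internally consistent.

## 4. Comorbidity clusters

Encounters are one-hot encoded over demographics (four age bins — left
closed, `[18,40) [40,60) [60,80) [80,90]`, since the printed bin labels
overlap at their boundaries — sex, race, ethnicity, location flags) plus
the top-500 diagnoses and top-500 medications, ranked by distinct-encounter
frequency with lexicographic tie-breaks.

Clustering is K-means with Hamming distance (k-modes): Lloyd alternation
between nearest-centroid assignment (ties to the lowest cluster index) and
per-column majority-bit centroids (exact 50% ties resolve to 0 —
deterministic and sparsity-favoring). Majority bits minimize total Hamming
distance for a fixed assignment, so inertia is non-increasing; this is
asserted per iteration in the tests. Empty clusters are reseeded with the
row farthest from its centroid.

Two practical choices matter on sparse one-hot data and are worth stating
plainly:

* **Initialization.** Plain random-row seeding collapses badly (clusters
  of size one, mode centroids degenerating to the all-common-codes row).
  Centroids are therefore seeded k-means++-style on distinct rows —
  distance-squared weighted sampling — with `n_init` restarts keeping the
  best final inertia.
* **Mode thresholds.** A binary-mode centroid retains a feature only if
  it appears in a majority of the cluster; signals carried by features
  below 50% within-cluster prevalence are invisible to k-modes. This is a
  property of the method, not of this implementation.

The cluster count is fixed at 4 for the pipeline; `elbow_scan()` (inertia
over k = 2…30 on a 10,000-row sample of *encounters* — "subjects" is read
as encounters, the clustering unit) is diagnostic, with automated
selection by maximum second difference of the inertia curve.

## 5. Marginal models

All effects are population-averaged: logistic GEE for diLQTS and the
mortality windows, Poisson-log GEE for hospital duration in fractional
days (a quasi-likelihood contract — only the mean model and the robust
variance are used, so non-integer outcomes are fine). The working
correlation is exchangeable within patient, with the Liang–Zeger moment
estimator for α and Pearson-based scale φ; standard errors are sandwich
estimates. Scoring stops when the maximum coefficient change is below
1e-6 (cap 100 iterations); non-convergence and suspected separation are
flagged with warnings, never silently repaired. With one record per
cluster the solution coincides with ML GLM estimation — asserted to 1e-6
in the acceptance suite, and the whole solver is checked against an
independently computed exchangeable-GEE reference on a frozen fixture.

The adjustment set is age (continuous), sex, race, ethnicity, location
flags, comorbidity cluster (reference: largest cluster), pre-exposure
maximum QTc, and potassium/magnesium/creatinine with their timing
offsets (linear hours). Missing labs use the missing-indicator method —
cohort-mean imputation plus a missingness flag plus the offset covariate —
because the source adjusts for lab timing but never states a missing-data
method; indicators keep every event in the model. Reference levels:
no-alert, ignore-action, pre-era, largest medication. Aliased or constant
columns (e.g. a missingness flag that never fires in a subset) are
dropped with a warning. Era analyses exclude alert terms — the exposure is
the medication-specific deployment month (first calendar day of the stated
month) — and their report carries an explicit calendar-time confounding
caveat; no secular-trend adjustment is attempted because the source has
none. Predictive margins are computed by marginal standardization with
delta-method standard errors.

## 6. The synthetic generator: a stated world

`generator_config()` defaults encode the study conditions: baseline QTc
mean 422 / SD 58 ms; 8.4% of patients carrying prior trigger evidence;
8.25% diLQTS prevalence; conditional alert→diLQTS log-odds `log(2.28)`;
length-of-stay rate ratio 1.08 under an alert on a baseline of 5.5 days;
encounters per patient shifted-geometric with mean 1.7 (the simplest
long-tailed law consistent with ~1.73 encounters/patient and a 1–52
range); ages truncated-normal (59.19, 17.94) on [18, 90]; the ten-drug
order mix at the observed per-drug shares; per-drug in-alert action
multinomials with the observed comply spread (sotalol ~10.6% up to
azithromycin ~69.8%); mortality anchors near 3.2/6.9/8.4/10.3% for
inpatient/3m/6m/12m.

Design points:

* **Evidence-driven alerts with exact control.** Alert-eligible patients
  get a planted pre-admission ECG with Bazett QTc ≥ 500; everyone else's
  baseline ECGs are capped below the trigger. `high_qtc_prob = 0`
  therefore yields exactly zero alerts. Alerts exist only after the
  medication's deployment month. One consequence is accepted and
  documented rather than hidden: a *post-exposure* ECG of a diLQTS event
  can itself exceed the Bazett trigger, so re-running the rule over the
  full generated history can flag encounters beyond the planted set; the
  alert log (the observed artifact, as in a real EHR) is the source of
  truth downstream.
* **Outcome-consistent ECG construction.** diLQTS is drawn from a
  logistic model (intercept solved by root-finding against the realized
  linear predictors so the configured prevalence is met to binomial
  noise; medication shifts; a patient-level normal random effect of SD
  0.5 inducing the exchangeable correlation the models assume). The
  post-exposure ECG is then *constructed* so threshold adjudication on
  the raw intervals reproduces the drawn flag exactly — via the ≥ 500
  route or the > 60 rise route — with within-patient encounter spacing
  (≥ 45 days) guaranteeing the generator's running pre-exposure maximum
  equals what the cohort builder recomputes. The tests assert exact
  agreement at 50,000+ events.
* **Known estimands.** The registry records the conditional OR, the
  medication-standardized marginal OR, and the *crude* marginal OR
  implied by the realization (alert status is mildly confounded with
  medication through deployment dates, so crude ≠ standardized; coverage
  and recovery tests target the crude estimand of the unadjusted model).
  With the default random-effect SD, `log(2.28)` conditional corresponds
  to a crude/marginal OR near 2.20–2.23; the adjusted GEE lands between
  the two (≈ 2.27 at 150,000 events).
* **Length of stay** is gamma (shape 1.5) around a log-linear mean.
  Floors/caps (0.35–40 days, and a small floor keeping the index
  timeline inside the stay) are independent of alert status; their
  censoring shifts the realized mean ratio from the configured 1.08 to
  ≈ 1.075, well inside the ±0.03 recovery tolerance. Compliance lags are
  fitted *inside* the drawn stay (an earlier design floored the stay by
  the lag timeline and visibly biased the rate ratio upward — the kind of
  defect the ground-truth registry exists to catch).
* **Discrepancy injection.** The four recode classes are injected at
  configurable rates with deterministic counts and recorded event keys,
  so the cohort builder's recode audit can be compared exactly (modulo
  events the 18–90 age filter removes).
* **Comorbidity codes** are opaque tokens from a power-law background
  plus four archetype signature blocks (30 diagnoses + 30 medications
  each, present with probability 0.6 — "defining comorbidities present in
  most encounters of the phenotype", chosen so binary-mode centroids can
  retain them, see §4). Archetypes drive the latent severity that couples
  location, code burden, length of stay, and mortality.

**What the generator does not emulate** — and hence what a green test does
not establish: real ICD-10 semantics and code co-occurrence structure;
informative ECG surveillance (post-alert patients getting *more* ECGs,
a real adjudication confounder); cross-encounter death consistency
(encounters are outcome-independent given the patient effects, so a
"dead" patient can reappear); seasonal/secular trends in admission or
outcome rates; provider-level clustering of alert responses. Parameter
recovery on this world shows the estimators are correct, not that the
source study's estimates are.

## 7. Numerical conventions

Thresholds: trigger ≥ 500 inclusive; adjudication ≥ 500 inclusive and
rise > 60 strict. Post window half-open right-inclusive. Deployment
boundary: first day of the stated month, inclusive. Recode precedence as
listed in §3. Centroid ties to 0; assignment ties to the lowest index.
GEE convergence 1e-6 on the max coefficient step; α clamped to
[−1/(n_max−1) + 1e-6, 0.99]; exchangeable inverses by the closed
Sherman–Morrison form, so fits are O(N p²) and invariant to row order.
Percentages round only at the reporting layer (`summary_pct()`), with
full precision internally.

## 8. Known limitations

* The published headline estimates derive from restricted data; this
  package reproduces the printed-cell arithmetic exactly and the effect
  *recovery* on synthetic data, nothing stronger.
* k-modes results depend on initialization on real-sized sparse data;
  restarts mitigate but do not remove this — the exhaustive-optimum
  guarantee is asserted only on tiny instances.
* The one-hour post-exposure window (as stated) makes surveillance-driven
  under-ascertainment likely in real data; widen `post_window_h` for
  sensitivity analyses.
* Era contrasts are confounded with calendar time by construction; the
  report says so rather than adjusting for it.
* The published response-table grand total (57.1% action compliance) is
  inconsistent with its own text (60.13% of 14,963 − 21); the text figure
  is treated as authoritative, and one published cluster-percentage cell
  (inpatient mortality, first cluster) prints a percentage inconsistent
  with its own count — its standardized OR, however, reproduces from the
  counts and is tested.
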