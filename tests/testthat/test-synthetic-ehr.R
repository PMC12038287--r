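test_that("generator configuration is validated", {
  expect_error(generator_config(n_patients = 0), "empty bundle")
  expect_error(generator_config(n_patients = -5), "non-negative")
  expect_error(generator_config(encounters_per_patient_dist =
                                  list(name = "zipf")), "invalid")
  expect_error(generator_config(encounters_per_patient_dist =
                                  list(name = "shifted_geometric", mean = 0.5)),
               "mean >= 1")
  expect_error(generator_config(high_qtc_prob = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(med_prevalence = c(aspirin = 1)),
               "culprit")
  expect_error(generator_config(action_policy = list(sotalol = c(0.5, 0.5))),
               "4-way")
})

test_that("generation is deterministic under a fixed seed", {
  ds1 <- small_dataset(n_patients = 100, seed = 3)
  ds2 <- small_dataset(n_patients = 100, seed = 3)
  expect_identical(ds1$bundle, ds2$bundle)
  expect_identical(ds1$ground_truth$truth_events,
                   ds2$ground_truth$truth_events)
  ds3 <- small_dataset(n_patients = 100, seed = 4)
  expect_false(identical(ds1$bundle$ecgs, ds3$bundle$ecgs))
})

test_that("structural invariants hold on generated bundles", {
  ds <- small_dataset(n_patients = 600, seed = 21)
  b <- ds$bundle
  # location nesting: ICU implies telemetry, ICU and stepdown exclusive
  expect_true(all(b$encounters[icu == TRUE, telemetry]))
  expect_false(any(b$encounters$icu & b$encounters$stepdown))
  # referential integrity
  expect_true(all(b$encounters$patient_id %in% b$patients$patient_id))
  expect_true(all(b$ecgs$patient_id %in% b$patients$patient_id))
  expect_true(all(b$orders$encounter_id %in% b$encounters$encounter_id))
  expect_true(all(b$alerts$encounter_id %in% b$encounters$encounter_id))
  expect_true(all(na.omit(b$administrations$order_id) %in% b$orders$order_id))
  # in-stay timestamps stay within the admit-discharge span; only the
  # planted pre-admission ECG history may precede admission
  enc <- b$encounters
  ecg <- merge(b$ecgs, enc, by = "encounter_id")
  expect_true(all(ecg$ts >= ecg$admit_ts & ecg$ts <= ecg$discharge_ts))
  ord <- merge(b$orders, enc, by = "encounter_id")
  expect_true(all(ord$order_ts >= ord$admit_ts &
                    ord$order_ts <= ord$discharge_ts))
  adm <- merge(b$administrations, enc, by = "encounter_id")
  expect_true(all(adm$admin_ts >= adm$admit_ts &
                    adm$admin_ts <= adm$discharge_ts))
  # no administration precedes its signed order (no injected discrepancies)
  aa <- merge(b$administrations, b$orders, by = "order_id")
  expect_true(all(aa$admin_ts >= aa$order_ts))
  # every encounter carries at least one culprit-medication order
  expect_true(all(enc$encounter_id %in% b$orders$encounter_id))
})

test_that("no alerts fire when nobody carries prior trigger evidence", {
  ds <- small_dataset(n_patients = 500, seed = 8, high_qtc_prob = 0)
  expect_equal(nrow(ds$bundle$alerts), 0L)
  # and no generated ECG would trigger the rule before any order
  ecg <- derive_qtc(ds$bundle$ecgs)
  ords <- ds$bundle$orders[, .(first_order = min(order_ts)),
                           by = encounter_id]
  pre <- merge(ecg, ords, by = "encounter_id")
  expect_true(all(pre[ts < first_order, qtc_bazett_ms] < 500))
})

test_that("sample_action draws from the configured policy", {
  cfg <- generator_config(
    action_policy = stats::setNames(rep(list(c(
      "Cancel BPA" = 0, "Acknowledge or Override warning" = 0,
      "Accept BPA (no action taken)" = 0, "Remove single order" = 1)),
      10), culprit_medications()))
  set.seed(1)
  expect_true(all(sample_action("sotalol", 200, cfg) == "Remove single order"))
  expect_error(sample_action("aspirin", 1, cfg), "unknown")

  unif <- generator_config(
    action_policy = stats::setNames(rep(list(stats::setNames(
      rep(0.25, 4), provider_actions())), 10), culprit_medications()))
  set.seed(2)
  draws <- sample_action("ondansetron", 1e5, unif)
  freq <- table(draws) / 1e5
  expect_true(all(abs(freq - 0.25) < 0.01))  # ~7 binomial SEs

  # default sotalol policy complies ~10.6% of the time
  set.seed(3)
  sot <- sample_action("sotalol", 1e5, generator_config())
  expect_lt(abs(mean(sot == "Remove single order") - 0.106), 0.01)
})

test_that("marginal calibration at large n: alert, diLQTS and drug shares", {
  ds <- generate_ehr(generator_config(n_patients = 30000, seed = 2))
  te <- ds$ground_truth$truth_events
  cfg <- ds$ground_truth$config_echo
  n <- nrow(te)
  # diLQTS prevalence: intercept is solved on the realized linear
  # predictors, so only binomial noise remains
  p <- cfg$dilqts_prevalence
  expect_lt(abs(mean(te$dilqts) - p), 3 * sqrt(p * (1 - p) / n))
  # alert prevalence among post-era events equals the eligible-patient share
  post <- te[post_era == TRUE]
  pa <- cfg$high_qtc_prob
  expect_lt(abs(mean(post$alert_fired) - pa),
            3 * sqrt(pa * (1 - pa) / nrow(post)) * 1.5)  # patient clustering
  # per-drug first-slot shares
  first <- te[slot == 1L]
  for (m in names(cfg$med_prevalence)) {
    pm <- cfg$med_prevalence[[m]]
    expect_lt(abs(mean(first$medication == m) - pm),
              3 * sqrt(pm * (1 - pm) / nrow(first)) + 1e-9)
  }
})

test_that("null alert effect yields a crude odds ratio near 1", {
  ds <- generate_ehr(generator_config(n_patients = 30000, seed = 6,
                                      alert_effect_logodds = 0))
  te <- ds$ground_truth$truth_events
  tab <- table(te$alert_fired, te$dilqts)
  or <- (tab[2, 2] / tab[2, 1]) / (tab[1, 2] / tab[1, 1])
  se_log <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or)), 3 * se_log)
  # the crude truth is not exactly 1 under the null: alert status is mildly
  # confounded by medication through the deployment dates
  expect_equal(ds$ground_truth$true_crude_or_alert_dilqts, 1,
               tolerance = 0.01)
})

test_that("bundle round-trips through delimited text", {
  ds <- small_dataset(n_patients = 80, seed = 13,
                      discrepancy_rates = c(order_gt_48h = 0.05))
  dir <- withr::local_tempdir()
  write_bundle(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "patients.csv", "encounters.csv", "ecgs.csv", "orders.csv",
    "administrations.csv", "alerts.csv", "labs.csv", "diagnoses.csv",
    "medications_list.csv", "ground_truth.json", "truth_events.csv")))))
  rb <- read_bundle(dir)
  expect_identical(nrow(rb$ecgs), nrow(ds$bundle$ecgs))
  expect_identical(rb$patients$patient_id, ds$bundle$patients$patient_id)
  expect_equal(rb$ecgs$qt_ms, ds$bundle$ecgs$qt_ms, tolerance = 1e-6)
  # ISO-8601 timestamps survive to second precision
  expect_true(all(abs(as.numeric(rb$encounters$admit_ts) -
                        as.numeric(ds$bundle$encounters$admit_ts)) <= 1))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$true_irr_alert_los,
               ds$ground_truth$true_irr_alert_los, tolerance = 1e-9)
})

test_that("mortality windows are nested in the generated truth", {
  ds <- small_dataset(n_patients = 1500, seed = 17)
  ev <- build_index_events(ds$bundle)
  expect_true(all(!ev$death_3m | ev$death_6m))
  expect_true(all(!ev$death_6m | ev$death_12m))
  # an inpatient death within three months of admission is a 3-month death
  enc <- ds$bundle$encounters[inpatient_death == TRUE]
  short <- enc[as.numeric(death_date - admit_ts, units = "days") < 85]
  evs <- ev[encounter_id %in% short$encounter_id]
  expect_true(all(evs$death_3m))
})
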