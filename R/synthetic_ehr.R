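# Synthetic EHR generator: a schema-complete, fully synthetic inpatient
# cohort with known ground truth, emulating the statistical structure of a
# large QT-prolongation CDS evaluation (repeated encounters per patient,
# a 10-drug culprit-medication mix, ~8% alert prevalence, ~8% diLQTS
# prevalence, nested inpatient locations, and configurable alert->outcome
# effect sizes).

#' Build and validate a generator configuration
#'
#' Defaults encode the stated study world: baseline QTc mean 422 / SD 58 ms,
#' alert-eligible patient share 8.4%, diLQTS prevalence 8.25%, a conditional
#' alert-to-diLQTS odds ratio of 2.28, a length-of-stay rate ratio of 1.08
#' under an alert, encounters per patient following a shifted geometric law
#' with mean 1.7, and ages truncated-normal (59.19, 17.94) on 18-90 years.
#'
#' @param n_patients number of patients to simulate (> 0).
#' @param encounters_per_patient_dist list: either
#'   `list(name = "shifted_geometric", mean = 1.7)` (support 1, 2, ...) or
#'   `list(name = "fixed", value = k)`.
#' @param med_prevalence named probabilities over the 10 culprit medications
#'   for the first order slot; must sum to <= 1 and is normalized internally.
#' @param second_med_prob probability an encounter carries a second, distinct
#'   culprit medication (a second index event).
#' @param baseline_qtc_mean,baseline_qtc_sd patient baseline QTc moments (ms).
#' @param high_qtc_prob probability that a patient enters the system with a
#'   prior ECG of Bazett QTc >= 500 ms (the alert rule's trigger evidence);
#'   with probability 0 no alert ever fires.
#' @param dilqts_prevalence target marginal diLQTS prevalence across index
#'   events; the outcome-model intercept is solved against the realized
#'   linear predictors so the configured value is met up to binomial noise.
#' @param alert_effect_logodds conditional log-odds effect of an alert firing
#'   on diLQTS (given medication and patient random effect).
#' @param per_med_dilqts_logodds named per-medication log-odds shifts for
#'   diLQTS (relative to ondansetron).
#' @param action_policy list medication -> multinomial probabilities over the
#'   four provider actions (see [provider_actions()]).
#' @param action_missing_prob probability an alert's provider action is
#'   missing from the record.
#' @param proceed_prob probability that a provider who did not remove the
#'   order proceeds to a signed order (and administration) after the alert.
#' @param los_rate_days baseline expected hospital length of stay (days).
#' @param los_alert_log_irr multiplicative alert effect on expected length of
#'   stay, on the log scale (log incidence-rate ratio).
#' @param los_shape gamma shape for length-of-stay noise.
#' @param mortality_logodds named list of baseline log-odds for `inpatient`,
#'   `m3`, `m6`, `m12` mortality.
#' @param mortality_alert_logodds additive alert effect on all mortality
#'   log-odds (default 0, the null).
#' @param patient_random_effect_sd SD of the patient-level normal random
#'   effect shared across outcomes (induces exchangeable within-patient
#'   correlation).
#' @param discrepancy_rates named rates (fractions of fired alerts) for the
#'   four injectable order/administration discrepancy classes
#'   `order_gt_48h`, `admin_gt_72h`, `order_no_admin`, `admin_no_order`.
#' @param lab_missing_prob probability each of potassium/magnesium/creatinine
#'   is absent for an encounter.
#' @param date_range first-admission date range (character or Date, length 2).
#' @param seed integer seed; fully determines the generated bundle.
#' @return object of class `qtcds_generator_config`.
#' @export
generator_config <- function(
    n_patients = 1000,
    encounters_per_patient_dist = list(name = "shifted_geometric", mean = 1.7),
    med_prevalence = default_med_prevalence(),
    second_med_prob = 0.02,
    baseline_qtc_mean = 422,
    baseline_qtc_sd = 58,
    high_qtc_prob = 0.084,
    dilqts_prevalence = 0.0825,
    alert_effect_logodds = log(2.28),
    per_med_dilqts_logodds = c(
      ondansetron = 0, haloperidol = 0.25, azithromycin = 0.2,
      levofloxacin = 0.2, escitalopram = 0.4, citalopram = 0.4,
      sotalol = 1.2, droperidol = 0.1, methadone = 0.6,
      hydroxychloroquine = 0.3),
    action_policy = default_action_policy(),
    action_missing_prob = 0.0014,
    proceed_prob = 0.8,
    los_rate_days = 5.5,
    los_alert_log_irr = log(1.08),
    los_shape = 1.5,
    mortality_logodds = list(inpatient = stats::qlogis(0.0323),
                             m3 = stats::qlogis(0.0688),
                             m6 = stats::qlogis(0.0839),
                             m12 = stats::qlogis(0.1031)),
    mortality_alert_logodds = 0,
    patient_random_effect_sd = 0.5,
    discrepancy_rates = c(order_gt_48h = 0, admin_gt_72h = 0,
                          order_no_admin = 0, admin_no_order = 0),
    lab_missing_prob = 0.1,
    date_range = c("2011-07-06", "2024-04-16"),
    seed = 1L) {

  meds <- culprit_medications()
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 0 ||
      n_patients != floor(n_patients))
    stop("n_patients must be a non-negative integer", call. = FALSE)
  if (n_patients == 0)
    stop("n_patients = 0: refusing to generate an empty bundle", call. = FALSE)
  if (!is.list(encounters_per_patient_dist) ||
      is.null(encounters_per_patient_dist$name) ||
      !encounters_per_patient_dist$name %in% c("shifted_geometric", "fixed"))
    stop("invalid encounters_per_patient_dist specification", call. = FALSE)
  if (encounters_per_patient_dist$name == "shifted_geometric" &&
      (is.null(encounters_per_patient_dist$mean) ||
       encounters_per_patient_dist$mean < 1))
    stop("shifted_geometric needs mean >= 1", call. = FALSE)
  if (encounters_per_patient_dist$name == "fixed" &&
      (is.null(encounters_per_patient_dist$value) ||
       encounters_per_patient_dist$value < 1))
    stop("fixed encounter count must be >= 1", call. = FALSE)
  if (!all(names(med_prevalence) %in% meds))
    stop("med_prevalence names must be culprit medications", call. = FALSE)
  if (length(med_prevalence) == 0 || any(med_prevalence < 0) ||
      sum(med_prevalence) > 1 + 1e-8)
    stop("med_prevalence must be non-negative and sum to <= 1", call. = FALSE)
  probs <- c(high_qtc_prob, dilqts_prevalence, second_med_prob,
             action_missing_prob, proceed_prob, lab_missing_prob,
             unlist(discrepancy_rates))
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (baseline_qtc_sd <= 0 || los_rate_days <= 0 || los_shape <= 0)
    stop("scale parameters must be positive", call. = FALSE)
  if (patient_random_effect_sd < 0)
    stop("patient_random_effect_sd must be >= 0", call. = FALSE)
  for (m in names(action_policy)) {
    pa <- action_policy[[m]]
    if (length(pa) != 4 || any(pa < 0) || abs(sum(pa) - 1) > 1e-6)
      stop("action_policy[", m, "] must be a 4-way multinomial", call. = FALSE)
  }
  need <- c("order_gt_48h", "admin_gt_72h", "order_no_admin", "admin_no_order")
  dr <- stats::setNames(rep(0, 4), need)
  dr[names(discrepancy_rates)] <- unlist(discrepancy_rates)

  cfg <- list(
    n_patients = as.integer(n_patients),
    encounters_per_patient_dist = encounters_per_patient_dist,
    med_prevalence = med_prevalence / sum(med_prevalence),
    second_med_prob = second_med_prob,
    baseline_qtc_mean = baseline_qtc_mean,
    baseline_qtc_sd = baseline_qtc_sd,
    high_qtc_prob = high_qtc_prob,
    dilqts_prevalence = dilqts_prevalence,
    alert_effect_logodds = alert_effect_logodds,
    per_med_dilqts_logodds = per_med_dilqts_logodds,
    action_policy = action_policy,
    action_missing_prob = action_missing_prob,
    proceed_prob = proceed_prob,
    los_rate_days = los_rate_days,
    los_alert_log_irr = los_alert_log_irr,
    los_shape = los_shape,
    mortality_logodds = mortality_logodds,
    mortality_alert_logodds = mortality_alert_logodds,
    patient_random_effect_sd = patient_random_effect_sd,
    discrepancy_rates = dr,
    lab_missing_prob = lab_missing_prob,
    date_range = as.Date(date_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "qtcds_generator_config"
  cfg
}

# Truncated normal via inverse CDF (vectorized, deterministic under seed).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw provider actions from a medication's in-alert action policy
#'
#' @param medication one of [culprit_medications()].
#' @param n number of draws.
#' @param config a [generator_config()] (its `action_policy` is used).
#' @return character vector of action labels.
#' @export
sample_action <- function(medication, n = 1, config = generator_config()) {
  if (!is.character(medication) || length(medication) != 1 ||
      !medication %in% culprit_medications())
    stop("unknown culprit medication: ", medication, call. = FALSE)
  pol <- config$action_policy[[medication]]
  if (is.null(pol)) stop("no action policy for ", medication, call. = FALSE)
  sample(names(pol), n, replace = TRUE, prob = pol)
}

#' Generate a synthetic EHR bundle with ground truth
#'
#' Produces the nine flat tables of the cohort schema (patients, encounters,
#' ECGs, orders, administrations, alerts, labs, diagnoses, inpatient
#' medication lists) plus a ground-truth registry of the configured effect
#' sizes. An alert fires at an index order when the CDS was deployed for
#' that medication at the order date and the patient carries planted prior
#' evidence (an ECG with Bazett QTc >= 500 ms, present with probability
#' `high_qtc_prob`); ECGs of non-eligible patients are kept below the
#' trigger threshold so `high_qtc_prob = 0` yields zero alerts. diLQTS is
#' drawn from a logistic model with the configured conditional alert effect
#' and a shared patient random effect, and the post-exposure ECG is then
#' constructed so that threshold adjudication on the raw QT/QRS/RR
#' intervals reproduces the drawn outcome exactly.
#'
#' @param config a [generator_config()].
#' @return list of class `qtcds_dataset` with elements `bundle` (named list
#'   of data.tables) and `ground_truth`.
#' @export
generate_ehr <- function(config) {
  stopifnot(inherits(config, "qtcds_generator_config"))
  set.seed(config$seed)
  HOUR <- 3600; DAY <- 86400
  np <- config$n_patients
  meds <- names(config$med_prevalence)

  ## ---- patients -----------------------------------------------------------
  arch_probs <- c(0.05, 0.26, 0.07, 0.62)   # four comorbidity archetypes
  arch_sev   <- c(-0.5, 0.5, 1.4, -0.3)     # latent severity by archetype
  archetype <- sample.int(4, np, replace = TRUE, prob = arch_probs)
  sev <- stats::rnorm(np, arch_sev[archetype], 0.8)
  b   <- stats::rnorm(np, 0, config$patient_random_effect_sd)
  age0 <- rtruncnorm(np, 59.19, 17.94, 18, 88)
  sex <- sample(c("Female", "Male"), np, replace = TRUE, prob = c(0.526, 0.474))
  race <- sample(c("Caucasian", "Black", "Other race"), np, replace = TRUE,
                 prob = c(0.744, 0.097, 0.159))
  ethnicity <- sample(c("Hispanic", "Non-Hispanic"), np, replace = TRUE,
                      prob = c(0.15, 0.85))
  high_flag <- stats::runif(np) < config$high_qtc_prob
  qtc_base <- rtruncnorm(np, config$baseline_qtc_mean, config$baseline_qtc_sd,
                         330, 560)
  dist <- config$encounters_per_patient_dist
  n_enc <- if (dist$name == "fixed") rep(as.integer(dist$value), np)
           else 1L + stats::rgeom(np, 1 / dist$mean)

  ## ---- encounters ---------------------------------------------------------
  pid <- rep(seq_len(np), n_enc)
  ne <- length(pid)
  t0 <- as.numeric(as.POSIXct(config$date_range[1], tz = "UTC"))
  t1 <- as.numeric(as.POSIXct(config$date_range[2], tz = "UTC"))
  # first admissions skew toward recent years (Beta(4,1)): the pre-CDS era
  # stays a small minority, as in a system whose volume grew over time;
  # repeat stays are spaced >= 45 days apart so stays never overlap
  first_admit_p <- t0 + (t1 - t0) * stats::rbeta(np, 4, 1)
  gaps <- (45 + stats::rexp(ne, 1 / 60)) * DAY
  enc <- data.table::data.table(patient_id = pid, gap = gaps)
  enc[, rank := seq_len(.N), by = patient_id]
  enc[, admit_ts := first_admit_p[patient_id[1]] +
        c(0, cumsum(gap[-.N])), by = patient_id]
  enc[, gap := NULL]
  enc[, encounter_id := seq_len(.N)]
  enc[, `:=`(sev = sev[patient_id], b = b[patient_id],
             qtc_base = qtc_base[patient_id],
             age = pmin(90, age0[patient_id] +
                          (admit_ts - first_admit_p[patient_id]) / (365.25 * DAY)))]
  s <- enc$sev
  icu <- stats::runif(ne) < stats::plogis(-1.85 + 1.30 * s)
  stepdown <- !icu & (stats::runif(ne) < stats::plogis(-1.95 + 0.85 * s))
  telemetry <- icu | (stats::runif(ne) < stats::plogis(-0.85 + 0.60 * s))
  obgyn <- stats::runif(ne) < 0.006
  enc[, `:=`(icu = icu, stepdown = stepdown, telemetry = telemetry,
             obgyn = obgyn)]

  ## ---- index events (one per encounter-medication) ------------------------
  med1 <- sample(meds, ne, replace = TRUE, prob = config$med_prevalence)
  has2 <- stats::runif(ne) < config$second_med_prob
  idx2 <- which(has2)
  med2 <- vapply(idx2, function(i) {
    p <- config$med_prevalence; p[med1[i]] <- 0
    sample(meds, 1, prob = p / sum(p))
  }, character(1))
  ev <- rbind(
    data.table::data.table(encounter_id = enc$encounter_id, slot = 1L,
                           medication = med1),
    data.table::data.table(encounter_id = enc$encounter_id[idx2], slot = 2L,
                           medication = med2))
  ev <- merge(ev, enc, by = "encounter_id", sort = FALSE)
  data.table::setorder(ev, patient_id, admit_ts, slot)
  nev <- nrow(ev)
  ev[, row_id := seq_len(nev)]
  # slot-2 orders trail the encounter's first order by >= 2 h so the 1-hour
  # post-exposure ECG windows of the two index events never overlap
  base_off <- stats::runif(ne, 1, 5)
  ev[, order_offset_h := base_off[match(encounter_id, enc$encounter_id)] +
       (slot - 1L) * stats::runif(.N, 2, 12)]
  ev[, order_ts := admit_ts + order_offset_h * HOUR]

  ## ---- pre-exposure ECGs (per encounter, before the first order) ----------
  e1 <- ev[slot == 1L]
  n_pre <- 1L + stats::rpois(nrow(e1), 1.3)
  pre <- data.table::data.table(
    encounter_id = rep(e1$encounter_id, n_pre),
    patient_id = rep(e1$patient_id, n_pre),
    event_row = rep(e1$row_id, n_pre))
  pre[, ts := rep(e1$admit_ts, n_pre) +
        stats::runif(.N, 0.02, 0.95) * rep(e1$order_offset_h, n_pre) * HOUR]
  qtc_target <- rep(e1$qtc_base, n_pre) + stats::rnorm(nrow(pre), 0, 10)
  rr <- stats::runif(nrow(pre), 0.7, 1.1)
  qrs <- round(stats::runif(nrow(pre), 70, 130))
  qt <- qtc_target * rr^(1 / 3) + pmax(0, qrs - 100)
  # non-eligible patients never show a Bazett >= 500 at baseline: the alert
  # rule's trigger evidence is fully controlled by high_qtc_prob
  qt <- ifelse(high_flag[pre$patient_id], qt, pmin(qt, 495 * sqrt(rr)))
  pre[, `:=`(qt_ms = pmax(qt, 250), qrs_ms = qrs, rr_s = rr)]

  # planted trigger ECG for alert-eligible patients, before their first stay
  hp <- which(high_flag)
  prr <- stats::runif(length(hp), 0.6, 1.0)
  pqrs <- round(stats::runif(length(hp), 80, 120))
  planted <- data.table::data.table(
    encounter_id = NA_integer_, patient_id = hp, event_row = NA_integer_,
    ts = first_admit_p[hp] - stats::runif(length(hp), 10, 60) * DAY,
    qt_ms = (500 + stats::runif(length(hp), 2, 35)) * sqrt(prr),
    qrs_ms = pqrs, rr_s = prr)

  ## ---- alerts (static, evidence-driven eligibility) -----------------------
  deploy <- as.numeric(as.POSIXct(
    as.character(cds_deployment_dates()[ev$medication]), tz = "UTC"))
  ev[, post_era := order_ts >= deploy]
  ev[, alert_fired := post_era & high_flag[patient_id]]

  ## ---- diLQTS: intercept solved so the configured prevalence is met -------
  ev[, med_lo := config$per_med_dilqts_logodds[medication]]
  off <- ev$med_lo + ev$b + config$alert_effect_logodds * ev$alert_fired
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(c0 + off)) - config$dilqts_prevalence,
    lower = -15, upper = 10, tol = 1e-9)$root
  ev[, dilqts := stats::runif(.N) < stats::plogis(intercept + off)]

  ## ---- post-exposure QTc, consistent with threshold adjudication ----------
  # The pre-exposure maximum each event will see downstream (full patient
  # history before the order) is tracked sequentially so the constructed
  # post-exposure maximum reproduces the drawn diLQTS flag exactly under
  # the ">= 500 ms or rise > 60 ms" rule.
  pre[, adjfrid := (qt_ms - pmax(0, qrs_ms - 100)) / rr_s^(1 / 3)]
  planted[, adjfrid := (qt_ms - pmax(0, qrs_ms - 100)) / rr_s^(1 / 3)]
  run_max <- rep(-Inf, np)
  run_max[planted$patient_id] <- planted$adjfrid
  own_pre_max <- rep(-Inf, nev)
  pm <- pre[, .(m = max(adjfrid)), by = event_row]
  own_pre_max[pm$event_row] <- pm$m

  max_pre <- numeric(nev); post_v <- numeric(nev)
  u_route <- stats::runif(nev)
  z_true <- stats::rexp(nev, 1 / 12)
  z_delta <- stats::rexp(nev, 1 / 10)
  z_false <- stats::rnorm(nev, 5, 15)
  for (r in sort(unique(ev$rank))) {
    for (sl in 1:2) {
      idx <- ev[rank == r & slot == sl, row_id]
      if (!length(idx)) next
      p_idx <- ev$patient_id[idx]
      mp <- pmax(run_max[p_idx], own_pre_max[idx])
      max_pre[idx] <- mp
      dl <- ev$dilqts[idx]
      v <- numeric(length(idx))
      if (any(dl)) {
        i1 <- idx[dl]
        delta_route <- u_route[i1] < 0.35 & is.finite(mp[dl])
        v[dl] <- ifelse(delta_route,
                        pmax(500, mp[dl] + 61) + z_delta[i1],
                        500 + z_true[i1])
      }
      if (any(!dl)) {
        i0 <- idx[!dl]
        ub <- pmin(499, ifelse(is.finite(mp[!dl]), mp[!dl] + 60, 499)) - 0.5
        v[!dl] <- pmax(320, pmin(ev$qtc_base[i0] + z_false[i0], ub))
      }
      post_v[idx] <- v
      run_max[p_idx] <- pmax(run_max[p_idx], mp, v)
    }
  }
  ev[, `:=`(max_pre_true = max_pre, post_qtc_true = post_v)]

  post_rr <- stats::runif(nev, 0.7, 1.1)
  post <- data.table::data.table(
    encounter_id = ev$encounter_id, patient_id = ev$patient_id,
    event_row = ev$row_id,
    ts = ev$order_ts + stats::runif(nev, 1, 59) * 60,
    qt_ms = post_v * post_rr^(1 / 3),     # QRS <= 100: no excess subtracted
    qrs_ms = round(stats::runif(nev, 70, 100)), rr_s = post_rr)

  ecgs <- rbind(
    planted[, .(patient_id, encounter_id, ts, qt_ms, qrs_ms, rr_s)],
    pre[, .(patient_id, encounter_id, ts, qt_ms, qrs_ms, rr_s)],
    post[, .(patient_id, encounter_id, ts, qt_ms, qrs_ms, rr_s)])
  data.table::setorder(ecgs, patient_id, ts)
  ecgs[, ecg_id := seq_len(.N)]

  ## ---- provider actions, orders, administrations --------------------------
  ev[, provider_action := NA_character_]
  for (m in meds) {
    ii <- which(ev$alert_fired & ev$medication == m)
    if (length(ii))
      ev$provider_action[ii] <- sample(names(config$action_policy[[m]]),
                                       length(ii), replace = TRUE,
                                       prob = config$action_policy[[m]])
  }
  miss <- ev$alert_fired & stats::runif(nev) < config$action_missing_prob
  ev$provider_action[miss] <- NA_character_
  comply <- ev$alert_fired & !is.na(ev$provider_action) &
    ev$provider_action == "Remove single order"
  proceeds <- ev$alert_fired & !comply & stats::runif(nev) < config$proceed_prob

  ## ---- length of stay (drawn before lags: in-stay timelines must not
  ## censor the configured multiplicative alert effect on expected LOS) ----
  enc_ev0 <- ev[, .(any_alert = any(alert_fired),
                    max_off = max(order_offset_h)), by = encounter_id]
  enc <- merge(enc, enc_ev0, by = "encounter_id", sort = FALSE)
  eta_los <- log(config$los_rate_days) + 0.45 * enc$sev +
    config$los_alert_log_irr * enc$any_alert + 0.25 * enc$b
  los <- stats::rgamma(ne, shape = config$los_shape,
                       rate = config$los_shape / exp(eta_los))
  # a small floor (independent of alert status) keeps the index timeline
  # inside the stay; its censoring effect on the mean is negligible
  los <- pmin(pmax(los, 0.35, (enc$max_off + 1.3) / 24), 40)
  enc[, discharge_ts := admit_ts + los * DAY]
  ev[, discharge_ts := enc$discharge_ts[match(encounter_id,
                                              enc$encounter_id)]]
  ev[, avail_h := pmax((discharge_ts - order_ts) / HOUR - 0.4, 0.5)]

  # discrepancy injection: deterministic counts among proceed/comply pools
  dr <- config$discrepancy_rates
  n_alert <- sum(ev$alert_fired)
  want <- vapply(dr, function(r) as.integer(round(r * n_alert)), integer(1))
  take <- function(pool, n)
    if (n <= 0 || !length(pool)) integer(0) else pool[seq_len(min(n, length(pool)))]
  pool_abc <- which(proceeds)
  inj <- list()
  inj$order_gt_48h <- take(pool_abc, want["order_gt_48h"])
  pool_abc <- setdiff(pool_abc, inj$order_gt_48h)
  inj$admin_gt_72h <- take(pool_abc, want["admin_gt_72h"])
  pool_abc <- setdiff(pool_abc, inj$admin_gt_72h)
  inj$order_no_admin <- take(pool_abc, want["order_no_admin"])
  inj$admin_no_order <- take(which(ev$alert_fired & !proceeds),
                             want["admin_no_order"])

  ev[, `:=`(signed_lag_h = NA_real_, admin_lag_h = NA_real_)]
  pi <- which(proceeds)
  ev$signed_lag_h[pi] <- pmin(stats::rexp(length(pi), 1 / 3.6) + 0.1, 47,
                              ev$avail_h[pi] * 0.6)
  ev$admin_lag_h[pi] <- pmin(ev$signed_lag_h[pi] +
                               stats::rexp(length(pi), 1 / 4) + 0.2, 71,
                             ev$avail_h[pi] * 0.95)
  ev$signed_lag_h[inj$order_gt_48h] <-
    48.5 + stats::rexp(length(inj$order_gt_48h), 1 / 6)
  ev$admin_lag_h[inj$order_gt_48h] <-
    ev$signed_lag_h[inj$order_gt_48h] +
    stats::rexp(length(inj$order_gt_48h), 1 / 4)
  ev$admin_lag_h[inj$admin_gt_72h] <-
    72.5 + stats::rexp(length(inj$admin_gt_72h), 1 / 6)
  ev$admin_lag_h[inj$order_no_admin] <- NA_real_
  ev$admin_lag_h[inj$admin_no_order] <-
    stats::runif(length(inj$admin_no_order), 1, 24)
  na_idx <- which(!ev$alert_fired)
  ev$admin_lag_h[na_idx] <- pmin(stats::rexp(length(na_idx), 1 / 1.5) + 0.2,
                                 ev$avail_h[na_idx] * 0.95)

  # injected long timelines (rare, default off) extend the stay instead of
  # being truncated by it
  inj_rows <- unlist(inj)
  if (length(inj_rows)) {
    need <- ev[inj_rows, .(
      need_ts = max(order_ts + (pmax(data.table::fifelse(is.na(signed_lag_h),
                                                         0, signed_lag_h),
                                     data.table::fifelse(is.na(admin_lag_h),
                                                         0, admin_lag_h)) + 2) *
                      HOUR)), by = encounter_id]
    mi <- match(need$encounter_id, enc$encounter_id)
    enc$discharge_ts[mi] <- pmax(enc$discharge_ts[mi], need$need_ts)
  }

  # orders: the interrupted index order (signed = 0 when alerted), plus the
  # post-alert signed order when the provider proceeded; non-alerted index
  # orders are signed immediately
  has_signed2 <- !is.na(ev$signed_lag_h)
  orders <- rbind(
    data.table::data.table(
      encounter_id = ev$encounter_id, medication = ev$medication,
      order_ts = ev$order_ts, signed = as.integer(!ev$alert_fired)),
    data.table::data.table(
      encounter_id = ev$encounter_id[has_signed2],
      medication = ev$medication[has_signed2],
      order_ts = ev$order_ts[has_signed2] + ev$signed_lag_h[has_signed2] * HOUR,
      signed = 1L))
  data.table::setorder(orders, encounter_id, order_ts)
  orders[, order_id := seq_len(.N)]
  data.table::setcolorder(orders, c("order_id", "encounter_id", "medication",
                                    "order_ts", "signed"))

  has_admin <- !is.na(ev$admin_lag_h)
  admins <- data.table::data.table(
    encounter_id = ev$encounter_id[has_admin],
    medication = ev$medication[has_admin],
    admin_ts = ev$order_ts[has_admin] + ev$admin_lag_h[has_admin] * HOUR)
  signed_orders <- orders[signed == 1,
                          .(order_id, encounter_id, medication)]
  administrations <- merge(admins, signed_orders,
                           by = c("encounter_id", "medication"),
                           all.x = TRUE, sort = FALSE)
  administrations <- administrations[, .(order_id, encounter_id, medication,
                                         admin_ts)]
  data.table::setorder(administrations, encounter_id, admin_ts)

  alerts <- ev[alert_fired == TRUE,
               .(encounter_id, medication, alert_ts = order_ts,
                 provider_action)]
  alerts[, alert_id := seq_len(.N)]
  data.table::setcolorder(alerts, c("alert_id", "encounter_id", "medication",
                                    "alert_ts", "provider_action"))

  ## ---- mortality ----------------------------------------------------------
  ml <- config$mortality_logodds
  lin_m <- 1.15 * enc$sev + 0.3 * enc$b +
    config$mortality_alert_logodds * enc$any_alert
  # -0.8 recenters the linear predictor for the severity mixture so the
  # configured baseline log-odds land near the intended marginal rates
  p_inp <- stats::plogis(ml$inpatient - 0.8 + lin_m)
  p3  <- stats::plogis(ml$m3  - 0.8 + lin_m)
  p6  <- pmax(stats::plogis(ml$m6  - 0.8 + lin_m), p3)
  p12 <- pmax(stats::plogis(ml$m12 - 0.8 + lin_m), p6)
  u <- stats::runif(ne)
  inpatient_death <- stats::runif(ne) < p_inp
  death_date <- rep(NA_real_, ne)
  death_date[inpatient_death] <- enc$discharge_ts[inpatient_death]
  out_death <- !inpatient_death & u < p12
  horizon <- data.table::fifelse(u < p3, 85, data.table::fifelse(u < p6, 175, 355))
  dd <- pmax(enc$admit_ts + stats::runif(ne, 0.35, 0.98) * horizon * DAY,
             enc$discharge_ts + DAY)
  death_date[out_death] <- dd[out_death]
  enc[, `:=`(inpatient_death = inpatient_death, death_date = death_date)]

  ## ---- labs ---------------------------------------------------------------
  anchor <- ev[slot == 1L, .(encounter_id, order_ts, sev)]
  lab_one <- function(analyte, mu, sdv, lognorm = FALSE) {
    a <- anchor[stats::runif(nrow(anchor)) >= config$lab_missing_prob]
    val <- if (lognorm) exp(stats::rnorm(nrow(a), mu + 0.3 * a$sev, sdv))
           else stats::rnorm(nrow(a), mu, sdv)
    data.table::data.table(
      encounter_id = a$encounter_id, analyte = analyte,
      value = round(val, 2),
      ts = a$order_ts + stats::runif(nrow(a), -23, 23) * HOUR)
  }
  labs <- rbind(lab_one("potassium", 4.0, 0.5),
                lab_one("magnesium", 2.0, 0.3),
                lab_one("creatinine", log(0.95), 0.35, lognorm = TRUE))
  data.table::setorder(labs, encounter_id, analyte)

  ## ---- diagnoses and inpatient medication lists ---------------------------
  code_tables <- generate_code_tables(enc, archetype)
  to_ts <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")

  ## ---- assemble -----------------------------------------------------------
  patients <- data.table::data.table(
    patient_id = seq_len(np),
    birth_year = as.integer(format(to_ts(first_admit_p), "%Y")) -
      as.integer(round(age0)),
    sex = sex, race = race, ethnicity = ethnicity)

  data.table::setorder(enc, encounter_id)
  encounters <- enc[, .(encounter_id, patient_id, admit_ts = to_ts(admit_ts),
                        discharge_ts = to_ts(discharge_ts),
                        icu, telemetry, stepdown, obgyn,
                        inpatient_death, death_date = to_ts(death_date))]

  bundle <- list(
    patients = patients,
    encounters = encounters,
    ecgs = ecgs[, .(ecg_id, patient_id, encounter_id, ts = to_ts(ts),
                    qt_ms, qrs_ms, rr_s)],
    orders = orders[, .(order_id, encounter_id, medication,
                        order_ts = to_ts(order_ts), signed)],
    administrations = administrations[, .(order_id, encounter_id, medication,
                                          admin_ts = to_ts(admin_ts))],
    alerts = alerts[, .(alert_id, encounter_id, medication,
                        alert_ts = to_ts(alert_ts), provider_action)],
    labs = labs[, .(encounter_id, analyte, value, ts = to_ts(ts))],
    diagnoses = code_tables$diagnoses,
    medications_list = code_tables$medications_list)

  gt <- list(
    config_echo = config,
    dilqts_intercept = intercept,
    true_conditional_or_alert_dilqts = exp(config$alert_effect_logodds),
    true_marginal_or_alert_dilqts = marginal_or_alert(
      intercept, ev$med_lo, config$alert_effect_logodds,
      config$patient_random_effect_sd),
    true_crude_or_alert_dilqts = crude_or_alert(
      intercept, ev$med_lo, ev$alert_fired, config$alert_effect_logodds,
      config$patient_random_effect_sd),
    true_irr_alert_los = exp(config$los_alert_log_irr),
    per_medication_dilqts_logodds = config$per_med_dilqts_logodds,
    injected_discrepancies = vapply(inj, length, integer(1)),
    injected_events = data.table::rbindlist(lapply(names(inj), function(r)
      if (length(inj[[r]])) data.table::data.table(
        encounter_id = ev$encounter_id[inj[[r]]],
        medication = ev$medication[inj[[r]]], reason = r)
      else NULL)),
    n_patients = np, n_encounters = ne, n_index_events = nev,
    truth_events = ev[, .(encounter_id, medication, slot, alert_fired,
                          dilqts, post_era, max_pre_true, post_qtc_true)],
    patient_archetype = archetype,
    seed = config$seed)
  structure(list(bundle = bundle, ground_truth = gt),
            class = "qtcds_dataset")
}

# Crude (unadjusted) population-averaged alert odds ratio: the estimand of
# an intercept+alert marginal logistic model on this realization. Differs
# from the standardized marginal OR because the medication mix among
# alerted events is shifted by the medication-specific deployment dates.
crude_or_alert <- function(intercept, med_lo_events, alert, beta, re_sd) {
  if (!any(alert) || all(alert)) return(NA_real_)
  group_p <- function(lo_vec, shift) {
    tab <- table(lo_vec) / length(lo_vec)
    lo <- as.numeric(names(tab))
    p <- vapply(lo, function(m) {
      if (re_sd == 0) return(stats::plogis(intercept + m + shift))
      stats::integrate(function(z)
        stats::plogis(intercept + m + shift + re_sd * z) * stats::dnorm(z),
        -8, 8)$value
    }, numeric(1))
    sum(p * as.numeric(tab))
  }
  p1 <- group_p(med_lo_events[alert], beta)
  p0 <- group_p(med_lo_events[!alert], 0)
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

# Population-averaged alert odds ratio implied by the conditional model:
# integrates the patient random effect and the realized medication mixture
# out of the conditional logistic model.
marginal_or_alert <- function(intercept, med_lo_events, beta, re_sd) {
  mean_p <- function(shift) {
    med_tab <- table(med_lo_events) / length(med_lo_events)
    lo <- as.numeric(names(med_tab))
    p <- vapply(lo, function(m) {
      if (re_sd == 0) return(stats::plogis(intercept + m + shift))
      stats::integrate(function(z)
        stats::plogis(intercept + m + shift + re_sd * z) * stats::dnorm(z),
        -8, 8)$value
    }, numeric(1))
    sum(p * as.numeric(med_tab))
  }
  p1 <- mean_p(beta); p0 <- mean_p(0)
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

# Archetype-structured diagnosis and medication-list code tables. Codes are
# opaque tokens ("D###"/"M###") drawn from a power-law background plus an
# archetype-specific signature block, so comorbidity clustering on one-hot
# codes has recoverable structure.
generate_code_tables <- function(enc, archetype) {
  ne <- nrow(enc)
  arch <- archetype[enc$patient_id]
  n_tok <- 400L
  base_w <- seq_len(n_tok)^-0.9
  base_w <- base_w / sum(base_w)
  sig_idx <- lapply(1:4, function(a) ((a - 1) * 30 + 51):((a - 1) * 30 + 80))
  draw <- function(prefix, lam, sig_prob) {
    n_codes <- 2L + stats::rpois(ne, lam + 0.8 * pmax(enc$sev, 0))
    out <- vector("list", 8)
    for (a in 1:4) {
      rows <- which(arch == a)
      if (!length(rows)) next
      # power-law background ...
      toks <- sample.int(n_tok, sum(n_codes[rows]), replace = TRUE,
                         prob = base_w)
      out[[a]] <- data.table::data.table(
        encounter_id = rep(enc$encounter_id[rows], n_codes[rows]),
        code = sprintf("%s%03d", prefix, toks))
      # ... plus the archetype's signature block, each token present
      # independently with probability sig_prob
      hit <- matrix(stats::runif(length(rows) * 30) < sig_prob,
                    length(rows), 30)
      hi <- which(hit, arr.ind = TRUE)
      if (nrow(hi))
        out[[4 + a]] <- data.table::data.table(
          encounter_id = enc$encounter_id[rows][hi[, 1]],
          code = sprintf("%s%03d", prefix, sig_idx[[a]][hi[, 2]]))
    }
    unique(data.table::rbindlist(out))
  }
  # signature codes behave like defining comorbidities of a phenotype:
  # present in a clear majority of the archetype's encounters, so that
  # binary-mode centroids can retain them
  dx <- draw("D", 6, 0.6)
  md <- draw("M", 8, 0.6)
  to_ts <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
  diagnoses <- dx[, .(encounter_id, icd_code = code,
                      recorded_ts = to_ts(enc$admit_ts[match(encounter_id, enc$encounter_id)]))]
  medications_list <- md[, .(
    encounter_id, med_name = code,
    ordered_ts = to_ts(enc$admit_ts[match(encounter_id, enc$encounter_id)] +
                         stats::runif(.N, 0, 0.9) * 3600))]
  data.table::setorder(diagnoses, encounter_id, icd_code)
  data.table::setorder(medications_list, encounter_id, med_name)
  list(diagnoses = diagnoses, medications_list = medications_list)
}

#' Write a dataset bundle to delimited text
#'
#' One CSV per table (header row, ISO-8601 UTC timestamps), plus the ground
#' truth as `ground_truth.json` (the configured effect registry; the
#' event-level truth table is written as `truth_events.csv`).
#'
#' @param dataset a `qtcds_dataset` from [generate_ehr()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "qtcds_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  iso <- function(d) {
    d <- data.table::copy(d)
    for (cn in names(d))
      if (inherits(d[[cn]], "POSIXct"))
        data.table::set(d, j = cn,
                        value = format(d[[cn]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    d
  }
  for (nm in names(dataset$bundle))
    data.table::fwrite(iso(dataset$bundle[[nm]]),
                       file.path(dir, paste0(nm, ".csv")))
  gt <- dataset$ground_truth
  data.table::fwrite(gt$truth_events, file.path(dir, "truth_events.csv"))
  gt$truth_events <- NULL
  gt$config_echo <- unclass(gt$config_echo)
  gt$config_echo$date_range <- as.character(gt$config_echo$date_range)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset bundle written by [write_bundle()]
#'
#' @param dir directory containing the CSV tables.
#' @return named list of data.tables (timestamps parsed back to POSIXct).
#' @export
read_bundle <- function(dir) {
  tabs <- c("patients", "encounters", "ecgs", "orders", "administrations",
            "alerts", "labs", "diagnoses", "medications_list")
  out <- lapply(tabs, function(nm) {
    d <- data.table::fread(file.path(dir, paste0(nm, ".csv")))
    for (cn in grep("(_ts$|^ts$|_date$)", names(d), value = TRUE)) {
      if (inherits(d[[cn]], "POSIXct")) {
        data.table::set(d, j = cn, value = as.POSIXct(
          as.numeric(d[[cn]]), origin = "1970-01-01", tz = "UTC"))
      } else {
        data.table::set(d, j = cn, value = as.POSIXct(
          as.character(d[[cn]]), format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
      }
    }
    d
  })
  stats::setNames(out, tabs)
}
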