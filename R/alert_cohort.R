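# CDS alert rule, index-event construction, provider-action grouping,
# order/administration compliance, and the four missingness-recode rules.

#' Apply the CDS firing rule to a prior-ECG history
#'
#' The interruptive alert fires at medication order entry when any prior ECG
#' carries a Bazett QTc of at least 500 ms. Only ECGs strictly before the
#' order time count; an empty history never fires.
#'
#' @param prior_ecgs data.frame with `ts`, `qt_ms`, `rr_s` (a `qrs_ms` column
#'   is ignored: the rule uses Bazett's correction as stored by the carts).
#' @param order_ts time of the medication order.
#' @return logical flag.
#' @export
fire_alert_rule <- function(prior_ecgs, order_ts) {
  if (is.null(prior_ecgs) || nrow(prior_ecgs) == 0) return(FALSE)
  sel <- as.numeric(prior_ecgs$ts) < as.numeric(order_ts)
  if (!any(sel)) return(FALSE)
  any(qtc_bazett(prior_ecgs$qt_ms[sel], prior_ecgs$rr_s[sel]) >= 500)
}

#' Group the in-alert provider action into comply/ignore
#'
#' "Remove single order" is compliance; cancelling the advisory,
#' acknowledging/overriding the warning, and accepting it without action are
#' the ignore group. A missing action stays missing (excluded from
#' action-group analyses).
#'
#' @param provider_action character vector of action labels (or `NA`).
#' @return character vector: `"comply"`, `"ignore"`, or `NA`.
#' @export
classify_action <- function(provider_action) {
  known <- provider_actions()
  bad <- !is.na(provider_action) & !provider_action %in% known
  if (any(bad))
    stop("unknown provider action label(s): ",
         paste(unique(provider_action[bad]), collapse = ", "), call. = FALSE)
  out <- rep(NA_character_, length(provider_action))
  out[provider_action == "Remove single order"] <- "comply"
  out[!is.na(provider_action) &
        provider_action != "Remove single order"] <- "ignore"
  out
}

#' Downstream order/administration compliance with recode rules
#'
#' Order compliance means no signed culprit-medication order within 48 hours
#' of the alert; administration compliance means no administration within 72
#' hours. Four discrepancy classes are recoded to missing, checked in fixed
#' precedence: (a) order signed more than 48 h after the alert, (b)
#' administration more than 72 h after the alert, (c) a signed order with no
#' administration record, (d) an administration with no signed order. When an
#' event is recoded the compliance flags are null.
#'
#' @param alert_ts alert time (vectorized).
#' @param order_signed_ts time of the first signed order at/after the alert,
#'   `NA` if none.
#' @param admin_ts time of the first administration, `NA` if none.
#' @return data.table with `order_complied`, `admin_complied` (logical, `NA`
#'   when recoded) and `recode_missing_reason` (one of `order_gt_48h`,
#'   `admin_gt_72h`, `order_no_admin`, `admin_no_order`, `none`).
#' @export
classify_compliance <- function(alert_ts, order_signed_ts, admin_ts) {
  a <- as.numeric(alert_ts)
  o <- as.numeric(order_signed_ts)
  d <- as.numeric(admin_ts)
  n <- length(a)
  stopifnot(length(o) == n, length(d) == n)
  if (any(!is.na(d) & !is.na(o) & d < a))
    warning("administration precedes its alert despite a signed order: ",
            "possible data-integrity problem", call. = FALSE)
  reason <- rep("none", n)
  reason[!is.na(d) & is.na(o)] <- "admin_no_order"              # (d)
  reason[!is.na(o) & is.na(d)] <- "order_no_admin"              # (c)
  reason[!is.na(d) & d - a > 72 * 3600] <- "admin_gt_72h"       # (b)
  reason[!is.na(o) & o - a > 48 * 3600] <- "order_gt_48h"       # (a) wins
  order_complied <- !(!is.na(o) & o - a <= 48 * 3600)
  admin_complied <- !(!is.na(d) & d - a <= 72 * 3600)
  order_complied[reason != "none"] <- NA
  admin_complied[reason != "none"] <- NA
  data.table::data.table(order_complied = order_complied,
                         admin_complied = admin_complied,
                         recode_missing_reason = reason)
}

#' Classify an index order against the medication's CDS deployment date
#'
#' @param medication culprit medication name (vectorized).
#' @param order_ts order time (POSIXct or numeric epoch seconds, UTC).
#' @return `"pre"` or `"post"`; the first day of the deployment month counts
#'   as post.
#' @export
classify_cds_era <- function(medication, order_ts) {
  dd <- cds_deployment_dates()
  bad <- !medication %in% names(dd)
  if (any(bad))
    stop("unknown culprit medication: ",
         paste(unique(medication[bad]), collapse = ", "), call. = FALSE)
  boundary <- as.numeric(as.POSIXct(as.character(dd[medication]), tz = "UTC"))
  ifelse(as.numeric(order_ts) >= boundary, "post", "pre")
}

# Calendar-month offset with end-of-month clamping (e.g. Jan 31 + 1m ->
# Feb 28/29), used for the 3/6/12-month mortality windows.
add_months <- function(ts, months) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  day <- lt$mday
  lt$mday <- 1L
  lt$mon <- lt$mon + months
  lt <- as.POSIXlt(as.POSIXct(lt, tz = "UTC"), tz = "UTC")
  max_day <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[lt$mon + 1L]
  leap <- (lt$year + 1900) %% 4 == 0 &
    ((lt$year + 1900) %% 100 != 0 | (lt$year + 1900) %% 400 == 0)
  max_day[lt$mon == 1L & leap] <- 29
  lt$mday <- pmin(day, max_day)
  as.POSIXct(lt, tz = "UTC")
}

#' Build one index event per (encounter, culprit medication)
#'
#' The analysis unit: each encounter contributes one event per culprit
#' medication, anchored at the first order of that medication. The event
#' carries alert status and provider action (joined from the alert log),
#' action group, downstream order/administration compliance with the four
#' recode rules, pre/post QTc aggregates and diLQTS adjudication,
#' covariates timed at the earlier of alert and order (demographics,
#' location flags, labs within 24 h), CDS era, and outcomes (hospital
#' duration, inpatient and 3/6/12-month mortality from the death date by
#' calendar-month arithmetic). Patients outside 18-90 years at the anchor
#' are excluded and counted in the attrition attribute.
#'
#' @param bundle named list of tables as produced by [generate_ehr()] (the
#'   `bundle` element) or [read_bundle()].
#' @param post_window_h post-exposure ECG window in hours (default 1).
#' @param pre_scope `"history"` (all prior ECGs of the patient, the default)
#'   or `"encounter"` (prior ECGs of the index encounter only).
#' @return data.table of index events, one row per (encounter, medication),
#'   with an `attrition` attribute listing exclusion counts.
#' @export
build_index_events <- function(bundle, post_window_h = 1,
                               pre_scope = c("history", "encounter")) {
  pre_scope <- match.arg(pre_scope)
  orders <- data.table::as.data.table(bundle$orders)
  enc <- data.table::as.data.table(bundle$encounters)
  pats <- data.table::as.data.table(bundle$patients)
  ecgs <- data.table::as.data.table(bundle$ecgs)
  alerts <- data.table::as.data.table(bundle$alerts)
  admins <- data.table::as.data.table(bundle$administrations)
  labs <- data.table::as.data.table(bundle$labs)

  orders <- orders[medication %in% culprit_medications()]
  n_enc_no_order <- nrow(enc) - data.table::uniqueN(orders$encounter_id)

  # index anchor: first order (signed or not) per (encounter, medication)
  ev <- orders[, .(order_ts = min(order_ts)), by = .(encounter_id, medication)]
  ev <- merge(ev, enc, by = "encounter_id")
  ev <- merge(ev, pats, by = "patient_id")

  # first alert per (encounter, medication)
  first_alert <- alerts[, .(alert_ts = min(alert_ts),
                            provider_action = provider_action[which.min(alert_ts)]),
                        by = .(encounter_id, medication)]
  ev <- merge(ev, first_alert, by = c("encounter_id", "medication"),
              all.x = TRUE)
  ev[, alert_fired := !is.na(alert_ts)]
  ev[, anchor_cov := pmin(as.numeric(order_ts), as.numeric(alert_ts),
                          na.rm = TRUE)]

  # age at the covariate anchor (mid-year birth date convention)
  birth <- as.numeric(as.POSIXct(paste0(ev$birth_year, "-07-01"), tz = "UTC"))
  ev[, age_years := (anchor_cov - birth) / (365.25 * 86400)]
  n_age_excl <- sum(ev$age_years < 18 | ev$age_years > 90)
  ev <- ev[age_years >= 18 & age_years <= 90]

  # QTc aggregates: pre (before order), post ((anchor, anchor + window])
  ecgs <- derive_qtc(ecgs)
  ecgs[, ts_num := as.numeric(ts)]
  ev[, `:=`(order_num = as.numeric(order_ts),
            anchor_post = pmax(as.numeric(order_ts), as.numeric(alert_ts),
                               na.rm = TRUE),
            event_id = .I)]
  pre_join <- if (pre_scope == "history") {
    ecgs[ev, on = .(patient_id, ts_num < order_num), allow.cartesian = TRUE,
         .(event_id = i.event_id, qtc = x.qtc_adjfrid_ms)]
  } else {
    ecgs[ev, on = .(encounter_id, ts_num < order_num), allow.cartesian = TRUE,
         .(event_id = i.event_id, qtc = x.qtc_adjfrid_ms)]
  }
  pre_agg <- pre_join[!is.na(qtc),
                      .(max_pre_qt = max(qtc), mean_pre_qt = mean(qtc),
                        n_pre = .N), by = event_id]
  ev[, win_end := anchor_post + post_window_h * 3600]
  post_join <- ecgs[ev, on = .(patient_id, ts_num > anchor_post,
                               ts_num <= win_end), allow.cartesian = TRUE,
                    .(event_id = i.event_id, qtc = x.qtc_adjfrid_ms)]
  post_agg <- post_join[!is.na(qtc),
                        .(max_post_qt = max(qtc), mean_post_qt = mean(qtc),
                          n_post = .N), by = event_id]
  ev <- merge(ev, pre_agg, by = "event_id", all.x = TRUE)
  ev <- merge(ev, post_agg, by = "event_id", all.x = TRUE)
  ev[is.na(n_pre), n_pre := 0L]
  ev[is.na(n_post), n_post := 0L]
  ev[, dilqts := adjudicate_dilqts(max_post_qt, max_pre_qt)]

  # provider action group and downstream compliance (alerted events only)
  ev[, action_group := classify_action(provider_action)]
  signed <- orders[signed == 1]
  ev_al <- ev[alert_fired == TRUE,
              .(event_id, encounter_id, medication,
                alert_num = as.numeric(alert_ts))]
  so <- signed[ev_al, on = .(encounter_id, medication),
               allow.cartesian = TRUE,
               .(event_id = i.event_id, alert_num = i.alert_num,
                 ts = as.numeric(x.order_ts))]
  so <- so[!is.na(ts) & ts >= alert_num,
           .(order_signed_ts = min(ts)), by = event_id]
  ad <- admins[ev_al, on = .(encounter_id, medication),
               allow.cartesian = TRUE,
               .(event_id = i.event_id, ts = as.numeric(x.admin_ts))]
  ad <- ad[!is.na(ts), .(admin_first_ts = min(ts)), by = event_id]
  ev_al <- merge(ev_al, so, by = "event_id", all.x = TRUE)
  ev_al <- merge(ev_al, ad, by = "event_id", all.x = TRUE)
  comp <- classify_compliance(ev_al$alert_num, ev_al$order_signed_ts,
                              ev_al$admin_first_ts)
  ev_al <- cbind(ev_al[, .(event_id)], comp)
  ev <- merge(ev, ev_al, by = "event_id", all.x = TRUE)
  ev[alert_fired == FALSE, recode_missing_reason := NA_character_]

  # covariates: labs closest to the anchor within +/- 24 h
  labs[, ts_num := as.numeric(ts)]
  lj <- labs[ev[, .(event_id, encounter_id, anchor_cov)], on = .(encounter_id),
             allow.cartesian = TRUE,
             .(event_id = i.event_id, analyte = x.analyte, value = x.value,
               offset_h = (x.ts_num - i.anchor_cov) / 3600)]
  lj <- lj[!is.na(value) & abs(offset_h) <= 24]
  lj[, abs_off := abs(offset_h)]
  data.table::setorder(lj, event_id, analyte, abs_off)
  lj <- lj[, .(value = value[1], offset_h = offset_h[1]),
           by = .(event_id, analyte)]
  for (an in c("potassium", "magnesium", "creatinine")) {
    w <- lj[analyte == an]
    ev[, paste0(an) := w$value[match(event_id, w$event_id)]]
    ev[, paste0(an, "_offset_h") := w$offset_h[match(event_id, w$event_id)]]
  }

  # era and outcomes
  ev[, cds_era := classify_cds_era(medication, order_ts)]
  ev[, hospital_duration_days :=
       (as.numeric(discharge_ts) - as.numeric(admit_ts)) / 86400]
  dd_num <- as.numeric(ev$death_date)
  adm <- ev$admit_ts
  ev[, death_3m := !is.na(dd_num) & dd_num <= as.numeric(add_months(adm, 3L))]
  ev[, death_6m := !is.na(dd_num) & dd_num <= as.numeric(add_months(adm, 6L))]
  ev[, death_12m := !is.na(dd_num) & dd_num <= as.numeric(add_months(adm, 12L))]

  out <- ev[, .(
    event_id, encounter_id, patient_id, medication,
    order_ts, alert_fired, alert_ts, provider_action, action_group,
    order_complied, admin_complied, recode_missing_reason,
    max_pre_qt, mean_pre_qt, max_post_qt, mean_post_qt, n_pre, n_post,
    dilqts, age_years, sex, race, ethnicity, icu, telemetry, stepdown, obgyn,
    potassium, potassium_offset_h, magnesium, magnesium_offset_h,
    creatinine, creatinine_offset_h, cds_era,
    hospital_duration_days, inpatient_death, death_3m, death_6m, death_12m)]
  data.table::setorder(out, encounter_id, medication)
  out[, event_id := seq_len(.N)]
  data.table::setattr(out, "attrition",
                      list(encounters_without_culprit_order = n_enc_no_order,
                           events_excluded_age = n_age_excl))
  out[]
}

#' Recode-audit counts per missingness reason
#'
#' @param events index events from [build_index_events()].
#' @return data.table of counts per `recode_missing_reason` among fired
#'   alerts (mirrors the published 441/346/1846/355 accounting).
#' @export
recode_audit <- function(events) {
  ev <- data.table::as.data.table(events)[alert_fired == TRUE]
  reasons <- c("order_gt_48h", "admin_gt_72h", "order_no_admin",
               "admin_no_order", "none")
  cnt <- vapply(reasons, function(r)
    sum(ev$recode_missing_reason == r, na.rm = TRUE), integer(1))
  data.table::data.table(reason = reasons, n = cnt)
}
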