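# Marginal model suite: adjusted logistic GEE for diLQTS and mortality,
# Poisson GEE for hospital duration, with the study's adjustment set,
# interaction variants, and predictive margins.

#' Prepare index events for marginal modeling
#'
#' Applies the missing-indicator method for labs and pre-exposure QTc
#' (value imputed to the cohort mean, a missingness flag, and the lab
#' timing offset — imputed to 0 when absent — as covariates), sets factor
#' reference levels (no-alert, ignore action, pre era, largest medication
#' and largest cluster), and exposes the outcome columns expected by
#' [fit_marginal()].
#'
#' @param events index events, optionally carrying a `cluster` column.
#' @return data.table ready for model fitting.
#' @export
prepare_model_data <- function(events) {
  ev <- data.table::as.data.table(data.table::copy(events))
  impute <- function(v) {
    m <- mean(ev[[v]], na.rm = TRUE)
    if (!is.finite(m)) m <- 0
    ev[, paste0(v, "_missing") := as.integer(is.na(get(v)))]
    ev[, paste0(v, "_imp") := data.table::fifelse(is.na(get(v)), m, get(v))]
  }
  for (v in c("potassium", "magnesium", "creatinine", "max_pre_qt"))
    impute(v)
  for (v in c("potassium_offset_h", "magnesium_offset_h",
              "creatinine_offset_h"))
    ev[, paste0(v, "_imp") := data.table::fifelse(is.na(get(v)), 0, get(v))]
  biggest <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  ev[, medication := stats::relevel(factor(medication),
                                    ref = biggest(medication))]
  ev[, sex := factor(sex)]
  ev[, race := factor(race)]
  ev[, ethnicity := factor(ethnicity)]
  ev[, cds_era := factor(cds_era, levels = c("pre", "post"))]
  if ("cluster" %in% names(ev))
    ev[, cluster := stats::relevel(factor(cluster), ref = biggest(cluster))]
  if ("action_group" %in% names(ev))
    ev[, action_group := factor(action_group,
                                levels = c("ignore", "comply"))]
  ev[, alert_fired := as.integer(alert_fired)]
  ev[]
}

#' Specify a marginal model
#'
#' @param outcome one of `dilqts`, `inpatient_death`, `death_3m`,
#'   `death_6m`, `death_12m` (binomial-logit) or `los_days`
#'   (Poisson-log on fractional hospital days).
#' @param exposure main exposure term: `"alert_fired"`, `"action_group"`,
#'   `"cds_era"`, or `"dilqts"`.
#' @param adjusted include the standard adjustment set (age, sex,
#'   race/ethnicity, location flags, cluster if present, pre-exposure QTc,
#'   labs with timing offsets, medication)?
#' @param interaction optional: `"icu"`, `"telemetry"`, or `"medication"` —
#'   interacts the exposure with that term.
#' @return object of class `qtcds_model_spec`.
#' @export
model_spec <- function(outcome, exposure = "alert_fired", adjusted = TRUE,
                       interaction = NULL) {
  outcomes <- c(dilqts = "binomial", inpatient_death = "binomial",
                death_3m = "binomial", death_6m = "binomial",
                death_12m = "binomial", los_days = "poisson")
  if (!outcome %in% names(outcomes))
    stop("unknown outcome: ", outcome, call. = FALSE)
  if (!is.null(interaction) &&
      !interaction %in% c("icu", "telemetry", "medication"))
    stop("unsupported interaction: ", interaction, call. = FALSE)
  structure(list(outcome = outcome, family = unname(outcomes[outcome]),
                 exposure = exposure, adjusted = adjusted,
                 interaction = interaction),
            class = "qtcds_model_spec")
}

model_formula <- function(spec, data) {
  lhs <- if (spec$outcome == "los_days") "hospital_duration_days"
         else spec$outcome
  rhs <- spec$exposure
  if (spec$adjusted) {
    adj <- c("age_years", "sex", "race", "ethnicity",
             "icu", "telemetry", "stepdown", "obgyn",
             if ("cluster" %in% names(data)) "cluster",
             "max_pre_qt_imp", "max_pre_qt_missing",
             "potassium_imp", "potassium_missing", "potassium_offset_h_imp",
             "magnesium_imp", "magnesium_missing", "magnesium_offset_h_imp",
             "creatinine_imp", "creatinine_missing",
             "creatinine_offset_h_imp",
             "medication")
    adj <- setdiff(adj, spec$exposure)
    # avoid using the exposure's own outcome as an adjustment covariate
    if (spec$outcome == "dilqts") adj <- setdiff(adj, "dilqts")
    # constant covariates (e.g. a missingness flag that never fires, or a
    # location absent from a filtered subset) carry no information
    constant <- vapply(adj, function(v)
      v %in% names(data) && length(unique(data[[v]])) < 2, logical(1))
    rhs <- c(rhs, adj[!constant])
  }
  if (!is.null(spec$interaction))
    rhs <- c(rhs, paste0(spec$interaction, ":", spec$exposure))
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

#' Fit a specified marginal model by exchangeable GEE
#'
#' Estimand-specific filtering is applied first: action-group analyses keep
#' fired alerts with a recorded action and drop the recoded-missing
#' discrepancy classes; era analyses drop alert terms (the exposure is the
#' deployment era); diLQTS-as-exposure analyses require an adjudicable
#' diLQTS flag. Rows with a missing outcome are dropped.
#'
#' @param spec a [model_spec()].
#' @param events prepared events (see [prepare_model_data()]; raw index
#'   events are prepared automatically).
#' @param ... passed to [gee_fit()] (e.g. `tol`, `corstr`).
#' @return a `qtcds_gee` fit with the spec attached as `$spec`.
#' @export
fit_marginal <- function(spec, events, ...) {
  stopifnot(inherits(spec, "qtcds_model_spec"))
  ev <- data.table::as.data.table(events)
  if (!"max_pre_qt_imp" %in% names(ev)) ev <- prepare_model_data(ev)
  if (spec$exposure == "action_group")
    ev <- ev[alert_fired == 1 & !is.na(action_group) &
               (is.na(recode_missing_reason) |
                  recode_missing_reason == "none")]
  if (spec$exposure == "dilqts" || spec$outcome == "dilqts")
    ev <- ev[!is.na(dilqts)]
  lhs <- if (spec$outcome == "los_days") "hospital_duration_days"
         else spec$outcome
  ev <- ev[!is.na(ev[[lhs]])]
  ev <- droplevels(ev)
  fit <- gee_fit(model_formula(spec, ev), data = ev, id = "patient_id",
                 family = spec$family, ...)
  fit$spec <- spec
  fit
}

#' Run the marginal analysis suite
#'
#' Executes one of the four model families on the prepared events:
#' `alert` (diLQTS, hospital duration, and the four mortality windows
#' against alert firing, with no-interaction / ICU / telemetry / medication
#' interaction variants for diLQTS), `action` (the same outcomes against
#' the in-alert action group among fired alerts), `era` (outcomes against
#' the medication-specific CDS deployment era, without alert terms), and
#' `dilqts` (hospital duration and mortality against adjudicated diLQTS).
#' Failing fits are captured as failure entries rather than aborting the
#' suite.
#'
#' @param events index events (raw or prepared).
#' @param suite one of `"alert"`, `"action"`, `"era"`, `"dilqts"`.
#' @param outcomes optional subset of outcomes to run.
#' @param ... passed to [gee_fit()].
#' @return list of class `qtcds_suite`: `fits` (named), `table`
#'   (consolidated exposure estimates with CIs), `failures`.
#' @export
run_analysis_suite <- function(events,
                               suite = c("alert", "action", "era", "dilqts"),
                               outcomes = NULL, ...) {
  suite <- match.arg(suite)
  ev <- prepare_model_data(events)
  exposure <- switch(suite, alert = "alert_fired", action = "action_group",
                     era = "cds_era", dilqts = "dilqts")
  outs <- outcomes %||% switch(suite,
    alert = c("dilqts", "los_days", "inpatient_death", "death_3m",
              "death_6m", "death_12m"),
    action = c("dilqts", "los_days", "inpatient_death", "death_12m"),
    era = c("dilqts", "los_days", "inpatient_death", "death_3m",
            "death_6m", "death_12m"),
    dilqts = c("los_days", "inpatient_death", "death_3m", "death_6m",
               "death_12m"))
  variants <- list(none = NULL)
  if (suite == "alert")
    variants <- list(none = NULL, icu = "icu", telemetry = "telemetry",
                     medication = "medication")
  fits <- list(); failures <- list(); rows <- list()
  for (out in outs) {
    for (vn in names(variants)) {
      if (vn != "none" && out != "dilqts") next
      key <- paste(out, vn, sep = ".")
      sp <- model_spec(out, exposure = exposure,
                       interaction = variants[[vn]])
      res <- tryCatch(fit_marginal(sp, ev, ...), error = function(e)
        structure(list(message = conditionMessage(e)), class = "qtcds_fail"))
      if (inherits(res, "qtcds_fail")) { failures[[key]] <- res$message; next }
      fits[[key]] <- res
      en <- grep(paste0("^", exposure), names(res$coefficients), value = TRUE)
      for (trm in en)
        rows[[length(rows) + 1]] <- data.table::data.table(
          suite = suite, outcome = out, variant = vn, term = trm,
          estimate = res$coefficients[[trm]],
          robust_se = res$robust_se[[trm]],
          effect = exp(res$coefficients[[trm]]),
          lower = res$exponentiated[trm, "lower"],
          upper = res$exponentiated[trm, "upper"],
          p = 2 * stats::pnorm(-abs(res$coefficients[[trm]] /
                                      res$robust_se[[trm]])))
    }
  }
  structure(list(fits = fits,
                 table = data.table::rbindlist(rows),
                 failures = failures, suite = suite),
            class = "qtcds_suite")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
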