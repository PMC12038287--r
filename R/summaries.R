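# Descriptive cohort outputs: per-cluster means/percentages with
# population-standardized measures (SMD for continuous, odds ratio for
# categorical), alert-response cross-tabulations, pre/post-CDS counts, and
# chi-square / one-way ANOVA group comparisons.

#' Standardized mean difference against the whole population
#'
#' `(cluster mean - population mean) / population SD`. A zero population SD
#' leaves the measure undefined (`NA` with a warning).
#'
#' @param cluster_mean,pop_mean,pop_sd numeric (vectorized).
#' @return the SMD.
#' @examples
#' smd(62.73, 59.19, 17.94)  # ~0.20
#' @export
smd <- function(cluster_mean, pop_mean, pop_sd) {
  out <- (cluster_mean - pop_mean) / pop_sd
  if (any(pop_sd <= 0, na.rm = TRUE)) {
    warning("non-positive population SD: SMD undefined", call. = FALSE)
    out[pop_sd <= 0] <- NA_real_
  }
  out
}

#' Population-standardized odds ratio from percentages
#'
#' Ratio of the within-cluster odds to the whole-population odds, with odds
#' computed from percentages as `pct / (100 - pct)`. Degenerate percentages
#' (0 or 100) give infinite or zero odds and are flagged with a warning.
#'
#' @param cluster_pct,pop_pct percentages in \[0, 100\] (vectorized).
#' @return the odds ratio.
#' @examples
#' cluster_or(67.36, 19.66)  # ~8.43
#' @export
cluster_or <- function(cluster_pct, pop_pct) {
  if (any(c(cluster_pct, pop_pct) < 0 | c(cluster_pct, pop_pct) > 100,
          na.rm = TRUE))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  if (any(c(cluster_pct, pop_pct) %in% c(0, 100)))
    warning("degenerate percentage (0 or 100): odds are 0 or infinite",
            call. = FALSE)
  (cluster_pct / (100 - cluster_pct)) / (pop_pct / (100 - pop_pct))
}

#' Percentage of a count over a denominator, at reporting precision
#'
#' The single formatting rule used by every summary table: full precision is
#' kept internally and rounding happens only at this reporting layer.
#'
#' @param n numerator count(s); @param d denominator count(s);
#' @param dp decimal places (default 2).
#' @return `round(100 n / d, dp)`; `NA` where the denominator is 0.
#' @export
summary_pct <- function(n, d, dp = 2) {
  out <- round(100 * n / d, dp)
  out[d == 0] <- NA_real_
  out
}

#' Cluster summary table with population-standardized measures
#'
#' Mean (SD) and SMD per cluster for continuous variables; n (%) and
#' population-standardized OR for binary variables, in the layout of a
#' demographics-and-outcomes-by-cluster table.
#'
#' @param events index events carrying a `cluster` column.
#' @param continuous,binary named character vectors of columns to summarize.
#' @return long data.table: variable, cluster, n, mean, sd, pct,
#'   standardized (SMD or OR).
#' @export
cluster_table <- function(events,
                          continuous = c("age_years", "max_pre_qt",
                                         "mean_pre_qt",
                                         "hospital_duration_days"),
                          binary = c("icu", "telemetry", "stepdown", "obgyn",
                                     "dilqts", "alert_fired",
                                     "inpatient_death", "death_3m",
                                     "death_6m", "death_12m")) {
  ev <- data.table::as.data.table(events)
  stopifnot("cluster" %in% names(ev))
  rows <- list()
  for (v in continuous) {
    pm <- mean(ev[[v]], na.rm = TRUE); ps <- stats::sd(ev[[v]], na.rm = TRUE)
    d <- ev[, .(n = sum(!is.na(get(v))), mean = mean(get(v), na.rm = TRUE),
                sd = stats::sd(get(v), na.rm = TRUE)), by = cluster]
    d[, `:=`(variable = v, pct = NA_real_,
             standardized = smd(mean, pm, ps))]
    rows[[length(rows) + 1]] <- d
  }
  for (v in binary) {
    pp <- 100 * mean(ev[[v]], na.rm = TRUE)
    d <- ev[, .(n = sum(get(v), na.rm = TRUE),
                pct = 100 * mean(get(v), na.rm = TRUE)), by = cluster]
    d[, `:=`(variable = v, mean = NA_real_, sd = NA_real_,
             standardized = cluster_or(pct, pp))]
    rows[[length(rows) + 1]] <- d
  }
  out <- data.table::rbindlist(rows, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(out, c("variable", "cluster", "n", "mean", "sd",
                                 "pct", "standardized"))
  data.table::setorder(out, variable, cluster)
  out[]
}

#' Alert-response summary by stratum
#'
#' For each stratum (age bin, sex, race, ethnicity, location flag,
#' medication, cluster if present, and the total): the number of entries,
#' alerts fired (percent of entries), and action / order / administration
#' compliance (percent of fired alerts — action compliance excludes alerts
#' with a missing in-alert response; order and administration compliance
#' exclude the recoded-missing discrepancy classes).
#'
#' @param events index events from [build_index_events()].
#' @return data.table, one row per stratum.
#' @export
response_table <- function(events) {
  ev <- data.table::as.data.table(events)
  ev <- data.table::copy(ev)
  ev[, age_bin := as.character(bin_age(age_years))]
  one <- function(sel, var, level) {
    e <- ev[sel]
    f <- e[alert_fired == TRUE]
    fa <- f[!is.na(action_group)]
    fo <- f[!is.na(order_complied)]
    fd <- f[!is.na(admin_complied)]
    data.table::data.table(
      stratum_var = var, stratum = level, n = nrow(e),
      fired_n = nrow(f), fired_pct = summary_pct(nrow(f), nrow(e), 1),
      action_complied_n = sum(fa$action_group == "comply"),
      action_complied_pct = summary_pct(sum(fa$action_group == "comply"),
                                        nrow(fa), 1),
      order_complied_n = sum(fo$order_complied),
      order_complied_pct = summary_pct(sum(fo$order_complied), nrow(fo), 1),
      admin_complied_n = sum(fd$admin_complied),
      admin_complied_pct = summary_pct(sum(fd$admin_complied), nrow(fd), 1))
  }
  out <- list()
  for (lv in levels(bin_age(18)))
    out[[length(out) + 1]] <- one(ev$age_bin == lv, "age", lv)
  for (lv in sort(unique(ev$sex)))
    out[[length(out) + 1]] <- one(ev$sex == lv, "sex", lv)
  for (lv in sort(unique(ev$race)))
    out[[length(out) + 1]] <- one(ev$race == lv, "race", lv)
  for (lv in sort(unique(ev$ethnicity)))
    out[[length(out) + 1]] <- one(ev$ethnicity == lv, "ethnicity", lv)
  for (lv in c("icu", "telemetry", "obgyn", "stepdown"))
    out[[length(out) + 1]] <- one(ev[[lv]] == TRUE, "location", lv)
  for (lv in sort(unique(ev$medication)))
    out[[length(out) + 1]] <- one(ev$medication == lv, "medication", lv)
  if ("cluster" %in% names(ev))
    for (lv in sort(unique(ev$cluster)))
      out[[length(out) + 1]] <- one(ev$cluster == lv, "cluster",
                                    as.character(lv))
  out[[length(out) + 1]] <- one(rep(TRUE, nrow(ev)), "total", "total")
  data.table::rbindlist(out)
}

#' Pre/post-CDS encounter counts per medication
#'
#' @param events index events with a `cds_era` column.
#' @return data.table: medication, pre_n, pre_pct, post_n, post_pct (row
#'   percentages), plus a total row; totals equal the number of events.
#' @export
era_table <- function(events) {
  ev <- data.table::as.data.table(events)
  d <- ev[, .(pre_n = sum(cds_era == "pre"), post_n = sum(cds_era == "post")),
          by = medication]
  data.table::setorder(d, medication)
  tot <- data.table::data.table(medication = "total",
                                pre_n = sum(d$pre_n), post_n = sum(d$post_n))
  d <- rbind(d, tot)
  d[, `:=`(pre_pct = summary_pct(pre_n, pre_n + post_n),
           post_pct = summary_pct(post_n, pre_n + post_n))]
  d[, .(medication, pre_n, pre_pct, post_n, post_pct)]
}

#' Compare a variable across groups
#'
#' Categorical variables: Pearson chi-square on the contingency table,
#' without continuity correction (multi-level tables); a validity flag is
#' raised when any expected cell is below 1. Continuous variables: one-way
#' ANOVA (classic equal-variance F).
#'
#' @param values numeric (continuous) or character/factor/logical
#'   (categorical) vector.
#' @param groups group labels, same length.
#' @return list with `method`, `statistic`, `df`, `p_value`, and
#'   `low_expected` (chi-square only).
#' @export
compare_groups <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 2) stop("need >= 2 groups", call. = FALSE)
  if (is.numeric(values)) {
    ft <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
    list(method = "anova", statistic = unname(ft$statistic),
         df = unname(ft$parameter), p_value = ft$p.value)
  } else {
    tab <- table(values, groups)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "chi-square", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         low_expected = any(ht$expected < 1))
  }
}
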