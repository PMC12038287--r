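# Shared domain constants: the 10 culprit medications, their CDS deployment
# months, and the four in-alert provider actions.

#' The ten culprit QT-prolonging medications covered by the CDS
#' @return character vector of medication names.
#' @export
culprit_medications <- function() {
  c("ondansetron", "haloperidol", "azithromycin", "levofloxacin",
    "escitalopram", "citalopram", "sotalol", "droperidol", "methadone",
    "hydroxychloroquine")
}

#' Medication-specific CDS deployment dates
#'
#' The interruptive alert went live per medication in a stated month; the
#' boundary is taken as the first calendar day of that month (dates are only
#' known to month granularity).
#'
#' @return named `Date` vector, one entry per culprit medication.
#' @export
cds_deployment_dates <- function() {
  as.Date(c(
    haloperidol        = "2011-11-01",
    sotalol            = "2015-06-01",
    methadone          = "2016-07-01",
    citalopram         = "2016-07-01",
    droperidol         = "2016-07-01",
    ondansetron        = "2016-07-01",
    azithromycin       = "2016-07-01",
    escitalopram       = "2016-07-01",
    levofloxacin       = "2016-09-01",
    hydroxychloroquine = "2020-03-01"
  ))
}

#' The four in-alert provider actions
#'
#' "Remove single order" is the complying action; the other three
#' (cancelling the advisory, acknowledging/overriding the warning, or
#' accepting it without action) constitute the ignore group.
#'
#' @return character vector of the four action labels.
#' @export
provider_actions <- function() {
  c("Cancel BPA", "Acknowledge or Override warning",
    "Accept BPA (no action taken)", "Remove single order")
}

# Default share of index orders per medication (first order slot), shaped on
# the observed per-drug encounter mix of a large inpatient system.
default_med_prevalence <- function() {
  p <- c(
    ondansetron = 107236, haloperidol = 26842, azithromycin = 15428,
    levofloxacin = 9581, droperidol = 6556, escitalopram = 4956,
    citalopram = 3669, methadone = 1577, hydroxychloroquine = 1299,
    sotalol = 953
  )
  p / 178097
}

# Default in-alert action multinomials per medication. The complying share
# per drug follows the observed spread (high for ondansetron/azithromycin,
# very low for sotalol); the ignore mass is split across the three
# non-complying actions in fixed proportions.
default_action_policy <- function() {
  comply <- c(
    ondansetron = 0.694, haloperidol = 0.615, azithromycin = 0.698,
    levofloxacin = 0.606, escitalopram = 0.137, citalopram = 0.163,
    sotalol = 0.106, droperidol = 0.592, methadone = 0.260,
    hydroxychloroquine = 0.181
  )
  ignore_split <- c(0.25, 0.55, 0.20)  # Cancel / Acknowledge / Accept
  pol <- lapply(comply, function(p) {
    c("Cancel BPA" = (1 - p) * ignore_split[1],
      "Acknowledge or Override warning" = (1 - p) * ignore_split[2],
      "Accept BPA (no action taken)" = (1 - p) * ignore_split[3],
      "Remove single order" = p)
  })
  pol
}
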