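#' Heart-rate-corrected QT interval: QRS-adjusted Fridericia
#'
#' Computes the corrected QT interval used for outcome adjudication:
#' the QRS duration in excess of 100 ms is subtracted from the QT interval
#' before applying Fridericia's cube-root rate correction,
#' \deqn{QTc = \frac{QT - \max(0,\; QRS - 100)}{RR^{1/3}}.}
#' Subtracting the QRS excess first is the established wide-complex
#' adjustment: for a narrow QRS (\eqn{\le} 100 ms) the formula reduces to
#' plain Fridericia, and at RR = 1 s the correction is the identity.
#'
#' @param qt_ms QT interval in milliseconds (> 0). Vectorized.
#' @param qrs_ms QRS duration in milliseconds (>= 0). Vectorized.
#' @param rr_s RR interval in seconds (> 0). Vectorized.
#' @return Corrected QT in milliseconds.
#' @examples
#' qtc_adjusted_fridericia(400, 80, 1.0)    # 400: no QRS excess, RR = 1
#' qtc_adjusted_fridericia(480, 120, 0.64)  # 460 / 0.64^(1/3)
#' @seealso [qtc_bazett()] for the square-root correction used by the alert rule.
#' @export
qtc_adjusted_fridericia <- function(qt_ms, qrs_ms, rr_s) {
  stopifnot(is.numeric(qt_ms), is.numeric(qrs_ms), is.numeric(rr_s))
  if (any(qt_ms <= 0, na.rm = TRUE)) stop("qt_ms must be positive")
  if (any(qrs_ms < 0, na.rm = TRUE)) stop("qrs_ms must be non-negative")
  if (any(rr_s <= 0, na.rm = TRUE)) stop("rr_s must be positive")
  (qt_ms - pmax(0, qrs_ms - 100)) / rr_s^(1 / 3)
}

#' Heart-rate-corrected QT interval: Bazett
#'
#' Bazett's square-root correction, \eqn{QTc = QT / \sqrt{RR}}. This is the
#' correction applied by the bedside ECG carts whose stored values drive the
#' alert firing rule (any prior QTc >= 500 ms).
#'
#' @inheritParams qtc_adjusted_fridericia
#' @return Corrected QT in milliseconds.
#' @examples
#' qtc_bazett(400, 0.64)  # 500
#' @export
qtc_bazett <- function(qt_ms, rr_s) {
  stopifnot(is.numeric(qt_ms), is.numeric(rr_s))
  if (any(qt_ms <= 0, na.rm = TRUE)) stop("qt_ms must be positive")
  if (any(rr_s <= 0, na.rm = TRUE)) stop("rr_s must be positive")
  qt_ms / sqrt(rr_s)
}

#' Add derived QTc columns to an ECG table
#'
#' @param ecgs data.frame/data.table with columns `qt_ms`, `qrs_ms`, `rr_s`.
#' @return The table with `qtc_bazett_ms` and `qtc_adjfrid_ms` columns added.
#' @export
derive_qtc <- function(ecgs) {
  ecgs <- data.table::as.data.table(ecgs)
  ecgs[, `:=`(
    qtc_bazett_ms  = qtc_bazett(qt_ms, rr_s),
    qtc_adjfrid_ms = qtc_adjusted_fridericia(qt_ms, qrs_ms, rr_s)
  )]
  ecgs[]
}

#' Pre/post-exposure QTc aggregates for one index event
#'
#' Pre-exposure aggregates are taken over all ECGs strictly before the
#' medication order; post-exposure aggregates over ECGs in the half-open
#' window `(t_anchor, t_anchor + post_window_h]`, where the anchor is the
#' later of the order time and the alert time. An ECG falling exactly at the
#' window's right edge is included. Aggregation uses the QRS-adjusted
#' Fridericia QTc. Empty windows yield `NA` aggregates with a zero count,
#' never an error: missingness is a first-class state that downstream
#' adjudication must handle.
#'
#' @param ecgs data.frame with columns `ts` (numeric or POSIXct), `qt_ms`,
#'   `qrs_ms`, `rr_s`; may be empty.
#' @param order_ts time of the index medication order (pre-window boundary).
#' @param t_anchor post-window anchor (later of order and alert time);
#'   defaults to `order_ts`.
#' @param post_window_h width of the post-exposure window in hours (> 0),
#'   default 1. The default surveillance window is deliberately exposed as a
#'   parameter: one hour is short for diLQTS surveillance and analysts may
#'   want to widen it.
#' @return list with `max_pre_qt`, `mean_pre_qt`, `max_post_qt`,
#'   `mean_post_qt`, `n_pre`, `n_post`.
#' @export
aggregate_qtc <- function(ecgs, order_ts, t_anchor = order_ts, post_window_h = 1) {
  stopifnot(post_window_h > 0)
  ts <- as.numeric(ecgs$ts)
  order_ts <- as.numeric(order_ts)
  t_anchor <- as.numeric(t_anchor)
  qtc <- if (nrow(ecgs) > 0) {
    qtc_adjusted_fridericia(ecgs$qt_ms, ecgs$qrs_ms, ecgs$rr_s)
  } else numeric(0)
  pre  <- qtc[ts < order_ts]
  post <- qtc[ts > t_anchor & ts <= t_anchor + post_window_h * 3600]
  list(
    max_pre_qt   = if (length(pre))  max(pre)   else NA_real_,
    mean_pre_qt  = if (length(pre))  mean(pre)  else NA_real_,
    max_post_qt  = if (length(post)) max(post)  else NA_real_,
    mean_post_qt = if (length(post)) mean(post) else NA_real_,
    n_pre  = length(pre),
    n_post = length(post)
  )
}

#' Adjudicate drug-induced long-QT syndrome (diLQTS)
#'
#' diLQTS is present when the post-exposure maximum QTc reaches 500 ms
#' (inclusive) or rises by more than 60 ms (strict) over the pre-exposure
#' maximum. With no post-exposure ECG the adjudication is missing (`NA`),
#' not `FALSE`. With a missing pre-exposure maximum the delta clause is
#' undefined and evaluates `FALSE`; the 500 ms clause alone decides.
#'
#' @param max_post_qt post-exposure maximum QTc (ms); `NA` if no post ECG.
#' @param max_pre_qt pre-exposure maximum QTc (ms); `NA` if no pre ECG.
#' @return logical (vectorized); `NA` where `max_post_qt` is missing.
#' @examples
#' adjudicate_dilqts(505, 470)  # TRUE  (>= 500)
#' adjudicate_dilqts(470, 400)  # TRUE  (delta 70 > 60)
#' adjudicate_dilqts(499, 439)  # FALSE (delta exactly 60 is not "over 60")
#' @export
adjudicate_dilqts <- function(max_post_qt, max_pre_qt = NA_real_) {
  delta_hit <- !is.na(max_pre_qt) & (max_post_qt - max_pre_qt > 60)
  out <- (max_post_qt >= 500) | delta_hit
  out[is.na(max_post_qt)] <- NA
  out
}
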