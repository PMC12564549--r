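# Incremental cost-effectiveness arithmetic: deltas, ICER with dominance
# classification, net monetary benefit, currency conversion, and the
# Table-1-style two-strategy summary.

#' Incremental cost and effectiveness
#'
#' Intervention minus comparator, exactly.
#'
#' @param c1,e1 Intervention total cost and effectiveness (QALYs).
#' @param c0,e0 Comparator total cost and effectiveness.
#' @return A one-row tibble with `delta_cost`, `delta_effect`.
#' @examples
#' incremental(641680, 9.40, 75273, 4.94)
#' @export
incremental <- function(c1, e1, c0, e0) {
  tibble(delta_cost = c1 - c0, delta_effect = e1 - e0)
}

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' `delta_cost / delta_effect` when the ratio is interpretable
#' (`delta_effect > 0`); `"dominant"` when the intervention is cheaper and
#' more effective, `"dominated"` when costlier and less effective,
#' `"undefined"` when `delta_effect = 0`. In the south-west quadrant
#' (cheaper, less effective) the ratio is still reported, flagged
#' `"ratio_sw"`.
#'
#' @param delta_cost,delta_effect Incremental cost and effectiveness.
#' @return A list of class `icer_result` with elements `value` (USD/QALY or
#'   `NA`) and `status` (`"ratio"`, `"ratio_sw"`, `"dominant"`,
#'   `"dominated"`, `"undefined"`).
#' @examples
#' icer(505854, 4.47)
#' @export
icer <- function(delta_cost, delta_effect) {
  status <- if (delta_effect > 0) {
    if (delta_cost <= 0) "dominant" else "ratio"
  } else if (delta_effect < 0) {
    if (delta_cost >= 0) "dominated" else "ratio_sw"
  } else {
    "undefined"
  }
  value <- if (status %in% c("ratio", "ratio_sw")) {
    delta_cost / delta_effect
  } else {
    NA_real_
  }
  structure(list(value = value, status = status), class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  if (x$status %in% c("ratio", "ratio_sw")) {
    cat(sprintf("ICER: %s per QALY%s\n", format(round(x$value), big.mark = ","),
                if (x$status == "ratio_sw") " (south-west quadrant)" else ""))
  } else {
    cat(sprintf("ICER: %s\n", x$status))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * effect - cost`. The incremental NMB is positive exactly when the
#' ICER lies below the willingness-to-pay threshold (for a QALY gain).
#'
#' @param cost,effect Totals for one strategy.
#' @param wtp Willingness-to-pay threshold (currency per QALY).
#' @export
nmb <- function(cost, effect, wtp) {
  if (any(wtp <= 0)) abort("`wtp` must be positive.")
  wtp * effect - cost
}

#' Convert a local-currency amount to USD
#'
#' @param amount Amount in the local currency.
#' @param usd_per_unit_rate Units of local currency per USD (e.g. 0.74 GBP
#'   per USD).
#' @return `amount / rate`, rounded to whole USD for reporting.
#' @examples
#' convert_currency(88000, 0.74) # GBP 88,000
#' @export
convert_currency <- function(amount, usd_per_unit_rate) {
  if (any(usd_per_unit_rate <= 0)) abort("conversion rate must be positive.")
  round(amount / usd_per_unit_rate)
}

as_totals <- function(x) {
  if (inherits(x, "econ_trace")) {
    list(cost = attr(x, "total_cost"), qaly = attr(x, "total_qaly"),
         name = attr(x, "strategy"))
  } else if (is.list(x) && all(c("cost", "qaly") %in% names(x))) {
    list(cost = x$cost, qaly = x$qaly, name = x$name %||% NA_character_)
  } else {
    abort("expected an `econ_trace` or a list with `cost` and `qaly`.")
  }
}

#' Two-strategy cost-effectiveness summary
#'
#' Builds the base-case results table: per-strategy totals, increments,
#' ICER, and NMB at the willingness-to-pay threshold (comparator row first).
#'
#' @param intervention,comparator `econ_trace` objects (or lists with
#'   `cost`, `qaly`, optionally `name`).
#' @param wtp Willingness-to-pay threshold, USD/QALY (default 102120).
#' @return A tibble of class `cea_result` with columns `strategy`, `cost`,
#'   `incr_cost`, `effectiveness`, `incr_effect`, `icer`, `nmb`; the ICER
#'   dominance status is kept in attribute `icer_status`.
#' @export
cea_summary <- function(intervention, comparator, wtp = 102120) {
  check_number(wtp, "wtp", lower = 1e-9)
  i <- as_totals(intervention)
  c0 <- as_totals(comparator)
  inc <- incremental(i$cost, i$qaly, c0$cost, c0$qaly)
  ic <- icer(inc$delta_cost, inc$delta_effect)
  out <- tibble(
    strategy = c(c0$name %||% "comparator", i$name %||% "intervention"),
    cost = c(c0$cost, i$cost),
    incr_cost = c(NA_real_, inc$delta_cost),
    effectiveness = c(c0$qaly, i$qaly),
    incr_effect = c(NA_real_, inc$delta_effect),
    icer = c(NA_real_, ic$value),
    nmb = nmb(c(c0$cost, i$cost), c(c0$qaly, i$qaly), wtp)
  )
  new_psmcea_tbl(out, "cea_result", wtp = wtp, icer_status = ic$status)
}

#' @exportS3Method generics::glance
glance.cea_result <- function(x, ...) {
  tibble(
    delta_cost = x$incr_cost[2L], delta_effect = x$incr_effect[2L],
    icer = x$icer[2L], icer_status = attr(x, "icer_status"),
    incremental_nmb = x$nmb[2L] - x$nmb[1L], wtp = attr(x, "wtp"),
    cost_effective = if (attr(x, "icer_status") == "dominant") TRUE else
      x$nmb[2L] - x$nmb[1L] > 0
  )
}

#' Round a CEA table for reporting
#'
#' Whole USD for money, two decimals for QALYs.
#'
#' @param x A `cea_result`.
#' @export
format_cea_table <- function(x) {
  mutate(
    as_tibble(x),
    dplyr::across(c("cost", "incr_cost", "icer", "nmb"), round),
    dplyr::across(c("effectiveness", "incr_effect"), \(v) round(v, 2))
  )
}
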