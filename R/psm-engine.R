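# Three-state partitioned survival model (progression-free / progressed /
# dead). State occupancy is read directly off the two survival curves:
# pfs = min(S_PFS, S_OS), pd = S_OS - pfs, dead = 1 - S_OS, so the states
# sum to one by construction and no transition probabilities are needed.

DAYS_PER_MODEL_MONTH <- 30.4375  # 365.25 / 12

#' Model settings
#'
#' @param cycle_length Cycle length in months (default 1).
#' @param horizon Time horizon in months (default 120, i.e. 10 years); must
#'   be a positive multiple of `cycle_length`.
#' @param discount_rate_annual Annual discount rate for costs and QALYs
#'   (default 0.03).
#' @param half_cycle_correction Evaluate occupancy at cycle midpoints
#'   (default `TRUE`) rather than cycle ends; midpoint evaluation reduces
#'   discretization bias.
#' @return A list of class `model_settings`.
#' @export
model_settings <- function(cycle_length = 1, horizon = 120,
                           discount_rate_annual = 0.03,
                           half_cycle_correction = TRUE) {
  check_number(cycle_length, "cycle_length", lower = 1e-6)
  check_number(horizon, "horizon", lower = 1e-6)
  check_number(discount_rate_annual, "discount_rate_annual", 0, 1 - 1e-9)
  n <- horizon / cycle_length
  if (abs(n - round(n)) > 1e-8) {
    abort("`horizon` must be a positive multiple of `cycle_length`.")
  }
  structure(
    list(
      cycle_length = cycle_length, horizon = horizon,
      discount_rate_annual = discount_rate_annual,
      half_cycle_correction = isTRUE(half_cycle_correction),
      n_cycles = as.integer(round(n))
    ),
    class = "model_settings"
  )
}

#' Dosing regimen
#'
#' @param name Regimen label.
#' @param dose_basis `"per_kg"`, `"per_m2"`, or `"flat"`.
#' @param dose_amount mg per kg, per m2, or per administration (flat).
#' @param administrations Day offsets of administrations within the regimen
#'   cycle (e.g. `c(1, 8)` for days 1 and 8).
#' @param regimen_cycle_days Length of the regimen cycle in days.
#' @param route `"IV"` or `"oral"`.
#' @param unit_price Currency per mg.
#' @return A list of class `regimen`.
#' @examples
#' # sacituzumab govitecan: 10 mg/kg IV, days 1 and 8 of a 21-day cycle
#' regimen("SG", "per_kg", 10, c(1, 8), 21, unit_price = 15)
#' @export
regimen <- function(name, dose_basis = c("per_kg", "per_m2", "flat"),
                    dose_amount, administrations, regimen_cycle_days,
                    route = c("IV", "oral"), unit_price) {
  dose_basis <- match.arg(dose_basis)
  route <- match.arg(route)
  check_number(dose_amount, "dose_amount", lower = 1e-12)
  check_number(regimen_cycle_days, "regimen_cycle_days", lower = 1e-6)
  check_number(unit_price, "unit_price", lower = 0)
  administrations <- as.numeric(administrations)
  if (length(administrations) < 1L || any(administrations > regimen_cycle_days)) {
    abort("`administrations` must be day offsets within the regimen cycle.")
  }
  structure(
    list(name = name, dose_basis = dose_basis, dose_amount = dose_amount,
         administrations = administrations,
         regimen_cycle_days = regimen_cycle_days, route = route,
         unit_price = unit_price),
    class = "regimen"
  )
}

#' Patient profile used for dose calculation
#'
#' Defaults reflect a mean Taiwanese female patient: 57.3 kg body weight,
#' 1.72 m2 body surface area.
#'
#' @param body_weight kg.
#' @param bsa Body surface area in m2.
#' @export
patient_profile <- function(body_weight = 57.3, bsa = 1.72) {
  check_number(body_weight, "body_weight", lower = 1e-6)
  check_number(bsa, "bsa", lower = 1e-6)
  structure(list(body_weight = body_weight, bsa = bsa),
            class = "patient_profile")
}

#' Economic inputs for one strategy
#'
#' Costs are per model cycle unless stated otherwise; utilities are QALY
#' weights in \[0, 1\]. Adverse-event (AE) cost and disutility are one-off,
#' applied in cycle 1 weighted by `ae_incidence` (the fraction of the cohort
#' experiencing a grade >= 3 event). When AE burden is nonzero and no
#' incidence is supplied, the whole cohort (1.0) is assumed, with a warning.
#'
#' @param name Strategy label.
#' @param regimen A [regimen()].
#' @param admin_cost_per_cycle Administration cost per model cycle while
#'   progression-free.
#' @param assessment_cost_per_cycle Disease-assessment (e.g. MRI) cost per
#'   model cycle while progression-free.
#' @param ae_cost_one_time One-off cost of treating grade >= 3 adverse
#'   events.
#' @param ae_disutility One-off utility decrement for grade >= 3 adverse
#'   events, applied over cycle 1 (default 0.28).
#' @param ae_incidence Fraction of the cohort incurring the AE burden.
#' @param pd_cost_per_cycle Progressed-disease cost per model cycle
#'   (assessments, palliative/supportive care, amortized hospice).
#' @param u_pfs,u_pd Utility weights for the progression-free and progressed
#'   states.
#' @return A list of class `strategy_inputs`.
#' @export
strategy_inputs <- function(name, regimen, admin_cost_per_cycle = 0,
                            assessment_cost_per_cycle = 0,
                            ae_cost_one_time = 0, ae_disutility = 0.28,
                            ae_incidence = NULL, pd_cost_per_cycle = 0,
                            u_pfs, u_pd) {
  stopifnot(inherits(regimen, "regimen"))
  for (nm in c("admin_cost_per_cycle", "assessment_cost_per_cycle",
               "ae_cost_one_time", "pd_cost_per_cycle")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(u_pfs, "u_pfs", 0, 1)
  check_number(u_pd, "u_pd", 0, 1)
  check_number(ae_disutility, "ae_disutility", 0, 1)
  if (is.null(ae_incidence)) {
    if (ae_cost_one_time > 0 || ae_disutility > 0) {
      warn(sprintf(
        paste0("strategy '%s': no AE incidence supplied; assuming the whole ",
               "cohort (1.0) incurs the grade >= 3 AE cost/disutility."),
        name
      ))
    }
    ae_incidence <- 1
  }
  check_number(ae_incidence, "ae_incidence", 0, 1)
  structure(
    list(name = name, regimen = regimen,
         admin_cost_per_cycle = admin_cost_per_cycle,
         assessment_cost_per_cycle = assessment_cost_per_cycle,
         ae_cost_one_time = ae_cost_one_time, ae_disutility = ae_disutility,
         ae_incidence = ae_incidence, pd_cost_per_cycle = pd_cost_per_cycle,
         u_pfs = u_pfs, u_pd = u_pd),
    class = "strategy_inputs"
  )
}

#' Discount factor
#'
#' @param t Time in months.
#' @param annual_rate Annual discount rate.
#' @return `(1 + annual_rate)^(-t / 12)`.
#' @export
discount_factor <- function(t, annual_rate) {
  (1 + annual_rate)^(-t / 12)
}

# coerce the things occupancy() accepts into a survival function of time
as_surv_fn <- function(x) {
  if (inherits(x, "parametric_fit")) return(function(t) survival_at(x, t))
  if (inherits(x, "km_estimate")) return(function(t) km_survival(x, t))
  if (is.function(x)) return(x)
  abort("expected a `parametric_fit`, `km_estimate`, or function of time.")
}

#' State occupancy of the partitioned survival model
#'
#' Evaluates the two survival curves on the cycle grid (midpoints when
#' half-cycle correction is on, cycle ends otherwise) and partitions the
#' cohort: `pfs = min(S_PFS, S_OS)`, `pd = S_OS - pfs`, `dead = 1 - S_OS`.
#' Clamping `pfs` to `S_OS` handles digitized curves that cross.
#'
#' @param S_pfs,S_os Survival curves: `parametric_fit`, `km_estimate`, or a
#'   function of time in months.
#' @param settings A [model_settings()].
#' @return A tibble of class `occupancy_trace` with columns `cycle`, `time`,
#'   `pfs`, `pd`, `dead`; rows sum to 1 exactly.
#' @export
occupancy <- function(S_pfs, S_os, settings = model_settings()) {
  f_pfs <- as_surv_fn(S_pfs)
  f_os <- as_surv_fn(S_os)
  cyc <- seq_len(settings$n_cycles)
  te <- if (settings$half_cycle_correction) {
    (cyc - 0.5) * settings$cycle_length
  } else {
    cyc * settings$cycle_length
  }
  s_pfs <- pmin(pmax(f_pfs(te), 0), 1)
  s_os <- pmin(pmax(f_os(te), 0), 1)
  pfs <- pmin(s_pfs, s_os)
  new_psmcea_tbl(
    tibble(cycle = cyc, time = te, pfs = pfs, pd = s_os - pfs,
           dead = 1 - s_os),
    "occupancy_trace", settings = settings
  )
}

#' Drug acquisition cost per model cycle
#'
#' mg per administration is `dose_amount` times body weight (per_kg), BSA
#' (per_m2), or 1 (flat); exact milligrams are priced (no vial rounding).
#' The regimen-cycle cost is prorated to the model cycle through
#' `cycle_length_days / regimen_cycle_days`, with 30.4375 days per model
#' month.
#'
#' @param reg A [regimen()].
#' @param patient A [patient_profile()].
#' @param cycle_length Model cycle length in months.
#' @return Currency per model cycle.
#' @export
regimen_cost_per_model_cycle <- function(reg, patient = patient_profile(),
                                         cycle_length = 1) {
  mg <- reg$dose_amount * switch(reg$dose_basis,
    per_kg = patient$body_weight,
    per_m2 = patient$bsa,
    flat = 1,
    abort(sprintf("unknown dose basis '%s'", reg$dose_basis))
  )
  per_regimen_cycle <- mg * reg$unit_price * length(reg$administrations)
  per_regimen_cycle * (cycle_length * DAYS_PER_MODEL_MONTH) / reg$regimen_cycle_days
}

# cost/QALY accrual over a precomputed occupancy trace; split out from
# run_psm() so PSA draws can reuse one trace
accrue_econ <- function(strategy, occ, settings, patient = patient_profile()) {
  drug <- regimen_cost_per_model_cycle(strategy$regimen, patient,
                                       settings$cycle_length)
  df <- discount_factor(occ$time, settings$discount_rate_annual)
  cl_years <- settings$cycle_length / 12
  cost <- (occ$pfs * (drug + strategy$admin_cost_per_cycle +
                        strategy$assessment_cost_per_cycle) +
             occ$pd * strategy$pd_cost_per_cycle) * df
  qaly <- (occ$pfs * strategy$u_pfs + occ$pd * strategy$u_pd) * cl_years * df
  cost[1L] <- cost[1L] + strategy$ae_cost_one_time * strategy$ae_incidence * df[1L]
  qaly[1L] <- qaly[1L] -
    strategy$ae_disutility * strategy$ae_incidence * cl_years * df[1L]
  new_psmcea_tbl(
    tibble(cycle = occ$cycle, time_months = occ$time, pfs = occ$pfs,
           pd = occ$pd, dead = occ$dead, disc_cost = cost, disc_qaly = qaly),
    "econ_trace",
    strategy = strategy$name,
    total_cost = sum(cost), total_qaly = sum(qaly)
  )
}

#' Run the partitioned survival model for one strategy
#'
#' Per cycle: cost = \[pfs x (drug + administration + assessment) +
#' pd x pd_cost\] x discount factor; QALY = \[pfs x u_pfs + pd x u_pd\] x
#' (cycle length / 12) x discount factor. The one-off AE cost and
#' disutility enter in cycle 1, weighted by the AE incidence.
#'
#' @param strategy A [strategy_inputs()].
#' @inheritParams occupancy
#' @param patient A [patient_profile()].
#' @return A tibble of class `econ_trace` with per-cycle discounted cost and
#'   QALY; totals are available via [glance()] or attributes `total_cost`,
#'   `total_qaly`.
#' @export
run_psm <- function(strategy, S_pfs, S_os, settings = model_settings(),
                    patient = patient_profile()) {
  occ <- occupancy(S_pfs, S_os, settings)
  accrue_econ(strategy, occ, settings, patient)
}

#' @exportS3Method generics::glance
glance.econ_trace <- function(x, ...) {
  tibble(strategy = attr(x, "strategy") %||% NA_character_,
         total_cost = attr(x, "total_cost"),
         total_qaly = attr(x, "total_qaly"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.occupancy_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("pfs", "pd", "dead"),
                            names_to = "state", values_to = "proportion")
  df$state <- factor(df$state, levels = c("dead", "pd", "pfs"),
                     labels = c("Dead", "Progressed", "Progression-free"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$proportion,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Months", y = "Proportion of cohort", fill = NULL)
}
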