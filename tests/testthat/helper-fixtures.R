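# Shared fixture builders. Everything is generated in code; no files on
# disk except what a test writes to its own tempdir.

# exponential-as-weibull helper: median m -> scale
exp_scale <- function(median) median / log(2)

# a two-arm trial spec with weibull survival; defaults give clear arm
# separation, moderate administrative censoring, and PFS < OS
make_trial_spec <- function(n = 200, os_medians = c(14, 7),
                            pfs_medians = c(6, 3), shape = 1.2,
                            accrual = 10, followup = 36) {
  wb <- function(med) {
    list(family = "weibull",
         params = c(shape = shape, scale = med / log(2)^(1 / shape)))
  }
  synthetic_trial_spec(
    arms = list(
      SG = list(n = n, os = wb(os_medians[1]), pfs = wb(pfs_medians[1])),
      TPC = list(n = n, os = wb(os_medians[2]), pfs = wb(pfs_medians[2]))
    ),
    accrual_months = accrual, max_followup_months = followup
  )
}

make_regimen_sg <- function(unit_price = 30) {
  regimen("SG", "per_kg", 10, c(1, 8), 21, unit_price = unit_price)
}

make_regimen_tpc <- function(unit_price = 3) {
  # eribulin schedule: 1.4 mg/m2 IV, days 1 and 8 of a 21-day cycle
  regimen("eribulin", "per_m2", 1.4, c(1, 8), 21, unit_price = unit_price)
}

make_strategy <- function(name = "SG", reg = make_regimen_sg(),
                          u_pfs = 0.85, u_pd = 0.52, ae_incidence = 0.6,
                          ...) {
  strategy_inputs(
    name = name, regimen = reg, admin_cost_per_cycle = 150,
    assessment_cost_per_cycle = 250, ae_cost_one_time = 3000,
    ae_disutility = 0.28, ae_incidence = ae_incidence,
    pd_cost_per_cycle = 900, u_pfs = u_pfs, u_pd = u_pd, ...
  )
}

# parametric survival set with wide arm separation, so incremental QALYs
# are sizable and drug cost dominates the tornado when the price is high
make_surv_set <- function() {
  wb <- function(shape, scale) parametric_surv("weibull",
                                               c(shape = shape, scale = scale))
  list(
    intervention = list(pfs = wb(1.2, 9), os = wb(1.2, 26)),
    comparator = list(pfs = wb(1.2, 4), os = wb(1.2, 12))
  )
}

make_inputs <- function(sg_price = 30, wtp = 102120,
                        settings = model_settings()) {
  cea_inputs(
    intervention = make_strategy("SG", make_regimen_sg(sg_price)),
    comparator = make_strategy("TPC", make_regimen_tpc(), u_pfs = 0.58,
                               ae_incidence = 0.4),
    surv = make_surv_set(), settings = settings, wtp = wtp
  )
}

# write a complete curve/risk fixture bundle plus YAML config; returns the
# config path
write_test_config <- function(dir, n = 150, psa_draws = 100, seed = 11) {
  spec <- make_trial_spec(n = n)
  files <- write_fixture_bundle(dir, spec, seed = seed, n_points = 60,
                                jitter_sd = 0.004)
  arm_of <- c(intervention = "SG", comparator = "TPC")
  curves <- lapply(arm_of, function(a) {
    lapply(c(pfs = "pfs", os = "os"), function(ep) {
      list(curve = file.path(dir, sprintf("curve_%s_%s.csv", a, ep)),
           risk = file.path(dir, sprintf("risk_%s_%s.csv", a, ep)))
    })
  })
  cfg <- list(
    settings = list(cycle_length = 1, horizon = 120,
                    discount_rate_annual = 0.03,
                    half_cycle_correction = TRUE),
    patient = list(body_weight = 57.3, bsa = 1.72),
    wtp = 102120,
    curves = curves,
    strategies = list(
      intervention = list(
        name = "SG",
        regimen = list(dose_basis = "per_kg", dose_amount = 10,
                       administrations = c(1, 8), regimen_cycle_days = 21,
                       route = "IV", unit_price = 30),
        admin_cost_per_cycle = 150, assessment_cost_per_cycle = 250,
        ae_cost_one_time = 3000, ae_disutility = 0.28, ae_incidence = 0.6,
        pd_cost_per_cycle = 900, u_pfs = 0.85, u_pd = 0.52
      ),
      comparator = list(
        name = "TPC",
        regimen = list(dose_basis = "per_m2", dose_amount = 1.4,
                       administrations = c(1, 8), regimen_cycle_days = 21,
                       route = "IV", unit_price = 3),
        admin_cost_per_cycle = 150, assessment_cost_per_cycle = 250,
        ae_cost_one_time = 1500, ae_disutility = 0.28, ae_incidence = 0.4,
        pd_cost_per_cycle = 900, u_pfs = 0.58, u_pd = 0.52
      )
    ),
    psa = list(n_draws = psa_draws, seed = seed, cost_sd_frac = 0.25,
               util_sd_frac = 0.10),
    scenarios = list(list(label = "price70", price_multiplier = 0.7),
                     list(label = "price50", price_multiplier = 0.5))
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
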