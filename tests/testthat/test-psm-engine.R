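test_that("discount factors follow the annual-rate formula", {
  expect_equal(discount_factor(0, 0.07), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(120, 0.03), 1.03^-10)
})

test_that("model settings validate the grid", {
  s <- model_settings()
  expect_equal(s$n_cycles, 120L)
  expect_error(model_settings(cycle_length = 1, horizon = 100.5),
               "multiple")
  expect_error(model_settings(discount_rate_annual = -0.1), "discount")
})

test_that("occupancy partitions the cohort from the two curves", {
  s <- model_settings(half_cycle_correction = FALSE)

  # identical curves: nobody is ever in the progressed state
  occ0 <- occupancy(function(t) exp(-0.1 * t), function(t) exp(-0.1 * t), s)
  expect_true(all(occ0$pd == 0))

  # closed forms at t = 10 for exponential curves
  occ <- occupancy(function(t) exp(-0.2 * t), function(t) exp(-0.1 * t), s)
  row <- occ[occ$time == 10, ]
  expect_equal(row$pfs, exp(-2))
  expect_equal(row$pd, exp(-1) - exp(-2))
  expect_equal(row$dead, 1 - exp(-1))

  # crossing curves: pfs clamped to S_OS, pd floored at zero
  occx <- occupancy(function(t) exp(-0.05 * t), function(t) exp(-0.1 * t), s)
  expect_true(all(occx$pd == 0))
  expect_equal(occx$pfs, 1 - occx$dead)
})

test_that("occupancy conserves the cohort at every cycle", {
  surv <- make_surv_set()
  for (hcc in c(TRUE, FALSE)) {
    s <- model_settings(half_cycle_correction = hcc)
    occ <- occupancy(surv$intervention$pfs, surv$intervention$os, s)
    expect_lt(max(abs(occ$pfs + occ$pd + occ$dead - 1)), 1e-12)
    expect_true(all(diff(occ$dead) >= -1e-12))
    expect_true(all(occ$pfs >= 0 & occ$pd >= 0 & occ$dead >= 0))
  }
})

test_that("regimen cost arithmetic follows dose basis and schedule", {
  patient <- patient_profile() # 57.3 kg, 1.72 m2

  # SG: 10 mg/kg x 57.3 kg = 573 mg per administration, days 1 and 8 / 21 d
  sg <- regimen("SG", "per_kg", 10, c(1, 8), 21, unit_price = 1)
  expect_equal(regimen_cost_per_model_cycle(sg, patient),
               573 * 2 * 30.4375 / 21)

  # zero price, zero cost
  free <- regimen("x", "per_kg", 10, c(1, 8), 21, unit_price = 0)
  expect_equal(regimen_cost_per_model_cycle(free, patient), 0)

  # vinorelbine: 25 mg/m2 x 1.72 = 43 mg weekly
  vino <- regimen("vinorelbine", "per_m2", 25, 1, 7, unit_price = 2)
  expect_equal(regimen_cost_per_model_cycle(vino, patient),
               43 * 2 * 30.4375 / 7)

  # longer model cycles scale proportionally
  expect_equal(regimen_cost_per_model_cycle(sg, patient, cycle_length = 3),
               3 * regimen_cost_per_model_cycle(sg, patient))
})

test_that("economic accrual matches hand-computable limits", {
  reg <- make_regimen_sg(0)
  s_exp <- function(l) function(t) exp(-l * t)

  # zero utilities give zero QALYs
  st0 <- strategy_inputs("z", reg, u_pfs = 0, u_pd = 0, ae_disutility = 0,
                         ae_incidence = 0)
  tr0 <- run_psm(st0, s_exp(0.2), s_exp(0.1))
  expect_equal(attr(tr0, "total_qaly"), 0)

  # equal utilities, no discounting: QALYs approach the OS integral / 12
  st1 <- strategy_inputs("u", reg, u_pfs = 1, u_pd = 1, ae_disutility = 0,
                         ae_incidence = 0)
  s0 <- model_settings(discount_rate_annual = 0)
  tr1 <- run_psm(st1, s_exp(0.1), s_exp(0.1), s0)
  analytic <- (1 - exp(-0.1 * 120)) / 0.1 / 12
  expect_lt(abs(attr(tr1, "total_qaly") - analytic) / analytic, 0.02)

  # zero rate equals the undiscounted accumulation exactly
  st2 <- make_strategy()
  surv <- make_surv_set()$intervention
  tr_disc0 <- run_psm(st2, surv$pfs, surv$os,
                      model_settings(discount_rate_annual = 0))
  undisc <- run_psm(st2, surv$pfs, surv$os,
                    model_settings(discount_rate_annual = 0))
  expect_equal(attr(tr_disc0, "total_cost"), attr(undisc, "total_cost"))
})

test_that("discrete accrual agrees with a continuous-time oracle", {
  # numerical integration on a 1000x finer grid, exponential curves,
  # half-cycle correction on
  s <- model_settings()
  lam_pfs <- 0.15; lam_os <- 0.06
  st <- make_strategy(ae_incidence = 0)
  tr <- run_psm(st, function(t) exp(-lam_pfs * t),
                function(t) exp(-lam_os * t), s)
  h <- s$cycle_length / 1000
  tg <- seq(h / 2, s$horizon - h / 2, by = h)
  drug <- regimen_cost_per_model_cycle(st$regimen)
  df <- discount_factor(tg, s$discount_rate_annual)
  pfs <- exp(-lam_pfs * tg); os <- exp(-lam_os * tg)
  cost_cont <- sum((pfs * (drug + st$admin_cost_per_cycle +
                             st$assessment_cost_per_cycle) +
                      (os - pfs) * st$pd_cost_per_cycle) * df) / 1000
  qaly_cont <- sum((pfs * st$u_pfs + (os - pfs) * st$u_pd) * df) / 1000 / 12
  expect_lt(abs(attr(tr, "total_cost") - cost_cont) / cost_cont, 0.01)
  expect_lt(abs(attr(tr, "total_qaly") - qaly_cont) / qaly_cont, 0.01)
})

test_that("AE burden is a one-off in cycle 1 weighted by incidence", {
  surv <- make_surv_set()$intervention
  st_no <- make_strategy(ae_incidence = 0)
  st_half <- make_strategy(ae_incidence = 0.5)
  tr_no <- run_psm(st_no, surv$pfs, surv$os)
  tr_half <- run_psm(st_half, surv$pfs, surv$os)
  s <- model_settings()
  df1 <- discount_factor(0.5 * s$cycle_length, s$discount_rate_annual)
  expect_equal(attr(tr_half, "total_cost") - attr(tr_no, "total_cost"),
               0.5 * st_half$ae_cost_one_time * df1)
  expect_equal(attr(tr_no, "total_qaly") - attr(tr_half, "total_qaly"),
               0.5 * st_half$ae_disutility / 12 * df1)
  # later cycles identical
  expect_equal(tr_no$disc_cost[-1], tr_half$disc_cost[-1])
})

test_that("totals respond monotonically to horizon, discounting, and price", {
  surv <- make_surv_set()$intervention
  st <- make_strategy()
  t60 <- run_psm(st, surv$pfs, surv$os, model_settings(horizon = 60))
  t120 <- run_psm(st, surv$pfs, surv$os, model_settings(horizon = 120))
  expect_gt(attr(t120, "total_cost"), attr(t60, "total_cost"))
  expect_gt(attr(t120, "total_qaly"), attr(t60, "total_qaly"))

  q_rates <- vapply(c(0, 0.03, 0.08), function(r) {
    attr(run_psm(st, surv$pfs, surv$os,
                 model_settings(discount_rate_annual = r)), "total_qaly")
  }, numeric(1))
  expect_true(all(diff(q_rates) < 0))

  # doubling the unit price exactly doubles the drug component only
  st2 <- make_strategy(reg = make_regimen_sg(60))
  tr1 <- run_psm(st, surv$pfs, surv$os)
  tr2 <- run_psm(st2, surv$pfs, surv$os)
  s <- model_settings()
  drug_pv <- sum(occupancy(surv$pfs, surv$os, s)$pfs *
                   regimen_cost_per_model_cycle(make_regimen_sg(30)) *
                   discount_factor(occupancy(surv$pfs, surv$os, s)$time,
                                   s$discount_rate_annual))
  expect_equal(attr(tr2, "total_cost") - attr(tr1, "total_cost"), drug_pv)
  expect_equal(attr(tr2, "total_qaly"), attr(tr1, "total_qaly"))
})

test_that("strategy constructor warns when AE incidence is defaulted", {
  expect_warning(
    strategy_inputs("SG", make_regimen_sg(), ae_cost_one_time = 1000,
                    u_pfs = 0.85, u_pd = 0.52),
    "whole cohort"
  )
  expect_error(
    strategy_inputs("SG", make_regimen_sg(), u_pfs = 1.2, u_pd = 0.5,
                    ae_incidence = 0),
    "u_pfs"
  )
})
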