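# One-way (tornado) sensitivity analysis, probabilistic sensitivity
# analysis with cost-effectiveness acceptability curves, and the
# price-reduction / willingness-to-pay scenario machinery.

#' Bundle everything needed for one cost-effectiveness comparison
#'
#' @param intervention,comparator [strategy_inputs()] objects.
#' @param surv Nested list of survival curves:
#'   `list(intervention = list(pfs =, os =), comparator = list(pfs =, os =))`,
#'   each a `parametric_fit`, `km_estimate`, or function of time.
#' @param settings A [model_settings()].
#' @param patient A [patient_profile()].
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @return A list of class `cea_inputs`.
#' @export
cea_inputs <- function(intervention, comparator, surv,
                       settings = model_settings(),
                       patient = patient_profile(), wtp = 102120) {
  stopifnot(inherits(intervention, "strategy_inputs"),
            inherits(comparator, "strategy_inputs"))
  for (st in c("intervention", "comparator")) {
    if (!all(c("pfs", "os") %in% names(surv[[st]] %||% list()))) {
      abort(sprintf("`surv$%s` must have elements `pfs` and `os`.", st))
    }
  }
  check_number(wtp, "wtp", lower = 1e-9)
  structure(
    list(intervention = intervention, comparator = comparator, surv = surv,
         settings = settings, patient = patient, wtp = wtp),
    class = "cea_inputs"
  )
}

#' Run the base-case comparison
#'
#' @param inputs A [cea_inputs()].
#' @return A `cea_result` (see [cea_summary()]).
#' @export
run_base_case <- function(inputs) {
  tr1 <- run_psm(inputs$intervention, inputs$surv$intervention$pfs,
                 inputs$surv$intervention$os, inputs$settings, inputs$patient)
  tr0 <- run_psm(inputs$comparator, inputs$surv$comparator$pfs,
                 inputs$surv$comparator$os, inputs$settings, inputs$patient)
  cea_summary(tr1, tr0, inputs$wtp)
}

# dotted-path access into the inputs bundle, e.g. "intervention.u_pfs" or
# "comparator.regimen.unit_price"
get_param <- function(inputs, path) {
  purrr::reduce(strsplit(path, ".", fixed = TRUE)[[1L]],
                function(x, k) x[[k]], .init = inputs)
}

set_param <- function(inputs, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  set_rec <- function(x, keys) {
    if (length(keys) == 1L) {
      x[[keys]] <- value
    } else {
      x[[keys[1L]]] <- set_rec(x[[keys[1L]]], keys[-1L])
    }
    x
  }
  set_rec(inputs, keys)
}

default_owsa_parameters <- function(inputs) {
  leafs <- c("regimen.unit_price", "admin_cost_per_cycle",
             "assessment_cost_per_cycle", "ae_cost_one_time",
             "pd_cost_per_cycle", "u_pfs", "u_pd")
  paths <- c(outer(c("intervention.", "comparator."), leafs, paste0))
  paths[vapply(paths, function(p) get_param(inputs, p) > 0, logical(1))]
}

owsa_icer <- function(inputs) {
  g <- glance(run_base_case(inputs))
  g$icer
}

#' One-way sensitivity analysis (tornado)
#'
#' Each parameter is varied alone to `lower` x and `upper` x its base value
#' (0.7/1.3 by default) and the full model is re-run; entries are sorted by
#' the induced ICER range, descending — the tornado ordering.
#'
#' @param inputs A [cea_inputs()].
#' @param parameters Character vector of dotted parameter paths into the
#'   inputs (e.g. `"intervention.regimen.unit_price"`,
#'   `"comparator.u_pfs"`). Default: every nonzero cost and utility of both
#'   strategies.
#' @param lower,upper Multipliers applied to the base value.
#' @return A tibble of class `owsa_result` with columns `parameter`,
#'   `base_value`, `low_value`, `high_value`, `icer_low`, `icer_high`,
#'   `range`.
#' @export
owsa <- function(inputs, parameters = NULL, lower = 0.7, upper = 1.3) {
  parameters <- parameters %||% default_owsa_parameters(inputs)
  base_icer <- owsa_icer(inputs)
  rows <- purrr::map_dfr(parameters, function(p) {
    base <- tryCatch(get_param(inputs, p), error = function(e) NULL)
    if (is.null(base) || !is.numeric(base)) {
      abort(sprintf("parameter '%s' not found in the inputs.", p))
    }
    lo <- base * lower
    hi <- base * upper
    # utilities stay inside [0, 1]
    hi_u <- if (grepl("(^|\\.)(u_pfs|u_pd|ae_disutility)$", p)) min(hi, 1) else hi
    tibble(
      parameter = p, base_value = base, low_value = lo, high_value = hi_u,
      icer_low = owsa_icer(set_param(inputs, p, lo)),
      icer_high = owsa_icer(set_param(inputs, p, hi_u))
    )
  })
  rows$range <- abs(rows$icer_high - rows$icer_low)
  out <- arrange(rows, desc(.data$range))
  new_psmcea_tbl(out, "owsa_result", base_icer = base_icer,
                 lower = lower, upper = upper)
}

# moment-matched gamma draw: mean = base, sd = sd_frac * base
draw_gamma <- function(base, sd_frac) {
  if (base <= 0 || sd_frac == 0) return(base)
  shape <- 1 / sd_frac^2
  rgamma(1L, shape = shape, scale = base * sd_frac^2)
}

# moment-matched beta draw: mean = base, sd = sd_frac * base (shrunk to the
# feasible region if needed)
draw_beta <- function(base, sd_frac, what = "utility") {
  if (sd_frac == 0) return(base)
  if (base <= 0 || base >= 1) {
    if (base == 0 || base == 1) return(base)  # degenerate: keep base
    abort(sprintf("cannot draw beta for %s: mean %g outside (0, 1).",
                  what, base))
  }
  s2 <- (sd_frac * base)^2
  s2max <- base * (1 - base)
  if (s2 >= s2max) s2 <- 0.81 * s2max
  nu <- base * (1 - base) / s2 - 1
  if (nu <= 0) {
    abort(sprintf("infeasible beta moments for %s (mean %g).", what, base))
  }
  rbeta(1L, shape1 = base * nu, shape2 = (1 - base) * nu)
}

sample_strategy <- function(strategy, cost_sd_frac, util_sd_frac) {
  strategy$regimen$unit_price <-
    draw_gamma(strategy$regimen$unit_price, cost_sd_frac)
  for (nm in c("admin_cost_per_cycle", "assessment_cost_per_cycle",
               "ae_cost_one_time", "pd_cost_per_cycle")) {
    strategy[[nm]] <- draw_gamma(strategy[[nm]], cost_sd_frac)
  }
  for (nm in c("u_pfs", "u_pd", "ae_disutility")) {
    strategy[[nm]] <- draw_beta(strategy[[nm]], util_sd_frac, nm)
  }
  strategy
}

#' Draw one probabilistic parameter set
#'
#' Costs are drawn from gamma distributions (mean = base, SD =
#' `cost_sd_frac` x base, moment-matched shape/scale) and utilities from
#' beta distributions (mean = base, SD = `util_sd_frac` x base,
#' moment-matched, SD shrunk into the feasible region when necessary).
#' Draws are independent. An SD fraction of 0 returns the base value.
#'
#' @param inputs A [cea_inputs()].
#' @param cost_sd_frac SD of each cost as a fraction of its mean
#'   (default 0.25).
#' @param util_sd_frac SD of each utility as a fraction of its mean
#'   (default 0.10).
#' @param seed Optional integer; when given, the draw is made under this
#'   seed without disturbing the global RNG state.
#' @return A `cea_inputs` with sampled costs and utilities.
#' @export
sample_parameters <- function(inputs, cost_sd_frac = 0.25,
                              util_sd_frac = 0.10, seed = NULL) {
  draw <- function() {
    inputs$intervention <- sample_strategy(inputs$intervention,
                                           cost_sd_frac, util_sd_frac)
    inputs$comparator <- sample_strategy(inputs$comparator,
                                         cost_sd_frac, util_sd_frac)
    inputs
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Probabilistic sensitivity analysis with acceptability curves
#'
#' For each Monte-Carlo draw, costs and utilities are re-sampled
#' ([sample_parameters()]) and the partitioned survival model is re-run for
#' both strategies; survival curves are held at their point estimates (the
#' sampled distributions cover only costs and utilities), so state
#' occupancy is computed once and reused. The acceptability curve reports,
#' at each willingness-to-pay value, the fraction of draws in which the
#' intervention has positive incremental net monetary benefit.
#'
#' @param inputs A [cea_inputs()].
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed; the full PSA is reproducible under it.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve
#'   (default 0 to 200,000 by 2,000).
#' @inheritParams sample_parameters
#' @return A list of class `psa_result`: `draws` (tibble `draw`, per-
#'   strategy cost/qaly, `dc`, `de`, `nmb_incr`) and `ceac` (tibble `wtp`,
#'   `p_intervention`, `p_comparator`).
#' @export
run_psa <- function(inputs, n_draws = 1000, seed = 1L,
                    wtp_grid = seq(0, 200000, by = 2000),
                    cost_sd_frac = 0.25, util_sd_frac = 0.10) {
  if (n_draws < 1) abort("`n_draws` must be at least 1.")
  occ1 <- occupancy(inputs$surv$intervention$pfs, inputs$surv$intervention$os,
                    inputs$settings)
  occ0 <- occupancy(inputs$surv$comparator$pfs, inputs$surv$comparator$os,
                    inputs$settings)
  draws <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_draws), function(i) {
      smp <- sample_parameters(inputs, cost_sd_frac, util_sd_frac)
      g1 <- glance(accrue_econ(smp$intervention, occ1, smp$settings,
                               smp$patient))
      g0 <- glance(accrue_econ(smp$comparator, occ0, smp$settings,
                               smp$patient))
      tibble(draw = i, cost_intervention = g1$total_cost,
             qaly_intervention = g1$total_qaly,
             cost_comparator = g0$total_cost,
             qaly_comparator = g0$total_qaly,
             dc = g1$total_cost - g0$total_cost,
             de = g1$total_qaly - g0$total_qaly)
    })
  })
  draws$nmb_incr <- inputs$wtp * draws$de - draws$dc
  ceac <- tibble(
    wtp = wtp_grid,
    p_intervention = vapply(wtp_grid,
                            function(w) mean(w * draws$de - draws$dc > 0),
                            numeric(1))
  )
  ceac$p_comparator <- 1 - ceac$p_intervention
  structure(
    list(draws = draws, ceac = ceac, seed = seed, n_draws = n_draws,
         wtp = inputs$wtp),
    class = "psa_result"
  )
}

#' @exportS3Method generics::glance
glance.psa_result <- function(x, ...) {
  tibble(
    n_draws = x$n_draws, seed = x$seed, wtp = x$wtp,
    mean_dc = mean(x$draws$dc), mean_de = mean(x$draws$de),
    p_cost_effective = mean(x$draws$nmb_incr > 0)
  )
}

#' @export
print.psa_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<psa_result> %d draws (seed %d)\n  mean dC %.0f, mean dE %.3f\n  P(cost-effective at WTP %s) = %.1f%%\n",
    g$n_draws, g$seed, g$mean_dc, g$mean_de,
    format(g$wtp, big.mark = ","), 100 * g$p_cost_effective
  ))
  invisible(x)
}

#' Scenario analysis: price reduction, WTP swap, alternative input set
#'
#' Applies a price multiplier to the intervention's drug acquisition cost
#' only (other direct medical costs unchanged), and/or replaces the
#' willingness-to-pay threshold, then re-runs the base case and optionally
#' the PSA. Alternative populations (e.g. a subgroup) are handled by
#' passing that population's `cea_inputs`.
#'
#' @param inputs A [cea_inputs()].
#' @param price_multiplier Multiplier on the intervention drug unit price
#'   (e.g. 0.7 for a 30% price cut).
#' @param wtp Optional replacement willingness-to-pay threshold.
#' @param label Scenario label.
#' @param psa Run a PSA under the scenario as well?
#' @param n_draws,seed,cost_sd_frac,util_sd_frac Passed to [run_psa()] when
#'   `psa = TRUE`.
#' @return A list of class `scenario_result` with `label`, `cea` (a
#'   `cea_result`), and `psa` (a `psa_result` or `NULL`).
#' @export
run_scenario <- function(inputs, price_multiplier = 1, wtp = NULL,
                         label = NULL, psa = FALSE, n_draws = 1000,
                         seed = 1L, cost_sd_frac = 0.25,
                         util_sd_frac = 0.10) {
  if (price_multiplier <= 0) abort("`price_multiplier` must be positive.")
  inputs$intervention$regimen$unit_price <-
    inputs$intervention$regimen$unit_price * price_multiplier
  if (!is.null(wtp)) inputs$wtp <- wtp
  structure(
    list(
      label = label %||% sprintf("price x %.2f, WTP %s", price_multiplier,
                                 format(inputs$wtp, big.mark = ",")),
      price_multiplier = price_multiplier, wtp = inputs$wtp,
      cea = run_base_case(inputs),
      psa = if (psa) run_psa(inputs, n_draws, seed,
                             cost_sd_frac = cost_sd_frac,
                             util_sd_frac = util_sd_frac) else NULL
    ),
    class = "scenario_result"
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.owsa_result <- function(object, ...) {
  df <- as_tibble(object)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "base_icer"),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity (tornado)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.psa_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$ceac, c("p_intervention", "p_comparator"),
                            names_to = "strategy", values_to = "p")
  df$strategy <- factor(df$strategy, levels = c("p_intervention",
                                                "p_comparator"),
                        labels = c("Intervention", "Comparator"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wtp, y = .data$p,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$wtp, linetype = 2) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective", colour = NULL)
}
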