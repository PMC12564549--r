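# Synthetic two-arm OS/PFS trial generator. Emulates the publication
# pipeline — subject-level times, KM curves, digitized coordinates with
# click noise, numbers-at-risk tables — so that reconstruction, fitting and
# the economic model can be exercised end to end with known truth.

median_of <- function(family, params) {
  p <- check_family_params(family, params)
  switch(family,
    weibull = p[["scale"]] * log(2)^(1 / p[["shape"]]),
    gamma = qgamma(0.5, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal = exp(p[["meanlog"]]),
    loglogistic = p[["scale"]]
  )
}

draw_times <- function(n, family, params) {
  p <- params
  switch(family,
    weibull = rweibull(n, shape = p[["shape"]], scale = p[["scale"]]),
    gamma = rgamma(n, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal = rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    loglogistic = {
      u <- runif(n)
      p[["scale"]] * (u / (1 - u))^(1 / p[["shape"]])
    }
  )
}

#' Specify a synthetic two-arm trial
#'
#' Each arm has a death-time distribution (OS) and a latent
#' progression-time distribution; observed PFS is the minimum of
#' progression and death, so PFS <= OS holds at the subject level by
#' construction. Subjects accrue uniformly over `accrual_months` and are
#' administratively censored at `max_followup_months` after trial start.
#'
#' @param arms Named list; each element a list with `n`, `os` and `pfs`,
#'   where `os`/`pfs` are `list(family =, params =)` specifications of the
#'   death and latent progression time distributions.
#' @param accrual_months Uniform accrual window (0 = simultaneous entry).
#' @param max_followup_months Administrative cut-off from trial start
#'   (`Inf` = no censoring).
#' @return A list of class `synthetic_trial_spec`.
#' @examples
#' synthetic_trial_spec(list(
#'   SG = list(n = 100,
#'             os = list(family = "weibull", params = c(shape = 1.2, scale = 16)),
#'             pfs = list(family = "weibull", params = c(shape = 1.2, scale = 7)))
#' ), accrual_months = 12, max_followup_months = 36)
#' @export
synthetic_trial_spec <- function(arms, accrual_months = 0,
                                 max_followup_months = Inf) {
  check_number(accrual_months, "accrual_months", lower = 0)
  if (!is.list(arms) || length(arms) < 1L || is.null(names(arms))) {
    abort("`arms` must be a named list of arm specifications.")
  }
  for (nm in names(arms)) {
    a <- arms[[nm]]
    if (!all(c("n", "os", "pfs") %in% names(a))) {
      abort(sprintf("arm '%s' needs `n`, `os`, `pfs`.", nm))
    }
    if (a$n < 1) abort(sprintf("arm '%s': n must be >= 1.", nm))
    m_os <- median_of(a$os$family, a$os$params)
    m_pfs <- median_of(a$pfs$family, a$pfs$params)
    if (m_pfs > m_os) {
      abort(sprintf(
        "arm '%s': latent progression median (%.2f) exceeds OS median (%.2f).",
        nm, m_pfs, m_os
      ))
    }
  }
  structure(
    list(arms = arms, accrual_months = accrual_months,
         max_followup_months = max_followup_months),
    class = "synthetic_trial_spec"
  )
}

#' Simulate a two-arm OS/PFS trial
#'
#' Per subject: draw a death time and a latent progression time, set
#' PFS = min(progression, death); draw a uniform accrual offset and censor
#' both endpoints administratively at `max_followup - offset`. A PFS record
#' is censored whenever follow-up ends before both progression and death.
#' Byte-identical under the same seed.
#'
#' @param spec A [synthetic_trial_spec()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_trial`: `ipd` (tibble `arm`,
#'   `endpoint`, `time`, `event`), `truth` (per-subject latent times and
#'   the generating spec), `seed`.
#' @export
simulate_trial <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  sim <- function() {
    purrr::map_dfr(names(spec$arms), function(nm) {
      a <- spec$arms[[nm]]
      t_death <- draw_times(a$n, a$os$family, a$os$params)
      t_prog <- draw_times(a$n, a$pfs$family, a$pfs$params)
      offset <- if (spec$accrual_months > 0) {
        runif(a$n, 0, spec$accrual_months)
      } else {
        rep(0, a$n)
      }
      fup <- spec$max_followup_months - offset
      tibble(arm = nm, subject = seq_len(a$n), t_death = t_death,
             t_prog = pmin(t_prog, t_death), followup = fup)
    })
  }
  truth <- withr::with_seed(seed, sim())
  # tiny positive floor keeps parametric likelihoods defined
  eps <- 1e-6
  ipd <- bind_rows(
    mutate(truth,
           endpoint = "os",
           time = pmax(pmin(.data$t_death, .data$followup), eps),
           event = as.integer(.data$t_death <= .data$followup)),
    mutate(truth,
           endpoint = "pfs",
           time = pmax(pmin(.data$t_prog, .data$followup), eps),
           event = as.integer(.data$t_prog <= .data$followup))
  )
  structure(
    list(
      ipd = as_tibble(ipd[, c("arm", "endpoint", "time", "event")]),
      truth = truth, spec = spec, seed = seed
    ),
    class = "synthetic_trial"
  )
}

#' Extract one arm/endpoint as pseudo-IPD
#'
#' @param trial A `synthetic_trial`.
#' @param arm,endpoint Labels (`endpoint` is `"os"` or `"pfs"`).
#' @return A `pseudo_ipd` tibble.
#' @export
trial_ipd <- function(trial, arm, endpoint) {
  df <- filter(trial$ipd, .data$arm == !!arm, .data$endpoint == !!endpoint)
  if (nrow(df) == 0L) abort(sprintf("no records for %s/%s.", arm, endpoint))
  new_psmcea_tbl(df[, c("time", "event")], "pseudo_ipd",
                 arm = arm, endpoint = endpoint)
}

#' Emulate manual digitization of a Kaplan-Meier curve
#'
#' Samples the step function at survival-quantile-spaced times (clicks
#' cluster where the curve drops, as a careful digitizer's do), adds
#' truncated-normal click noise to the survival values (truncated at two
#' standard deviations), and repairs the result with
#' [clean_digitized_curve()]. `jitter_sd = 0` returns exact step samples.
#'
#' @param km A `km_estimate`.
#' @param n_points Number of clicks (>= 2).
#' @param jitter_sd Standard deviation of the click noise on the survival
#'   scale.
#' @param seed Optional seed for the jitter.
#' @return A `digitized_curve`.
#' @export
emulate_digitization <- function(km, n_points = 100, jitter_sd = 0,
                                 seed = NULL) {
  if (n_points < 2) abort("`n_points` must be at least 2.")
  s_grid <- seq(1, min(km$survival), length.out = n_points)
  t_max <- max(km$time)
  times <- vapply(s_grid, function(q) {
    hit <- which(km$survival <= q + 1e-12)
    if (length(hit) == 0L) 0 else km$time[hit[1L]]
  }, numeric(1))
  times <- sort(unique(c(0, times, t_max)))
  if (n_points == 2) times <- c(0, t_max)
  surv <- km_survival(km, times)
  if (jitter_sd > 0) {
    jitter <- function() {
      z <- rnorm(length(surv), 0, jitter_sd)
      pmin(pmax(z, -2 * jitter_sd), 2 * jitter_sd)
    }
    z <- if (is.null(seed)) jitter() else withr::with_seed(seed, jitter())
    surv <- surv + z
    surv[times == 0] <- 1
  }
  clean_digitized_curve(tibble(time = times, survival = surv),
                        endpoint = attr(km, "endpoint"),
                        arm = attr(km, "arm"))
}

#' Build a numbers-at-risk table from subject-level data
#'
#' @param ipd A `pseudo_ipd` (or data frame with `time`).
#' @param times Increasing vector of report times.
#' @return A `risk_table`: at each time, the count of records with
#'   `time >= t`.
#' @export
make_risk_table <- function(ipd, times) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  at_risk <- vapply(times, function(tt) sum(ipd$time >= tt), numeric(1))
  risk_table(times, at_risk)
}

#' Write a complete runnable fixture bundle
#'
#' Simulates a trial, emulates digitization, and writes the digitized-curve
#' and risk-table CSVs for every arm and endpoint in the dialects consumed
#' by [read_digitized_curve()] / [read_risk_table()], plus the true
#' subject-level IPD for reference.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synthetic_trial_spec()].
#' @param seed Integer seed.
#' @param n_points,jitter_sd Digitization emulation settings.
#' @param risk_times Risk-table report times; default: eight equal steps
#'   from 0 to the last observed time of each arm/endpoint.
#' @return Invisibly, a tibble of the files written (`arm`, `endpoint`,
#'   `curve`, `risk`).
#' @export
write_fixture_bundle <- function(dir, spec, seed = 1L, n_points = 80,
                                 jitter_sd = 0.005, risk_times = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trial <- simulate_trial(spec, seed)
  grid <- tidyr::expand_grid(arm = names(spec$arms),
                             endpoint = c("os", "pfs"))
  files <- purrr::pmap_dfr(grid, function(arm, endpoint) {
    ipd <- trial_ipd(trial, arm, endpoint)
    km <- km_estimate(ipd)
    rt_times <- risk_times %||% seq(0, max(ipd$time), length.out = 9L)
    curve <- emulate_digitization(km, n_points, jitter_sd,
                                  seed = seed + match(endpoint, c("os", "pfs")))
    rt <- make_risk_table(ipd, rt_times)
    curve_path <- file.path(dir, sprintf("curve_%s_%s.csv", arm, endpoint))
    risk_path <- file.path(dir, sprintf("risk_%s_%s.csv", arm, endpoint))
    readr::write_csv(as_tibble(curve), curve_path)
    readr::write_csv(as_tibble(rt), risk_path)
    write_ipd(ipd, file.path(dir, sprintf("ipd_%s_%s.csv", arm, endpoint)))
    tibble(arm = arm, endpoint = endpoint, curve = curve_path,
           risk = risk_path)
  })
  invisible(files)
}
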