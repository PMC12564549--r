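# Censored maximum-likelihood fitting of the four candidate survival
# families used for extrapolation, information-criterion selection, and
# survival evaluation on arbitrary time grids.
#
# Parameterizations (fixed):
#   weibull      shape, scale      S(t) = exp(-(t/scale)^shape)
#   gamma        shape, scale      S(t) = upper regularized incomplete gamma
#   lognormal    meanlog, sdlog    S(t) = 1 - Phi((log t - meanlog)/sdlog)
#   loglogistic  shape, scale      S(t) = 1 / (1 + (t/scale)^shape)

surv_families <- function() c("weibull", "gamma", "lognormal", "loglogistic")

param_names <- function(family) {
  switch(family,
    weibull = ,
    gamma = ,
    loglogistic = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    abort(sprintf("unknown family '%s'", family))
  )
}

check_family_params <- function(family, params) {
  nm <- param_names(family)
  if (length(params) != 2L) abort("`params` must have length 2.")
  if (!is.null(names(params)) && all(nm %in% names(params))) {
    params <- params[nm]
  } else {
    names(params) <- nm
  }
  pos <- if (family == "lognormal") params["sdlog"] else params
  if (any(!is.finite(params)) || any(pos <= 0)) {
    abort(sprintf("parameters out of domain for %s: (%s).", family,
                  paste(signif(params, 4), collapse = ", ")))
  }
  params
}

log_density <- function(family, params, t) {
  p <- params
  switch(family,
    weibull = dweibull(t, shape = p[["shape"]], scale = p[["scale"]], log = TRUE),
    gamma = dgamma(t, shape = p[["shape"]], scale = p[["scale"]], log = TRUE),
    lognormal = dlnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]], log = TRUE),
    loglogistic = {
      a <- p[["shape"]]; s <- p[["scale"]]
      log(a / s) + (a - 1) * log(t / s) - 2 * log1p((t / s)^a)
    }
  )
}

log_survival <- function(family, params, t) {
  p <- params
  switch(family,
    weibull = pweibull(t, shape = p[["shape"]], scale = p[["scale"]],
                       lower.tail = FALSE, log.p = TRUE),
    gamma = pgamma(t, shape = p[["shape"]], scale = p[["scale"]],
                   lower.tail = FALSE, log.p = TRUE),
    lognormal = plnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                       lower.tail = FALSE, log.p = TRUE),
    loglogistic = -log1p((t / p[["scale"]])^p[["shape"]])
  )
}

#' Censored log-likelihood of a parametric survival family
#'
#' \eqn{\sum_{events} \log f(t) + \sum_{censored} \log S(t)}, the objective
#' maximized by [fit_parametric()].
#'
#' @param family One of `"weibull"`, `"gamma"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @param params Length-2 numeric vector, named as the family's parameters
#'   (shape/scale, or meanlog/sdlog for the lognormal).
#' @param ipd Data frame with columns `time` (> 0) and `event` (0/1).
#' @return The log-likelihood (0 for an empty `ipd`).
#' @export
surv_loglik <- function(family, params, ipd) {
  family <- match.arg(family, surv_families())
  params <- check_family_params(family, params)
  if (nrow(ipd) == 0L) return(0)
  t <- as.numeric(ipd$time)
  ev <- as.integer(ipd$event)
  if (any(t <= 0)) abort("all times must be positive for parametric likelihoods.")
  sum(log_density(family, params, t[ev == 1L])) +
    sum(log_survival(family, params, t[ev == 0L]))
}

start_values <- function(family, ipd) {
  te <- ipd$time[ipd$event == 1L]
  lt <- log(te)
  total_time <- sum(ipd$time)
  d <- length(te)
  switch(family,
    weibull = c(shape = 1, scale = max(total_time / d, 1e-8)),
    gamma = {
      m <- mean(te); v <- stats::var(te)
      if (!is.finite(v) || v <= 0) v <- m^2
      c(shape = max(m^2 / v, 0.1), scale = max(v / m, 1e-8))
    },
    lognormal = {
      s <- sd(lt)
      c(meanlog = mean(lt), sdlog = if (is.finite(s) && s > 0) s else 1)
    },
    loglogistic = {
      s <- sd(lt)
      b <- if (is.finite(s) && s > 0) pi / (s * sqrt(3)) else 1
      c(shape = b, scale = max(median(te), 1e-8))
    }
  )
}

to_natural <- function(family, lp) {
  nm <- param_names(family)
  out <- if (family == "lognormal") c(lp[1L], exp(lp[2L])) else exp(lp)
  setNames(out, nm)
}

from_natural <- function(family, p) {
  if (family == "lognormal") c(p[[1L]], log(p[[2L]])) else log(p)
}

#' Fit a parametric survival family by censored maximum likelihood
#'
#' Quasi-Newton optimization on log-transformed parameters (positivity is
#' enforced by the transform), started from moment/log-scale heuristics,
#' with relative tolerance 1e-8 on the objective and a Nelder-Mead fallback.
#' Non-convergence is an error, never silent.
#'
#' @param ipd Data frame with columns `time` (> 0), `event` (0/1); at least
#'   two events are required for a two-parameter family to be identifiable.
#' @inheritParams surv_loglik
#' @return An object of class `parametric_fit`: a list with `family`,
#'   `params` (named), `loglik`, `n`, `k` (= 2), `aic`, `bic`, `converged`.
#' @examples
#' ipd <- data.frame(time = rweibull(200, 1.3, 10), event = 1)
#' fit_parametric(ipd, "weibull")
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  ev <- as.integer(ipd$event)
  if (sum(ev == 1L) == 0L) {
    abort("non-identifiable: all records are censored.")
  }
  if (sum(ev == 1L) < 2L) {
    abort("boundary: need at least 2 events to fit a two-parameter family.")
  }
  neg <- function(lp) {
    p <- to_natural(family, lp)
    ll <- suppressWarnings(surv_loglik(family, p, ipd))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  lp0 <- from_natural(family, start_values(family, ipd))
  opt <- optim(lp0, neg, method = "BFGS",
               control = list(reltol = 1e-8, maxit = 1000))
  if (opt$convergence != 0) {
    opt2 <- optim(opt$par, neg, method = "Nelder-Mead",
                  control = list(reltol = 1e-8, maxit = 5000))
    if (opt2$value <= opt$value) opt <- opt2
  }
  if (opt$convergence != 0) {
    abort(sprintf("MLE for %s did not converge (optim code %d).",
                  family, opt$convergence))
  }
  params <- to_natural(family, opt$par)
  loglik <- -opt$value
  n <- nrow(ipd)
  k <- 2L
  structure(
    list(
      family = family, params = params, loglik = loglik,
      n = n, k = k,
      aic = 2 * k - 2 * loglik,
      bic = k * log(n) - 2 * loglik,
      converged = TRUE
    ),
    class = "parametric_fit"
  )
}

#' Construct a parametric survival function from known parameters
#'
#' Mainly for scenario work and testing: wraps a (family, params) pair in the
#' same object [fit_parametric()] returns, without likelihood information.
#'
#' @inheritParams surv_loglik
#' @export
parametric_surv <- function(family, params) {
  family <- match.arg(family, surv_families())
  params <- check_family_params(family, params)
  structure(
    list(family = family, params = params, loglik = NA_real_,
         n = NA_integer_, k = 2L, aic = NA_real_, bic = NA_real_,
         converged = NA),
    class = "parametric_fit"
  )
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("<parametric_fit> %s(%s)\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", ")))
  if (is.finite(x$loglik)) {
    cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f  (n = %d)\n",
                x$loglik, x$aic, x$bic, x$n))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.parametric_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @exportS3Method generics::glance
glance.parametric_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik, AIC = x$aic, BIC = x$bic,
         nobs = x$n, df = x$k)
}

#' Fit all candidate families to one arm/endpoint
#'
#' @inheritParams fit_parametric
#' @param families Character vector of families to fit.
#' @return Named list of `parametric_fit` objects.
#' @export
fit_all_families <- function(ipd, families = surv_families()) {
  fits <- purrr::map(families, \(f) fit_parametric(ipd, f))
  setNames(fits, families)
}

#' Select the extrapolation family by information criterion
#'
#' Minimal AIC (default) or BIC; ties are broken by the fixed family order
#' weibull < gamma < lognormal < loglogistic.
#'
#' @param fits List of `parametric_fit` objects on the same data.
#' @param rule `"aic"` or `"bic"`.
#' @return The selected family name.
#' @export
select_distribution <- function(fits, rule = c("aic", "bic")) {
  rule <- match.arg(rule)
  if (length(fits) == 0L) abort("`fits` must be a non-empty list.")
  ns <- vapply(fits, `[[`, integer(1), "n")
  if (length(unique(ns)) > 1L) {
    abort("all fits must come from the same data (differing n).")
  }
  fam <- vapply(fits, `[[`, character(1), "family")
  crit <- vapply(fits, `[[`, numeric(1), rule)
  ord <- order(crit, match(fam, surv_families()))
  unname(fam[ord[1L]])
}

#' Parametric survival probability
#'
#' @param fit A `parametric_fit` (or the value of [parametric_surv()]).
#' @param t Vector of non-negative times (months).
#' @return S(t) for the fitted family.
#' @examples
#' survival_at(parametric_surv("weibull", c(shape = 2, scale = 10)), 10)
#' @export
survival_at <- function(fit, t) {
  if (any(t < 0)) abort("`t` must be non-negative.")
  out <- exp(log_survival(fit$family, fit$params, t))
  out[t == 0] <- 1
  pmin(pmax(out, 0), 1)
}

#' Tabulate fits with the selected family flagged
#'
#' One row per family, matching the fit-report CSV layout
#' (`endpoint,arm,family,param1,param2,loglik,aic,bic,selected`).
#'
#' @inheritParams select_distribution
#' @param endpoint,arm Labels for the report.
#' @export
fit_report <- function(fits, rule = c("aic", "bic"), endpoint = NA_character_,
                       arm = NA_character_) {
  rule <- match.arg(rule)
  sel <- select_distribution(fits, rule)
  purrr::map_dfr(fits, function(f) {
    tibble(
      endpoint = endpoint, arm = arm, family = f$family,
      param1 = unname(f$params[1L]), param2 = unname(f$params[2L]),
      loglik = f$loglik, aic = f$aic, bic = f$bic,
      selected = f$family == sel
    )
  })
}
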