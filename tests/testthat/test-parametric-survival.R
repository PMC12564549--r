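test_that("censored log-likelihood matches closed forms", {
  # exponential-as-weibull: d events, total time T -> d log(lambda) - lambda T
  ipd <- data.frame(time = c(2, 4, 7, 1, 3), event = c(1, 1, 1, 0, 0))
  lambda <- 0.2
  d <- 3; total <- sum(ipd$time)
  expect_equal(
    surv_loglik("weibull", c(shape = 1, scale = 1 / lambda), ipd),
    d * log(lambda) - lambda * total
  )

  # empty data: zero
  expect_equal(
    surv_loglik("gamma", c(shape = 2, scale = 3),
                data.frame(time = numeric(0), event = integer(0))),
    0
  )

  # all censored: sum of log-survivals, strictly negative
  cens <- data.frame(time = c(5, 8), event = 0)
  ll <- surv_loglik("lognormal", c(meanlog = 2, sdlog = 0.5), cens)
  expect_equal(ll, sum(plnorm(c(5, 8), 2, 0.5, lower.tail = FALSE,
                              log.p = TRUE)))
  expect_lt(ll, 0)

  expect_error(
    surv_loglik("weibull", c(1, 2), data.frame(time = c(0, 1), event = 1)),
    "positive"
  )
  expect_error(surv_loglik("weibull", c(-1, 2), ipd), "domain")
})

test_that("MLE recovers the exponential closed form within 0.5%", {
  t <- withr::with_seed(10, rweibull(2000, 1, 10))
  ipd <- data.frame(time = t, event = 1)
  fit <- fit_parametric(ipd, "weibull")
  scale_hat_closed <- sum(t) / length(t) # 1 / lambda-hat = T / d
  expect_lt(abs(fit$params[["scale"]] - scale_hat_closed) / scale_hat_closed,
            0.005)
  expect_lt(abs(fit$params[["shape"]] - 1), 0.05)
})

test_that("parameters are recovered under censoring", {
  # lognormal(2, 0.5), n = 1000, ~20% censoring
  sim <- withr::with_seed(21, {
    t <- rlnorm(1000, meanlog = 2, sdlog = 0.5)
    cens <- runif(1000) < 0.2
    data.frame(time = ifelse(cens, t * runif(1000), t),
               event = as.integer(!cens))
  })
  fit <- fit_parametric(sim, "lognormal")
  expect_lt(abs(fit$params[["meanlog"]] - 2) / 2, 0.10)
  expect_lt(abs(fit$params[["sdlog"]] - 0.5) / 0.5, 0.10)

  # weibull(1.5, 12) under the same scheme
  sim2 <- withr::with_seed(22, {
    t <- rweibull(1000, shape = 1.5, scale = 12)
    cens <- runif(1000) < 0.2
    data.frame(time = ifelse(cens, t * runif(1000), t),
               event = as.integer(!cens))
  })
  fit2 <- fit_parametric(sim2, "weibull")
  expect_lt(abs(fit2$params[["shape"]] - 1.5) / 1.5, 0.10)
  expect_lt(abs(fit2$params[["scale"]] - 12) / 12, 0.10)
})

test_that("fitted parameters sit at a local optimum", {
  sim <- withr::with_seed(31, data.frame(time = rweibull(300, 1.4, 9),
                                         event = 1))
  for (family in c("weibull", "gamma", "lognormal", "loglogistic")) {
    fit <- fit_parametric(sim, family)
    base <- surv_loglik(family, fit$params, sim)
    expect_equal(base, fit$loglik, tolerance = 1e-8)
    # +/- 1% perturbations never improve the objective beyond tolerance
    for (i in 1:2) {
      for (eps in c(-0.01, 0.01)) {
        p <- fit$params
        p[i] <- p[i] * (1 + eps)
        expect_lt(surv_loglik(family, p, sim), base + 1e-6)
      }
    }
  }

  # two-event toy set: fit succeeds and beats the heuristic start
  toy <- data.frame(time = c(1, 2), event = 1)
  fit <- fit_parametric(toy, "weibull")
  expect_gte(fit$loglik,
             surv_loglik("weibull", c(shape = 1, scale = 1.5), toy))
})

test_that("degenerate inputs are rejected explicitly", {
  expect_error(
    fit_parametric(data.frame(time = c(1, 2, 3), event = 0), "weibull"),
    "censored"
  )
  expect_error(
    fit_parametric(data.frame(time = c(1, 2), event = c(1, 0)), "gamma"),
    "2 events"
  )
})

test_that("information criteria follow their identities and select the minimum", {
  sim <- withr::with_seed(41, data.frame(time = rweibull(400, 1.5, 10),
                                         event = 1))
  fits <- fit_all_families(sim)
  for (f in fits) {
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$loglik)
    expect_equal(f$k, 2L)
  }
  sel_aic <- select_distribution(fits, "aic")
  crit <- vapply(fits, `[[`, numeric(1), "aic")
  expect_equal(sel_aic, names(which.min(crit)))

  # forced ties resolve in the fixed family order
  tied <- lapply(fits, function(f) { f$aic <- 100; f })
  expect_equal(select_distribution(tied, "aic"), "weibull")
  expect_error(select_distribution(list()), "non-empty")
})

test_that("AIC prefers the generating family most of the time", {
  hits <- 0L
  n_rep <- 200L
  withr::with_seed(55, {
    for (r in seq_len(n_rep)) {
      sim <- data.frame(time = rweibull(1000, shape = 1.5, scale = 10),
                        event = 1)
      sel <- select_distribution(fit_all_families(sim), "aic")
      if (sel == "weibull") hits <- hits + 1L
    }
  })
  expect_gte(hits / n_rep, 0.70)
})

test_that("survival functions match closed forms and decrease", {
  expect_equal(
    survival_at(parametric_surv("weibull", c(shape = 2, scale = 10)), 10),
    exp(-1)
  )
  expect_equal(
    survival_at(parametric_surv("loglogistic", c(shape = 1, scale = 5)), 5),
    0.5
  )
  grid <- seq(0, 200, by = 0.25)
  fits <- list(
    parametric_surv("weibull", c(shape = 0.8, scale = 12)),
    parametric_surv("gamma", c(shape = 2.5, scale = 4)),
    parametric_surv("lognormal", c(meanlog = 2, sdlog = 0.7)),
    parametric_surv("loglogistic", c(shape = 1.7, scale = 8))
  )
  for (f in fits) {
    s <- survival_at(f, grid)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_lt(survival_at(f, 1e4), 0.01)
  }
  expect_error(survival_at(fits[[1]], -1), "non-negative")
})

test_that("numerical MLE agrees with an independent implementation", {
  skip_if_not_installed("flexsurv")
  sim <- withr::with_seed(61, {
    t <- rweibull(500, 1.3, 11)
    cens <- runif(500) < 0.25
    data.frame(time = ifelse(cens, t * runif(500), t),
               event = as.integer(!cens))
  })
  for (family in c("weibull", "lognormal")) {
    mine <- fit_parametric(sim, family)
    dist <- if (family == "lognormal") "lnorm" else family
    ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                                 data = sim, dist = dist)
    expect_equal(mine$loglik, ref$loglik, tolerance = 1e-6)
    expect_equal(unname(mine$params), unname(ref$res[, "est"]),
                 tolerance = 1e-4)
  }
})

test_that("tidy and glance expose the fit in broom shape", {
  sim <- withr::with_seed(71, data.frame(time = rweibull(100, 1.2, 8),
                                         event = 1))
  fit <- fit_parametric(sim, "weibull")
  td <- tidy(fit)
  expect_equal(td$term, c("shape", "scale"))
  g <- glance(fit)
  expect_equal(g$AIC, fit$aic)
  rep <- fit_report(fit_all_families(sim), "aic", endpoint = "os", arm = "SG")
  expect_equal(nrow(rep), 4)
  expect_equal(sum(rep$selected), 1)
})
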