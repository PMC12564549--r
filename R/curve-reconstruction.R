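# Reconstruction of pseudo individual patient data (IPD) from digitized
# Kaplan-Meier coordinates and numbers-at-risk tables, following the
# deterministic interval-allocation scheme of Guyot et al., plus the
# product-limit re-estimation used for round-trip validation.

#' Repair a digitized survival curve
#'
#' Digitized Kaplan-Meier coordinates carry click noise: times may be
#' unsorted or duplicated, survival values may exceed \[0, 1\] or increase
#' locally, and the (0, 1) origin is often not clicked. Reconstruction
#' requires a valid survival function, so this cleans the raw points into a
#' monotone step-sample: sort by time, keep the minimum survival at
#' duplicated times, clamp survival to \[0, 1\], replace any local increase
#' by the running minimum, and anchor the curve at (0, 1).
#'
#' @param points Data frame with numeric columns `time` (months, >= 0) and
#'   `survival`.
#' @param endpoint,arm Optional labels (e.g. `"OS"`, `"SG"`) stored as
#'   attributes and propagated downstream.
#' @return A tibble of class `digitized_curve` with columns `time`,
#'   `survival`; strictly increasing times, non-increasing survival,
#'   first row `(0, 1)`.
#' @examples
#' clean_digitized_curve(data.frame(time = c(6, 3), survival = c(0.5, 0.8)))
#' @export
clean_digitized_curve <- function(points, endpoint = NULL, arm = NULL) {
  if (!is.data.frame(points) || !all(c("time", "survival") %in% names(points))) {
    abort("`points` must be a data frame with columns `time` and `survival`.")
  }
  pts <- tibble(
    time = as.numeric(points$time),
    survival = as.numeric(points$survival)
  )
  pts <- filter(pts, is.finite(.data$time), is.finite(.data$survival))
  if (nrow(pts) < 2L) {
    abort("invalid curve: need at least 2 finite digitized points.")
  }
  if (all(pts$survival < 0 | pts$survival > 1)) {
    abort("invalid curve: all survival values lie outside [0, 1].")
  }
  if (any(pts$time < 0)) {
    abort("invalid curve: negative times.")
  }
  pts$survival <- pmin(pmax(pts$survival, 0), 1)
  pts <- pts |>
    group_by(.data$time) |>
    summarise(survival = min(.data$survival), .groups = "drop") |>
    arrange(.data$time)
  if (pts$time[1L] > 0) {
    pts <- bind_rows(tibble(time = 0, survival = 1), pts)
  } else {
    pts$survival[1L] <- 1
  }
  pts$survival <- cummin(pts$survival)
  new_psmcea_tbl(pts, "digitized_curve", endpoint = endpoint, arm = arm)
}

#' Numbers-at-risk table
#'
#' @param times Increasing vector of months at which numbers at risk were
#'   published (first entry is usually 0).
#' @param at_risk Non-increasing vector of non-negative integer counts;
#'   `at_risk[1]` is the arm sample size.
#' @return A tibble of class `risk_table` with columns `time`, `at_risk`.
#' @export
risk_table <- function(times, at_risk) {
  times <- as.numeric(times)
  at_risk <- as.numeric(at_risk)
  if (length(times) != length(at_risk) || length(times) < 1L) {
    abort("`times` and `at_risk` must be equal-length, non-empty vectors.")
  }
  if (any(diff(times) <= 0)) abort("risk-table times must be strictly increasing.")
  if (any(at_risk < 0) || any(at_risk != round(at_risk))) {
    abort("`at_risk` must be non-negative integers.")
  }
  if (any(diff(at_risk) > 0)) abort("`at_risk` must be non-increasing.")
  new_psmcea_tbl(tibble(time = times, at_risk = as.integer(at_risk)), "risk_table")
}

# log-linear interpolation of survival at time t (piecewise-exponential
# between clicks); falls back to linear where a segment touches zero
interp_survival <- function(time, surv, t) {
  vapply(t, function(tt) {
    if (tt <= time[1L]) return(surv[1L])
    k <- findInterval(tt, time)
    if (k >= length(time)) return(surv[length(surv)])
    if (time[k] == tt) return(surv[k])
    s0 <- surv[k]; s1 <- surv[k + 1L]
    w <- (tt - time[k]) / (time[k + 1L] - time[k])
    if (s0 <= 0 || s1 <= 0) return(s0 + w * (s1 - s0))
    exp(log(s0) + w * (log(s1) - log(s0)))
  }, numeric(1))
}

#' Reconstruct pseudo individual patient data from a published curve
#'
#' Deterministic version of the Guyot algorithm: within each interval of the
#' numbers-at-risk table, event counts at the digitized times and uniformly
#' spaced censoring times are chosen iteratively so that the product-limit
#' estimate of the output matches the digitized curve and the implied
#' numbers at risk match the published table. Risk-table times that fall
#' between clicks are handled by log-linear survival interpolation. All
#' subjects still at risk at the last risk-table time are censored there.
#'
#' @param curve A `digitized_curve` (see [clean_digitized_curve()]).
#' @param risk A `risk_table` whose times lie within the curve's range and
#'   start at 0.
#' @param total_events Optional integer: published total event count for the
#'   arm. When supplied, the latest censored/event records are flipped until
#'   the reconstructed event count matches. Default `NULL` (off).
#' @return A tibble of class `pseudo_ipd` with columns `time` (months > 0)
#'   and `event` (1 = event, 0 = censored); exactly `risk$at_risk[1]` rows.
#' @examples
#' curve <- clean_digitized_curve(
#'   data.frame(time = c(0, 2, 5), survival = c(1, 0.9, 0.8))
#' )
#' reconstruct_ipd(curve, risk_table(c(0, 6), c(10, 8)))
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  if (!inherits(curve, "digitized_curve")) curve <- clean_digitized_curve(curve)
  if (!inherits(risk, "risk_table")) risk <- risk_table(risk$time, risk$at_risk)
  if (risk$time[1L] != 0) abort("risk table must start at time 0.")

  # merge risk times into the click grid (log-linear interpolation; flat
  # carry-forward beyond the last click), drop
  # clicks beyond the last risk-table time: records cannot extend past it
  t_end <- max(risk$time)
  tt <- sort(unique(c(curve$time[curve$time <= t_end + 1e-9], risk$time)))
  ss <- interp_survival(curve$time, curve$survival, tt)
  lower <- match(risk$time, tt)
  m <- nrow(risk)

  n_events <- integer(length(tt))
  cens_times <- vector("list", max(m - 1L, 1L))
  km_prod <- 1
  n_cur <- risk$at_risk[1L]

  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      ks <- lower[i]:(lower[i + 1L] - 1L)
      target <- risk$at_risk[i + 1L]
      s_lo <- ss[lower[i]]
      s_hi <- ss[lower[i + 1L]]
      nc <- if (s_lo > 0) round(n_cur * s_hi / s_lo) - target else 0
      nc <- max(0L, as.integer(nc))

      # walk the interval for a censoring count nc: events at each click
      # from the running product-limit ratio, censorings between clicks
      walk <- function(nc, d_fixed = NULL) {
        ct <- if (nc > 0) {
          tt[lower[i]] + seq_len(nc) * (tt[lower[i + 1L]] - tt[lower[i]]) / (nc + 1)
        } else numeric(0)
        cen_k <- vapply(seq_along(ks), function(j) {
          k <- ks[j]
          sum(ct >= tt[k] & ct < tt[k + 1L])
        }, integer(1))
        n_k <- n_cur; km <- km_prod
        d_k <- integer(length(ks))
        for (j in seq_along(ks)) {
          k <- ks[j]
          d <- if (!is.null(d_fixed)) {
            d_fixed[j]
          } else if (km > 0 && n_k > 0) {
            round(n_k * (1 - ss[k] / km))
          } else 0
          d <- min(max(d, 0), n_k)
          if (n_k > 0 && d > 0) km <- km * (1 - d / n_k)
          d_k[j] <- as.integer(d)
          n_k <- n_k - d - cen_k[j]
        }
        list(d_k = d_k, ct = ct, km = km, n_end = n_k)
      }

      res <- walk(nc)
      for (iter in 1:100) {
        disc <- res$n_end - target
        if (disc == 0L) break
        nc_new <- nc + disc
        if (nc_new < 0L) {
          if (nc == 0L) break
          nc_new <- 0L
        }
        if (nc_new == nc) break
        nc <- as.integer(nc_new)
        res <- walk(nc)
      }

      if (res$n_end > target) {
        # rounding left a few subjects unaccounted for: censor them at the
        # end of the interval, after any events there
        extra <- res$n_end - target
        hi <- tt[lower[i + 1L]]
        lo <- tt[lower[i + 1L] - 1L]
        res$ct <- c(res$ct, rep(lo + 0.999 * (hi - lo), extra))
        res$n_end <- target
      }
      if (res$n_end < target) {
        # the curve implies more events than the at-risk counts admit; a
        # handful is expected digitization noise (drop the latest events),
        # more than that means curve and table contradict each other
        shortfall <- target - res$n_end
        if (shortfall > max(3L, ceiling(0.1 * n_cur)) ||
            shortfall > sum(res$d_k)) {
          abort(sprintf(
            paste0("reconstruction infeasible in risk-table interval %d ",
                   "[%g, %g]: implied censoring is negative (curve drops ",
                   "faster than the at-risk counts allow)."),
            i, risk$time[i], risk$time[i + 1L]
          ))
        }
        d_k <- res$d_k
        left <- shortfall
        for (j in rev(seq_along(d_k))) {
          take <- min(d_k[j], left)
          d_k[j] <- d_k[j] - take
          left <- left - take
          if (left == 0L) break
        }
        res <- walk(nc, d_fixed = d_k)
      }
      if (res$n_end != target) {
        abort(sprintf(
          "reconstruction failed to match the at-risk count %d at t = %g.",
          target, risk$time[i + 1L]
        ))
      }
      n_events[ks] <- res$d_k
      cens_times[[i]] <- res$ct
      km_prod <- res$km
      n_cur <- target
    }
  }

  # events at the final risk-table time, then censor the remainder there
  k_last <- lower[m]
  d <- if (km_prod > 0 && n_cur > 0) round(n_cur * (1 - ss[k_last] / km_prod)) else 0
  d <- as.integer(min(max(d, 0), n_cur))
  n_events[k_last] <- n_events[k_last] + d
  n_cur <- n_cur - d

  rec <- bind_rows(
    tibble(
      time = rep(tt, n_events),
      event = 1L
    ),
    tibble(time = unlist(cens_times), event = 0L),
    tibble(time = rep(tt[k_last], n_cur), event = 0L)
  )
  rec <- arrange(rec, .data$time, desc(.data$event))

  if (!is.null(total_events)) {
    total_events <- as.integer(total_events)
    rec <- calibrate_events(rec, total_events)
  }

  new_psmcea_tbl(rec, "pseudo_ipd",
    endpoint = attr(curve, "endpoint"), arm = attr(curve, "arm")
  )
}

# flip the latest censored<->event records until the event count matches a
# published total
calibrate_events <- function(rec, total_events) {
  delta <- total_events - sum(rec$event)
  if (delta == 0L) return(rec)
  if (delta > 0L) {
    idx <- which(rec$event == 0L)
    if (length(idx) < delta) {
      abort("cannot calibrate: requested total exceeds record count.")
    }
    idx <- idx[order(rec$time[idx], decreasing = TRUE)][seq_len(delta)]
    rec$event[idx] <- 1L
  } else {
    idx <- which(rec$event == 1L)
    if (length(idx) < -delta) {
      abort("cannot calibrate: requested total is negative after adjustment.")
    }
    idx <- idx[order(rec$time[idx], decreasing = TRUE)][seq_len(-delta)]
    rec$event[idx] <- 0L
  }
  arrange(rec, .data$time, desc(.data$event))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] (events before censorings at tied times, the
#' standard convention) and returns the step function as a tibble.
#'
#' @param ipd A `pseudo_ipd` or any data frame with columns `time`, `event`.
#' @return A tibble of class `km_estimate` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`. S(0) = 1 is implicit (the first row
#'   is the first observed time).
#' @export
km_estimate <- function(ipd) {
  if (!is.data.frame(ipd) || nrow(ipd) < 1L) {
    abort("`ipd` must be a data frame with at least one record.")
  }
  df <- data.frame(time = as.numeric(ipd$time), event = as.integer(ipd$event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                           conf.type = "none")
  out <- tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  new_psmcea_tbl(out, "km_estimate",
    endpoint = attr(ipd, "endpoint"), arm = attr(ipd, "arm"),
    n = nrow(df)
  )
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km A `km_estimate`.
#' @param t Vector of times (months).
#' @return Survival probabilities; 1 before the first observed time,
#'   right-continuous steps thereafter.
#' @export
km_survival <- function(km, t) {
  sf <- stats::stepfun(km$time, c(1, km$survival), right = FALSE)
  sf(t)
}

#' Median survival time
#'
#' The smallest time at which the estimated survival reaches 0.5 or below;
#' `NA` when the curve never crosses ("not reached").
#'
#' @param km A `km_estimate`.
#' @return Months, or `NA_real_` if the median is not reached.
#' @export
median_survival <- function(km) {
  hit <- which(km$survival <= 0.5 + 1e-9)
  if (length(hit) == 0L) NA_real_ else km$time[hit[1L]]
}

# CSV dialects ---------------------------------------------------------------

#' Read/write the package's CSV formats
#'
#' Digitized curves are `time,survival` files (one per arm and endpoint),
#' risk tables `time,at_risk`, pseudo-IPD `time,event`. Reading a curve
#' applies [clean_digitized_curve()].
#'
#' @param path File path.
#' @param endpoint,arm Optional labels attached to the result.
#' @return A `digitized_curve`, `risk_table`, or `pseudo_ipd` tibble.
#' @name curve_io
NULL

#' @rdname curve_io
#' @export
read_digitized_curve <- function(path, endpoint = NULL, arm = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time = readr::col_double(), survival = readr::col_double()
  ))
  clean_digitized_curve(df, endpoint = endpoint, arm = arm)
}

#' @rdname curve_io
#' @export
read_risk_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time = readr::col_double(), at_risk = readr::col_double()
  ))
  risk_table(df$time, df$at_risk)
}

#' @rdname curve_io
#' @param ipd A `pseudo_ipd`.
#' @export
write_ipd <- function(ipd, path) {
  readr::write_csv(tibble(time = ipd$time, event = as.integer(ipd$event)), path)
  invisible(path)
}

#' @rdname curve_io
#' @export
read_ipd <- function(path, endpoint = NULL, arm = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time = readr::col_double(), event = readr::col_integer()
  ))
  new_psmcea_tbl(df, "pseudo_ipd", endpoint = endpoint, arm = arm)
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_estimate <- function(object, ...) {
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability")
}
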