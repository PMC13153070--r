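#' Digitized Kaplan-Meier curve
#'
#' Ordered step coordinates of a survival curve as read off a published
#' figure: strictly increasing times starting at 0 and non-increasing
#' survival probabilities starting at 1.
#'
#' @param time times in months.
#' @param survival survival probabilities in `[0, 1]`.
#' @return a `data.frame` of class `digitized_curve`.
#' @export
digitized_curve <- function(time, survival) {
  if (length(time) != length(survival) || length(time) < 1L)
    stop("digitized_curve: 'time' and 'survival' must have equal positive length")
  if (time[1] != 0 || survival[1] != 1) {
    time <- c(0, time)
    survival <- c(1, survival)
  }
  if (any(diff(time) <= 0))
    stop("digitized_curve: times must be strictly increasing")
  if (any(survival < 0 | survival > 1))
    stop("digitized_curve: survival must lie in [0, 1]")
  if (any(diff(survival) > 1e-12))
    stop("digitized_curve: survival must be non-increasing")
  structure(data.frame(time_months = time, survival = survival),
            class = c("digitized_curve", "data.frame"))
}

#' Number-at-risk table
#'
#' @param time times in months (non-decreasing, starting at or before the
#'   curve's first coordinate).
#' @param n_risk numbers at risk: non-negative, non-increasing integers.
#' @return a `data.frame` of class `risk_table`.
#' @export
risk_table <- function(time, n_risk) {
  if (length(time) != length(n_risk) || length(time) < 1L)
    stop("risk_table: 'time' and 'n_risk' must have equal positive length")
  if (any(diff(time) <= 0))
    stop("risk_table: times must be strictly increasing")
  if (any(n_risk < 0) || any(n_risk != floor(n_risk)))
    stop("risk_table: counts must be non-negative integers")
  if (any(diff(n_risk) > 0))
    stop("risk_table: counts must be non-increasing")
  structure(data.frame(time_months = time, n_risk = as.integer(n_risk)),
            class = c("risk_table", "data.frame"))
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Inverts the Kaplan-Meier estimator: given step coordinates read off a
#' published survival figure and the numbers at risk printed beneath it,
#' recovers a per-subject event/censoring table whose product-limit
#' estimate reproduces the input coordinates.  Within each risk-table
#' interval the number censored is found iteratively so that the implied
#' number at risk matches the printed count at the start of the next
#' interval; censoring times are spread uniformly over the interval, and
#' implied fractional event counts are converted to integers by
#' remainder-carrying rounding that preserves interval totals.  When a
#' total event count is supplied, per-interval events are proportionally
#' rescaled to honour it before rounding.
#'
#' @param curve a [digitized_curve()].
#' @param risk a [risk_table()]; if `NULL`, zero censoring before last
#'   follow-up is assumed (all drops are events) and `n` must be given.
#' @param n initial cohort size, required when `risk` is `NULL`.
#' @param total_events optional reported total number of events.
#' @param arm,endpoint labels carried through to the output.
#' @return a `data.frame` of class `pseudo_ipd` with columns
#'   `time_months`, `event`, `arm`, `endpoint`; one row per subject, as
#'   many rows as the initial number at risk.
#' @export
reconstruct_ipd <- function(curve, risk = NULL, n = NULL,
                            total_events = NULL,
                            arm = "arm", endpoint = "endpoint") {
  stopifnot(inherits(curve, "digitized_curve"))
  t_s <- curve$time_months
  s <- curve$survival
  k_n <- length(t_s)

  if (is.null(risk)) {
    if (is.null(n)) stop("reconstruct_ipd: 'n' required when no risk table")
    risk <- risk_table(time = 0, n_risk = n)
  }
  stopifnot(inherits(risk, "risk_table"))
  trisk <- risk$time_months
  nrisk <- risk$n_risk
  if (nrisk[1] < 1) stop("reconstruct_ipd: first number at risk must be >= 1")
  if (trisk[1] > t_s[1]) stop("reconstruct_ipd: risk table must cover the curve support")
  n_int <- length(trisk)

  # map curve coordinates to risk intervals; a drop exactly at a risk
  # time belongs to the preceding interval, since the printed number at
  # risk at that time already excludes neither the event nor ties
  # (events precede censorings at the same time)
  lower <- vapply(seq_len(n_int), function(i) {
    if (i == 1) which(t_s >= trisk[i])[1] else which(t_s > trisk[i])[1]
  }, numeric(1))
  if (anyNA(lower)) {
    n_int <- max(which(!is.na(lower)))
    lower <- lower[seq_len(n_int)]
    trisk <- trisk[seq_len(n_int)]
    nrisk <- nrisk[seq_len(n_int)]
  }
  # keep only risk rows whose interval contains at least one coordinate,
  # so every interval can be walked
  keep <- c(TRUE, diff(lower) > 0)
  lower <- lower[keep]; trisk <- trisk[keep]; nrisk <- nrisk[keep]
  n_int <- length(trisk)
  upper <- c(lower[-1] - 1, k_n)

  n_hat <- rep(NA_real_, k_n + 1)
  cen <- rep(0, k_n)
  d <- rep(0, k_n)
  km_hat <- rep(1, k_n)
  n_censor <- rep(0, n_int)
  last_i <- rep(1, n_int)

  walk_interval <- function(i, last0) {
    # distribute censors and derive events along klicks of interval i,
    # starting from n at risk nrisk[i]; returns updated state
    last <- last0
    n_hat[lower[i]] <<- nrisk[i]
    frac <- numeric(0)
    ks <- lower[i]:upper[i]
    # real-valued implied events, then remainder-carrying rounding
    for (k in ks) {
      if (k == 1) {
        d[k] <<- 0
        km_hat[k] <<- 1
      } else {
        d_real <- n_hat[k] * (1 - s[k] / km_hat[last])
        frac <- c(frac, d_real)
        d[k] <<- cascade_round(frac)[length(frac)]
        d[k] <<- max(0, min(d[k], n_hat[k]))
        km_hat[k] <<- km_hat[last] * (1 - d[k] / n_hat[k])
      }
      n_hat[k + 1] <<- n_hat[k] - d[k] - cen[k]
      if (d[k] != 0) last <- k
    }
    last
  }

  for (i in seq_len(n_int)) {
    if (i < n_int) {
      # first guess of censors on interval i from the survival drop
      place_censors <- function(nc) {
        cen[lower[i]:upper[i]] <<- 0
        if (nc > 0) {
          cen_t <- t_s[lower[i]] + seq_len(nc) *
            (t_s[lower[i + 1]] - t_s[lower[i]]) / (nc + 1)
          brk <- c(t_s[lower[i]:upper[i]], t_s[lower[i + 1]])
          cen[lower[i]:upper[i]] <<-
            vapply(seq_len(upper[i] - lower[i] + 1), function(j)
              sum(cen_t >= brk[j] & cen_t < brk[j + 1]), numeric(1))
        }
      }
      guess <- if (s[lower[i]] > 0)
        round(nrisk[i] * s[lower[i + 1]] / s[lower[i]]) - nrisk[i + 1]
      else 0
      c_try <- max(guess, 0)
      tried <- integer(0)
      gaps <- integer(0)
      # walk is deterministic in the censor count, so iterate the count
      # until the implied n at risk matches, keeping the best candidate
      # when integer rounding makes the residual gap oscillate around 0
      repeat {
        if (c_try %in% tried || length(tried) > nrisk[1] + 10) {
          best <- tried[which.min(abs(gaps))]
          place_censors(best)
          last_i[i + 1] <- walk_interval(i, last_i[i])
          n_censor[i] <- best
          break
        }
        place_censors(c_try)
        last_i[i + 1] <- walk_interval(i, last_i[i])
        gap <- n_hat[lower[i + 1]] - nrisk[i + 1]
        tried <- c(tried, c_try)
        gaps <- c(gaps, gap)
        n_censor[i] <- c_try
        if (gap == 0 || (gap < 0 && c_try == 0)) break
        c_try <- max(c_try + gap, 0)
      }
      resid <- abs(n_hat[lower[i + 1]] - nrisk[i + 1])
      if (resid > max(3, 0.02 * nrisk[1]))
        stop(sprintf("reconstruct_ipd: risk table inconsistent on interval %d (times %.3g-%.3g): implied n at risk misses the printed count by %d",
                     i, trisk[i], trisk[i + 1], as.integer(resid)))
      # small residuals (digitization noise / rounding): adopt the
      # implied count and continue
      nrisk[i + 1] <- n_hat[lower[i + 1]]
    } else {
      # final interval: spread censors at the average prior rate (none if
      # the curve reaches zero or there was no prior censoring)
      if (n_int > 1 && upper[n_int] > lower[n_int]) {
        span_prev <- t_s[lower[n_int]] - t_s[1]
        span <- t_s[upper[n_int]] - t_s[lower[n_int]]
        if (span_prev > 0)
          n_censor[i] <- min(round(sum(n_censor) * span / span_prev), nrisk[i])
      }
      if (n_censor[i] > 0) {
        cen_t <- t_s[lower[i]] + seq_len(n_censor[i]) *
          (t_s[upper[i]] - t_s[lower[i]]) / (n_censor[i] + 1)
        brk <- c(t_s[lower[i]:upper[i]], t_s[upper[i]] + 1e-9)
        cen[lower[i]:upper[i]] <-
          vapply(seq_len(upper[i] - lower[i] + 1), function(j)
            sum(cen_t >= brk[j] & cen_t < brk[j + 1]), numeric(1))
      }
      last_i[i] <- walk_interval(i, last_i[i])
    }
  }

  # optional total-events constraint: rescale events proportionally,
  # re-round, absorb the difference into censoring
  if (!is.null(total_events) && sum(d) > 0 && sum(d) != total_events) {
    d_scaled <- d * total_events / sum(d)
    d_new <- cascade_round(d_scaled)
    d_new <- pmax(0, d_new)
    cen <- cen + (d - d_new)
    cen <- pmax(0, cen)
    d <- d_new
  }

  # assemble subjects: events at klick times, censors inside intervals,
  # survivors censored at last follow-up
  times <- c(rep(t_s, d), rep(0, 0))
  events <- rep(1L, sum(d))
  cen_times <- numeric(0)
  for (k in seq_len(k_n)) {
    if (cen[k] > 0) {
      upper_t <- if (k < k_n) t_s[k + 1] else t_s[k_n]
      cen_times <- c(cen_times,
                     t_s[k] + seq_len(cen[k]) * (upper_t - t_s[k]) / (cen[k] + 1))
    }
  }
  n_left <- nrisk[1] - sum(d) - sum(cen)
  if (n_left < 0)
    stop("reconstruct_ipd: bookkeeping produced more subjects than were at risk")
  out_t <- c(times, cen_times, rep(t_s[k_n], n_left))
  out_e <- c(events, rep(0L, length(cen_times)), rep(0L, n_left))
  out_t <- pmax(out_t, .Machine$double.eps)
  ord <- order(out_t, -out_e)  # ties: events before censorings
  structure(data.frame(time_months = out_t[ord], event = out_e[ord],
                       arm = arm, endpoint = endpoint),
            class = c("pseudo_ipd", "data.frame"))
}

#' Product-limit (Kaplan-Meier) estimate of a subject table
#'
#' @param ipd data.frame with `time_months` and `event`.
#' @return a [digitized_curve()] of the product-limit estimate, with steps
#'   at event times only.
#' @export
km_estimate <- function(ipd) {
  if (nrow(ipd) == 0L) stop("km_estimate: empty table")
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = ipd)
  keep <- fit$n.event > 0
  digitized_curve(time = c(0, fit$time[keep]),
                  survival = c(1, fit$surv[keep]))
}

#' Median survival time of a digitized curve
#'
#' The smallest time at which survival falls to 0.5 or below; `NA` when
#' the curve never reaches 0.5 within follow-up.
#'
#' @param curve a [digitized_curve()] (or data.frame with the same columns).
#' @return months, or `NA_real_` when the median is undefined.
#' @export
median_survival <- function(curve) {
  idx <- which(curve$survival <= 0.5)
  if (length(idx) == 0L) return(NA_real_)
  curve$time_months[idx[1]]
}

#' Maximum absolute difference between two survival curves
#'
#' Evaluates both step functions at the union of their step times and at
#' the requested times, and reports the largest absolute difference.
#' Used to validate reconstruction round-trips.
#'
#' @param a,b digitized curves.
#' @param at optional times at which to compare; defaults to the step
#'   times of `a`.
#' @return the maximum absolute survival difference.
#' @export
curve_max_abs_diff <- function(a, b, at = NULL) {
  if (is.null(at)) at <- a$time_months
  sa <- eval_step(a$time_months, a$survival, at)
  sb <- eval_step(b$time_months, b$survival, at)
  max(abs(sa - sb))
}
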