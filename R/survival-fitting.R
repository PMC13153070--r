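#' @importFrom stats AIC BIC logLik setNames
NULL

# family label -> flexsurv distribution name
.family_dists <- c(
  "exponential"       = "exp",
  "weibull"           = "weibull",
  "gompertz"          = "gompertz",
  "log-logistic"      = "llogis",
  "log-normal"        = "lnorm",
  "generalized-gamma" = "gengamma"
)

#' Names of the supported parametric survival families
#' @return character vector of family labels.
#' @export
survival_families <- function() names(.family_dists)

#' Fit one parametric survival family to subject-level data
#'
#' Maximum-likelihood fit under right censoring.  Optimization is
#' delegated to [flexsurv::flexsurvreg()]; on failure the fit is retried
#' from up to five jittered starting values before an error is raised,
#' since Gompertz and generalized-gamma likelihoods can be awkward on
#' small samples.
#'
#' @param ipd data.frame with `time_months` and `event` columns and at
#'   least two events.
#' @param family one of [survival_families()].
#' @return an object of class `parametric_fit` with elements `family`,
#'   `pars` (natural-parameter estimates), `loglik`, `k` (parameter
#'   count), `n`, `aic` (`2k - 2 loglik`), `bic` (`k log n - 2 loglik`),
#'   `surv` (vectorized survival function) and the underlying `fit`.
#' @export
fit_parametric <- function(ipd, family = survival_families()) {
  family <- match.arg(family)
  if (sum(ipd$event) < 2) stop("fit_parametric: need at least 2 events")
  dist <- .family_dists[[family]]
  f <- NULL
  err <- NULL
  for (attempt in 0:5) {
    f <- tryCatch({
      if (attempt == 0) {
        flexsurv::flexsurvreg(
          survival::Surv(time_months, event) ~ 1, data = ipd, dist = dist)
      } else {
        base <- flexsurv::flexsurvreg(
          survival::Surv(time_months, event) ~ 1, data = ipd, dist = "exp")
        rate <- base$res[1, "est"]
        inits <- switch(dist,
          exp      = rate,
          weibull  = c(1, 1 / rate),
          gompertz = c(1e-4, rate),
          llogis   = c(1.2, log(2)^(1) / rate),
          lnorm    = c(-log(rate), 1),
          gengamma = c(-log(rate), 1, 1))
        set.seed(1000 + attempt)
        inits <- inits * exp(stats::rnorm(length(inits), 0, 0.2))
        if (dist == "lnorm" || dist == "gengamma")
          inits[1] <- inits[1] + stats::rnorm(1, 0, 0.2)
        flexsurv::flexsurvreg(
          survival::Surv(time_months, event) ~ 1, data = ipd, dist = dist,
          inits = inits)
      }
    }, error = function(e) { err <<- e; NULL })
    if (!is.null(f)) break
  }
  if (is.null(f))
    stop("fit_parametric: ", family, " fit failed to converge: ",
         conditionMessage(err))
  est <- f$res[, "est"]
  names(est) <- rownames(f$res)
  pfun <- f$dfns$p
  surv_fn <- local({
    est_l <- as.list(est); pfun_l <- pfun
    function(t) {
      s <- 1 - do.call(pfun_l, c(list(q = t), est_l))
      pmin(pmax(s, 0), 1)
    }
  })
  k <- nrow(f$res)
  ll <- as.numeric(logLik(f))
  n <- nrow(ipd)
  structure(list(family = family, dist = dist, pars = est,
                 loglik = ll, k = k, n = n,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 surv = surv_fn, fit = f, converged = TRUE),
            class = "parametric_fit")
}

#' Fit all six parametric families
#'
#' @inheritParams fit_parametric
#' @param families subset of [survival_families()] to fit.
#' @return named list of `parametric_fit` objects; families whose fit
#'   fails are dropped with a warning.
#' @export
fit_all_parametric <- function(ipd, families = survival_families()) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_parametric(ipd, fam), error = function(e) {
      warning("dropping family '", fam, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (length(fits) == 0L) stop("fit_all_parametric: every family failed")
  fits
}

#' Akaike weights of a set of fitted models
#'
#' `w_i = exp(-0.5 (AIC_i - min AIC)) / sum_j exp(-0.5 (AIC_j - min AIC))`.
#' Weights are invariant to adding a constant to every AIC.
#'
#' @param fits list of `parametric_fit` objects (or a numeric vector of
#'   AIC values).
#' @return numeric weights summing to 1.
#' @export
aic_weights <- function(fits) {
  if (length(fits) == 0L) stop("aic_weights: empty model list")
  aics <- if (is.numeric(fits)) fits
          else vapply(fits, function(f) f$aic, numeric(1))
  d <- aics - min(aics)
  w <- exp(-0.5 * d)
  w / sum(w)
}

#' AIC-weighted model-averaged survival curve on a monthly grid
#'
#' Pointwise convex combination of the member survival functions,
#' representing structural uncertainty over the extrapolation family
#' rather than committing to a single parametric distribution.
#'
#' @param fits list of `parametric_fit` objects.
#' @param weights weights from [aic_weights()] (defaults to computing
#'   them from `fits`).
#' @param grid evaluation times in months, typically `0:horizon`.
#' @param arm,endpoint labels carried on the result.
#' @return an object of class `averaged_survival` with elements `grid`,
#'   `surv` (the averaged values), `weights`, `fits`, `arm`, `endpoint`.
#' @export
model_average <- function(fits, weights = aic_weights(fits), grid = 0:240,
                          arm = NULL, endpoint = NULL) {
  if (length(fits) != length(weights))
    stop("model_average: 'fits' and 'weights' lengths differ")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("model_average: weights must sum to 1")
  mat <- vapply(fits, function(f) f$surv(grid), numeric(length(grid)))
  surv <- as.numeric(mat %*% weights)
  surv <- pmin(pmax(surv, 0), 1)
  surv <- cummin(surv)  # guard against floating non-monotonicity
  averaged_survival(grid = grid, surv = surv, weights = weights,
                    fits = fits, arm = arm, endpoint = endpoint)
}

#' Construct an averaged-survival object from explicit values
#'
#' Container used both by [model_average()] and wherever a survival curve
#' on the monthly grid enters the Markov engine directly (for instance
#' after a hazard-ratio transform).
#'
#' @param grid times in months.
#' @param surv survival values on the grid; must start at 1 and be
#'   non-increasing in `[0, 1]`.
#' @param weights,fits optional member information.
#' @param arm,endpoint optional labels.
#' @return an object of class `averaged_survival`.
#' @export
averaged_survival <- function(grid, surv, weights = 1, fits = NULL,
                              arm = NULL, endpoint = NULL) {
  if (length(grid) != length(surv))
    stop("averaged_survival: grid/surv lengths differ")
  if (abs(surv[1] - 1) > 1e-9)
    stop("averaged_survival: survival must start at 1")
  if (any(surv < -1e-12 | surv > 1 + 1e-12) || any(diff(surv) > 1e-9))
    stop("averaged_survival: survival must be non-increasing in [0, 1]")
  structure(list(grid = grid, surv = pmin(pmax(surv, 0), 1),
                 weights = weights, fits = fits,
                 arm = arm, endpoint = endpoint),
            class = "averaged_survival")
}

#' @export
print.averaged_survival <- function(x, ...) {
  lab <- paste(c(x$arm, x$endpoint), collapse = " ")
  cat("Model-averaged survival", if (nzchar(lab)) paste0("(", lab, ")"),
      "\n  grid: 0..", max(x$grid), " months\n", sep = "")
  if (!is.null(x$fits)) {
    cat("  members:\n")
    for (i in seq_along(x$fits))
      cat(sprintf("    %-18s w = %.4f  AIC = %.2f\n",
                  x$fits[[i]]$family, x$weights[i], x$fits[[i]]$aic))
  }
  med <- median_survival(data.frame(time_months = x$grid, survival = x$surv))
  cat(sprintf("  median: %s months\n",
              if (is.na(med)) "not reached" else format(med)))
  invisible(x)
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("Parametric survival fit: %s\n", x$family))
  print(round(x$pars, 5))
  cat(sprintf("  loglik %.3f  AIC %.3f  BIC %.3f  (n = %d, events used for fit)\n",
              x$loglik, x$aic, x$bic, x$n))
  invisible(x)
}

#' Proportional-hazards transform of a survival curve
#'
#' Raises the survival function to the power of the hazard ratio,
#' `S_sub(t) = S(t)^hr` — the transform used to derive subgroup survival
#' for the experimental arm from the comparator curve and a published
#' subgroup hazard ratio.
#'
#' @param surv an `averaged_survival` object or numeric survival values.
#' @param hr hazard ratio (> 0).
#' @return same type as `surv`, transformed.
#' @export
apply_hazard_ratio <- function(surv, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || hr <= 0)
    stop("apply_hazard_ratio: 'hr' must be a positive scalar")
  if (inherits(surv, "averaged_survival")) {
    averaged_survival(grid = surv$grid, surv = surv$surv^hr,
                      arm = surv$arm, endpoint = surv$endpoint)
  } else {
    if (any(surv < 0 | surv > 1) || any(diff(surv) > 1e-12))
      stop("apply_hazard_ratio: values must be a non-increasing survival curve")
    surv^hr
  }
}

#' Write a YAML report of parametric fits and their weights
#'
#' @param fits list of `parametric_fit` objects.
#' @param weights Akaike weights (defaults to [aic_weights()]).
#' @param path output YAML path.
#' @return invisibly, the path.
#' @export
write_fit_report <- function(fits, weights = aic_weights(fits), path) {
  rep <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    list(family = f$family, parameters = as.list(f$pars),
         loglik = f$loglik, aic = f$aic, bic = f$bic,
         weight = as.numeric(weights[i]))
  })
  yaml::write_yaml(rep, path)
  invisible(path)
}
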