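make_exp_ipd <- function(n, median, seed, censor = 1e6) {
  generate_arm_ipd(arm_spec("OS", "tarlatamab", n = n, median = median,
                            admin_censor = censor), seed)
}

test_that("exponential fit matches the closed-form MLE on uncensored data", {
  ipd <- make_exp_ipd(200, 10, 4)
  f <- fit_parametric(ipd, "exponential")
  lambda_hat <- nrow(ipd) / sum(ipd$time_months)   # closed form
  expect_equal(unname(f$pars["rate"]), lambda_hat, tolerance = 1e-6)
  # information criteria from their definitions
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)
  expect_equal(f$bic, log(nrow(ipd)) - 2 * f$loglik)
  # survival function is the model's own
  expect_equal(f$surv(c(0, 5)), c(1, exp(-lambda_hat * 5)), tolerance = 1e-6)
})

test_that("weibull nests the exponential: its maximized loglik is no worse", {
  ipd <- make_exp_ipd(150, 8, 12)
  ll_exp <- fit_parametric(ipd, "exponential")$loglik
  ll_wei <- fit_parametric(ipd, "weibull")$loglik
  expect_gte(ll_wei, ll_exp - 1e-6)
})

test_that("weibull parameters are recovered on large samples", {
  shape <- 1.3; median <- 13.6
  scale <- median / log(2)^(1 / shape)
  sp <- arm_spec("OS", "tarlatamab", n = 1000, family = "weibull",
                 median = median, shape = shape, admin_censor = 1e6)
  f <- fit_parametric(generate_arm_ipd(sp, 8), "weibull")
  expect_lt(abs(f$pars["shape"] - shape) / shape, 0.05)
  expect_lt(abs(f$pars["scale"] - scale) / scale, 0.05)
})

test_that("all six families fit a censored sample and report criteria", {
  sp <- arm_spec("OS", "chemotherapy", n = 300, median = 8.3,
                 admin_censor = 30, censor_rate = 0.01)
  fits <- fit_all_parametric(generate_arm_ipd(sp, 14))
  expect_setequal(names(fits), survival_families())
  for (f in fits) {
    expect_true(is.finite(f$aic) && is.finite(f$bic))
    expect_equal(f$surv(0), 1)
    s <- f$surv(0:60)
    expect_true(all(diff(s) <= 1e-12))
  }
  expect_error(fit_parametric(data.frame(time_months = c(1, 2),
                                         event = c(0, 1)), "weibull"),
               "2 events")
})

test_that("aic weights follow the exponential weight formula", {
  expect_equal(aic_weights(100), 1)
  expect_equal(aic_weights(c(100, 100)), c(0.5, 0.5))
  w <- aic_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(sum(w), 1)
  # shift invariance
  expect_equal(aic_weights(c(100, 102) + 57.3), w)
  expect_error(aic_weights(list()), "empty")
})

test_that("model averaging is the pointwise convex combination", {
  ipd <- make_exp_ipd(120, 9, 6)
  f1 <- fit_parametric(ipd, "exponential")
  f2 <- fit_parametric(make_exp_ipd(120, 15, 7), "exponential")
  grid <- 0:60
  # single fit, weight 1: identity
  one <- model_average(list(f1), weights = 1, grid = grid)
  expect_equal(one$surv, f1$surv(grid))
  # two exponentials, equal weights: closed-form mixture
  avg <- model_average(list(f1, f2), weights = c(0.5, 0.5), grid = grid)
  l1 <- unname(f1$pars["rate"]); l2 <- unname(f2$pars["rate"])
  expect_equal(avg$surv, (exp(-l1 * grid) + exp(-l2 * grid)) / 2,
               tolerance = 1e-10)
  # convex-combination bound
  lo <- pmin(f1$surv(grid), f2$surv(grid))
  hi <- pmax(f1$surv(grid), f2$surv(grid))
  expect_true(all(avg$surv >= lo - 1e-12 & avg$surv <= hi + 1e-12))
  expect_equal(avg$surv[1], 1)
  expect_true(all(diff(avg$surv) <= 0))
  expect_error(model_average(list(f1, f2), weights = 1, grid = grid),
               "lengths differ")
})

test_that("the generating family usually attains the largest weight", {
  # lighter version of the large-sample identifiability property:
  # exponential data at n = 1000 should rank an exponential-compatible
  # family (exponential or its weibull superset) on top
  wins <- 0
  for (seed in 1:10) {
    ipd <- make_exp_ipd(1000, 10, seed, censor = 60)
    fits <- fit_all_parametric(ipd, c("exponential", "log-normal",
                                      "gompertz"))
    w <- aic_weights(fits)
    if (names(fits)[which.max(w)] == "exponential") wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("hazard-ratio transform preserves structure and scales medians", {
  grid <- 0:120
  s <- exp_surv(8.3, grid)
  expect_equal(apply_hazard_ratio(s, 1), s)
  # closed-form exponential median under proportional hazards
  s2 <- apply_hazard_ratio(s, 0.5)
  expect_equal(s2, exp_surv(16.6, grid), tolerance = 1e-12)
  expect_error(apply_hazard_ratio(s, 0), "'hr'")
  av <- averaged_survival(grid, s)
  av2 <- apply_hazard_ratio(av, 0.60)
  expect_s3_class(av2, "averaged_survival")
  expect_equal(av2$surv, s^0.6)
  expect_equal(av2$surv[1], 1)
  expect_true(all(diff(av2$surv) <= 0))
})

test_that("fit reports serialize to yaml", {
  ipd <- make_exp_ipd(100, 10, 9)
  fits <- list(fit_parametric(ipd, "exponential"),
               fit_parametric(ipd, "weibull"))
  p <- tempfile(fileext = ".yaml")
  write_fit_report(fits, path = p)
  back <- yaml::read_yaml(p)
  expect_length(back, 2)
  expect_equal(back[[1]]$family, "exponential")
  expect_equal(sum(vapply(back, `[[`, numeric(1), "weight")), 1,
               tolerance = 1e-8)
})
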