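test_that("evaluation is deterministic and effects ignore the drug price", {
  m <- toy_model(horizon = 120)
  r1 <- evaluate(m)
  r2 <- evaluate(m)
  expect_identical(r1, r2)
  # doubling the price moves costs, never effects
  m2 <- set_ce_parameter(m, "tarlatamab.drug_price_per_mg",
                         2 * get_ce_parameter(m, "tarlatamab.drug_price_per_mg"))
  r3 <- evaluate(m2)
  expect_identical(r3$d_effect, r1$d_effect)
  expect_gt(r3$d_cost, r1$d_cost)
  # identical arms: zero incremental effect, no exception
  m$curves$tarlatamab <- m$curves$chemotherapy
  m$inputs$arms$tarlatamab <- m$inputs$arms$chemotherapy
  m$inputs$arms$tarlatamab$label <- "tarlatamab"
  r4 <- evaluate(m)
  expect_equal(r4$d_effect, 0)
})

test_that("one-way DSA spans behave and exclude the intervention price", {
  m <- toy_model(horizon = 60)
  tor <- one_way_dsa(m)
  expect_false("tarlatamab.drug_price_per_mg" %in% tor$param)
  expect_true("chemotherapy.drug_cost_per_cycle" %in% tor$param)
  expect_true(all(tor$span >= 0))
  expect_true(all(diff(tor$span) <= 1e-9))   # sorted descending
  # zero-width range gives zero span; non-bracketing range errors
  z <- one_way_dsa(m, ranges = data.frame(param = "eol_cost",
                                          low = get_ce_parameter(m, "eol_cost"),
                                          high = get_ce_parameter(m, "eol_cost")))
  expect_equal(z$span, 0)
  expect_error(one_way_dsa(m, ranges = data.frame(
    param = "eol_cost", low = 1e9, high = 2e9)), "eol_cost")
})

test_that("DSA of a linearly entering cost matches the analytic slope", {
  m <- toy_model(horizon = 60)
  traces <- sclcea:::ce_traces(m)
  disc <- (1 + m$inputs$discount_annual)^(-(0:59) / 12)
  # routine monitoring applies from cycle 1 on, weighted by PFS occupancy
  occ <- traces$tarlatamab$pfs[1:60]
  slope <- sum((occ * disc)[-1])
  d_eff <- evaluate(m)$d_effect
  base <- get_ce_parameter(m, "tarlatamab.monitoring_routine")
  tor <- one_way_dsa(m, ranges = data.frame(
    param = "tarlatamab.monitoring_routine",
    low = 0.8 * base, high = 1.2 * base))
  expect_equal(tor$span, slope * 0.4 * base / d_eff, tolerance = 1e-8)
})

test_that("zero-variance PSA reproduces the base case exactly", {
  m <- toy_model(horizon = 60)
  s <- psa(m, n_iter = 5, seed = 3, se_frac = 0)
  base <- evaluate(m)
  expect_true(all(s$d_cost == base$d_cost))
  expect_true(all(s$d_effect == base$d_effect))
  expect_true(all(s$cost_intervention == base$intervention$cost))
})

test_that("PSA draws are reproducible, valid, and moment-matched", {
  m <- toy_model(horizon = 60)
  s1 <- psa(m, n_iter = 60, seed = 12)
  s2 <- psa(m, n_iter = 60, seed = 12)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  draws <- attr(s1, "draws")
  # utilities and probabilities stay in [0, 1], ordering preserved
  expect_true(all(draws[, "utility_pfs"] >= 0 & draws[, "utility_pfs"] <= 1))
  expect_true(all(draws[, "utility_pd"] <= draws[, "utility_pfs"]))
  inc_cols <- grep("ae_incidence", colnames(draws), value = TRUE)
  expect_true(all(draws[, inc_cols] >= 0 & draws[, inc_cols] <= 1))
  # law of large numbers on a gamma-drawn cost
  s3 <- psa(m, n_iter = 400, seed = 7)
  d3 <- attr(s3, "draws")[, "eol_cost"]
  mu <- get_ce_parameter(m, "eol_cost")
  expect_lt(abs(mean(d3) - mu), 3 * (0.2 * mu) / sqrt(400))
  # the intervention drug price is never drawn
  expect_false("tarlatamab.drug_price_per_mg" %in% colnames(draws))
})

test_that("the acceptability curve follows the net-benefit rule", {
  samples <- data.frame(d_cost = c(10, 20, -5, 40),
                        d_effect = c(1, 2, 1, -1))
  # hand enumeration at lambda = 15: NMB = 5, 10, 20, -55 -> 3/4
  expect_equal(ceac(samples, 15)$probability, 0.75)
  expect_equal(ceac(samples, 0)$probability, 0.25)  # only the cost-saving draw
  all_pos <- data.frame(d_cost = c(10, 20), d_effect = c(0.1, 0.2))
  expect_equal(ceac(all_pos, 0)$probability, 0)
  expect_equal(ceac(all_pos, 1e9)$probability, 1)
  # non-decreasing in lambda when all effects are positive
  p <- ceac(all_pos, seq(0, 500, by = 50))$probability
  expect_true(all(diff(p) >= 0))
  expect_error(ceac(all_pos[0, ], 1), "empty")
})

test_that("ICER rises monotonically along a price sweep", {
  m <- toy_model(horizon = 60)
  sw <- price_sweep(m, prices = seq(0, 2000, by = 100))
  expect_true(all(diff(sw$icer) > 0))
  expect_equal(sw$icer[1], min(sw$icer))
  sw2 <- price_sweep(m, prices = seq(0, 2000, by = 100))
  expect_identical(sw, sw2)
  expect_error(price_sweep(m, prices = c(5, 3)), "increasing")
})

test_that("threshold price inverts the ICER and matches the linear closed form", {
  m <- toy_model(horizon = 60)
  wtp <- 150000
  th <- threshold_price(m, wtp)
  expect_equal(th$flag, "ok")
  r_at <- evaluate(sclcea:::.with_price(m, th$price))
  expect_lte(r_at$icer, wtp)
  # one tolerance step above flips the verdict
  r_above <- evaluate(sclcea:::.with_price(m, th$price + 0.011))
  expect_gt(r_above$icer, wtp - 1)
  # closed form: cost is linear in price through discounted drug accrual
  traces <- sclcea:::ce_traces(m)
  disc <- (1 + m$inputs$discount_annual)^(-(0:59) / 12)
  occ <- traces$tarlatamab$pfs[1:60]
  mg_weight <- 21 * occ[1] * disc[1] + 20 * sum((occ * disc)[-1])
  r0 <- evaluate(sclcea:::.with_price(m, 0))
  p_star <- (wtp * r0$d_effect - r0$d_cost) / mg_weight
  expect_lt(abs(th$price - p_star), 0.02)
  # bracketing consistency with a sweep
  sw <- price_sweep(m, prices = seq(0, 2000, by = 50))
  below <- max(sw$price[sw$icer <= wtp])
  expect_true(th$price >= below && th$price <= below + 50)
  # unattainable threshold flags instead of erroring: zero out the
  # comparator drug cost so the intervention is dearer even at zero price
  m_flag <- set_ce_parameter(m, "chemotherapy.drug_cost_per_cycle", 0)
  expect_gt(evaluate(sclcea:::.with_price(m_flag, 0))$icer, 1)
  th2 <- threshold_price(m_flag, 1)
  expect_equal(th2$flag, "never_cost_effective")
  expect_true(is.na(th2$price))
})

test_that("subgroup analysis transforms only the intervention arm", {
  m <- toy_model(horizon = 60)
  sg1 <- subgroup_spec("unit HR", c(1, 1, 1), c(1, 1, 1))
  r1 <- subgroup_analysis(m, sg1, n_psa = 10)
  # identical survival: life-years match exactly; the residual effect is
  # only the differing one-time adverse-event disutilities
  expect_equal(r1$result$intervention$ly, r1$result$comparator$ly)
  expect_lt(abs(r1$result$d_effect), 0.02)
  # smaller OS hazard ratio gives weakly larger incremental effect
  sgA <- subgroup_spec("hr 0.8", c(0.8, 0.8, 0.8), c(0.9, 0.9, 0.9))
  sgB <- subgroup_spec("hr 0.5", c(0.5, 0.5, 0.5), c(0.9, 0.9, 0.9))
  rA <- subgroup_analysis(m, sgA, n_psa = 10)
  rB <- subgroup_analysis(m, sgB, n_psa = 10)
  expect_gt(rB$result$d_effect, rA$result$d_effect)
  # the all-patients row reproduces the trial hazard ratios
  sg <- subgroup_spec("All patients", c(0.60, 0.47, 0.77),
                      c(0.71, 0.59, 0.86))
  rr <- subgroup_analysis(m, sg, n_psa = 50)
  expect_true(rr$result$d_effect > 0)
  expect_true(rr$icer_range[["lower_hr"]] < rr$icer_range[["upper_hr"]])
  expect_true(rr$ce_probability >= 0 && rr$ce_probability <= 1)
  # per-label seeding is deterministic
  rr2 <- subgroup_analysis(m, sg, n_psa = 50)
  expect_identical(rr$ce_probability, rr2$ce_probability)
})

test_that("scenarios apply exactly the named overrides", {
  m <- toy_model(horizon = 120)
  base <- evaluate(m)
  expect_identical(scenario_run(m, list()), base)
  expect_error(scenario_run(m, list(banana = 1)), "unknown scenario knob")
  # shorter horizons truncate accrual
  r5 <- scenario_run(m, list(horizon = 60))
  expect_lt(r5$intervention$qaly, base$intervention$qaly)
  expect_lt(r5$intervention$ly, base$intervention$ly)
  # SMR engages pre-progression mortality (small effect, not a no-op)
  r_smr <- scenario_run(m, list(smr = 1.5))
  expect_false(identical(r_smr$d_cost, base$d_cost))
  # recurrent adverse events cost more than one-time ones
  r_rec <- scenario_run(m, list(recurrent_ae = TRUE))
  expect_gt(r_rec$intervention$cost, base$intervention$cost)
  # grade 1-2 CRS inclusion raises intervention cost only
  r_crs <- scenario_run(m, list(include_crs_g12 = TRUE))
  expect_gt(r_crs$intervention$cost, base$intervention$cost)
  expect_equal(r_crs$comparator$cost, base$comparator$cost)
})

test_that("single-distribution scenarios need and use member fits", {
  m <- toy_model(horizon = 60)
  expect_error(scenario_run(m, list(dist = "log-normal")), "member fits")
  # attach real fits: build small averaged curves for all four endpoints
  mk_av <- function(med, seed) {
    sp <- arm_spec("OS", "chemotherapy", n = 150, median = med,
                   admin_censor = 36, censor_rate = 0.005)
    fits <- fit_all_parametric(generate_arm_ipd(sp, seed),
                               c("exponential", "log-normal"))
    model_average(fits, grid = 0:60)
  }
  m$curves <- list(
    tarlatamab = list(pfs = mk_av(4.2, 4), os = mk_av(13.6, 5)),
    chemotherapy = list(pfs = mk_av(3.7, 6), os = mk_av(8.3, 7)))
  r_ln <- scenario_run(m, list(dist = "log-normal"))
  r_ex <- scenario_run(m, list(dist = "exponential"))
  expect_false(identical(r_ln$icer, r_ex$icer))
  expect_error(scenario_run(m, list(dist = "gompertz")), "not among")
})
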