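#' Synthetic economic-inputs fixture for a region
#'
#' Returns a fully populated [economic_inputs()] object with synthetic
#' but realistic values emulating the structure of published second-line
#' SCLC costing tables: step-up dosing for the bispecific arm (1 mg on
#' day 1, then 10 mg on days 8 and 15, maintenance 10 mg twice monthly),
#' a chemotherapy arm standardized to one administration block per
#' month, grade >= 3 adverse events with incidence >= 5%, CRS stratified
#' by severity, a subsequent-therapy / best-supportive-care split after
#' progression, and one-time end-of-life cost.  Region defaults: US uses
#' a 3% annual discount rate and a $150,000/QALY threshold; China uses
#' 5%, a threshold of three times per-capita GDP ($40,247.01), and a
#' tarlatamab price of exactly one-third of the US price.  All values
#' other than those region-level conventions are synthetic stand-ins for
#' unavailable source tables.
#'
#' @param region `"US"` or `"China"`.
#' @param seed reserved for future stochastic fixtures; the fixture is
#'   deterministic given `region`, and the value is recorded unchanged.
#' @return an [economic_inputs()] object.
#' @export
generate_economic_fixture <- function(region = c("US", "China"),
                                      seed = NULL) {
  region <- match.arg(region)
  us_price <- 1567.49  # USD per mg, market list price
  if (region == "US") {
    price <- us_price
    k <- 1            # cost scale relative to US
    admin <- 180; mon_first <- 8000; mon_routine <- 350
    chemo_cycle <- 7500
    subsequent <- 6500; bsc <- 1800; eol <- 11000
    discount <- 0.03; wtp <- 150000
  } else {
    price <- us_price / 3
    k <- 0.25
    admin <- 40; mon_first <- 1500; mon_routine <- 80
    chemo_cycle <- 1100
    subsequent <- 2800; bsc <- 450; eol <- 2100
    discount <- 0.05; wtp <- 40247.01
  }
  tar_ae <- data.frame(
    item = c("neutropenia", "anemia", "lymphopenia", "crs_grade12",
             "crs_grade3plus"),
    incidence = c(0.06, 0.10, 0.08, 0.46, 0.03),
    unit_cost = k * c(16000, 9000, 4000, 2500, 32000),
    disutility = c(0.20, 0.12, 0.05, 0.05, 0.15),
    class = c("grade3plus", "grade3plus", "grade3plus", "crs_g12",
              "crs_ge3"))
  chemo_ae <- data.frame(
    item = c("neutropenia", "anemia", "thrombocytopenia",
             "febrile_neutropenia"),
    incidence = c(0.45, 0.25, 0.20, 0.06),
    unit_cost = k * c(16000, 9000, 12000, 24000),
    disutility = c(0.20, 0.12, 0.11, 0.15),
    class = rep("grade3plus", 4))

  arms <- list(
    tarlatamab = arm_economics(
      label = "tarlatamab",
      drug_price_per_mg = price,
      first_cycle_mg = c(1, 10, 10),
      maint_admin_per_cycle = 2, maint_mg_per_admin = 10,
      admin_cost_per_visit = admin,
      monitoring_first_cycle = mon_first,
      monitoring_routine = mon_routine,
      ae = tar_ae,
      subsequent_monthly_cost = subsequent, subsequent_uptake = 0.50,
      bsc_monthly_cost = bsc),
    chemotherapy = arm_economics(
      label = "chemotherapy",
      drug_cost_per_cycle = chemo_cycle,
      admin_cost_per_visit = admin,
      monitoring_first_cycle = mon_routine,
      monitoring_routine = mon_routine,
      ae = chemo_ae,
      subsequent_monthly_cost = subsequent, subsequent_uptake = 0.55,
      bsc_monthly_cost = bsc))

  out <- economic_inputs(region = region, arms = arms,
                         utility_pfs = 0.70, utility_pd = 0.60,
                         discount_annual = discount, wtp = wtp,
                         eol_cost = eol, currency_divisor = 1,
                         inflation_factor = 1)
  attr(out, "seed") <- seed
  out
}

#' Write economic inputs to a YAML file
#' @param inputs an [economic_inputs()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_economic_yaml <- function(inputs, path) {
  stopifnot(inherits(inputs, "economic_inputs"))
  x <- unclass(inputs)
  x$arms <- lapply(x$arms, function(a) {
    a <- unclass(a)
    a$ae <- as.list(as.data.frame(a$ae))
    a
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read economic inputs from a YAML file written by [write_economic_yaml()]
#' @param path YAML path.
#' @return an [economic_inputs()] object.
#' @export
read_economic_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  arms <- lapply(x$arms, function(a) {
    ae <- as.data.frame(a$ae, stringsAsFactors = FALSE)
    arm_economics(label = a$label,
                  drug_price_per_mg = a$drug_price_per_mg,
                  first_cycle_mg = unlist(a$first_cycle_mg),
                  maint_admin_per_cycle = a$maint_admin_per_cycle %||% 0,
                  maint_mg_per_admin = a$maint_mg_per_admin %||% 0,
                  drug_cost_per_cycle = a$drug_cost_per_cycle,
                  admin_cost_per_visit = a$admin_cost_per_visit,
                  monitoring_first_cycle = a$monitoring_first_cycle,
                  monitoring_routine = a$monitoring_routine,
                  ae = ae,
                  subsequent_monthly_cost = a$subsequent_monthly_cost,
                  subsequent_uptake = a$subsequent_uptake,
                  bsc_monthly_cost = a$bsc_monthly_cost)
  })
  economic_inputs(region = x$region, arms = arms,
                  utility_pfs = x$utility_pfs, utility_pd = x$utility_pd,
                  discount_annual = x$discount_annual, wtp = x$wtp,
                  eol_cost = x$eol_cost,
                  currency_divisor = x$currency_divisor,
                  inflation_factor = x$inflation_factor,
                  disutility_duration_months = x$disutility_duration_months)
}
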