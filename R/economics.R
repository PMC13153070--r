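#' Per-arm economic parameters
#'
#' Dosing, administration, monitoring, adverse-event, post-progression
#' and supportive-care inputs for one treatment strategy.  Drug
#' acquisition cost is either computed from a per-mg price and a dosing
#' schedule (first cycle versus maintenance) or supplied as a flat
#' per-cycle cost for regimens standardized to a 1-month equivalent.
#'
#' @param label arm name.
#' @param drug_price_per_mg acquisition price, USD per mg.
#' @param first_cycle_mg vector of per-administration doses (mg) in the
#'   first cycle (e.g. step-up dosing on days 1, 8 and 15).
#' @param maint_admin_per_cycle,maint_mg_per_admin maintenance schedule:
#'   administrations per monthly cycle and mg per administration.
#' @param drug_cost_per_cycle flat per-cycle acquisition cost (overrides
#'   the price/dose computation; used for the chemotherapy arm whose
#'   body-surface-area dosing collapses into a per-cycle unit cost).
#' @param admin_cost_per_visit administration cost per visit.
#' @param monitoring_first_cycle,monitoring_routine monitoring cost in
#'   the first cycle (intensive step-up monitoring where applicable) and
#'   in maintenance cycles.
#' @param ae data.frame of adverse-event items with columns `item`,
#'   `incidence`, `unit_cost`, `disutility`, `class` (one of
#'   `"grade3plus"`, `"crs_g12"`, `"crs_ge3"`).  Grade 1-2 CRS rows are
#'   excluded from costing by default and enabled by scenario.
#' @param subsequent_monthly_cost,subsequent_uptake monthly cost of
#'   subsequent anti-tumour therapy after progression and the proportion
#'   of patients receiving it; the remainder receive best supportive care.
#' @param bsc_monthly_cost monthly cost of best supportive care.
#' @return an object of class `arm_economics`.
#' @export
arm_economics <- function(label,
                          drug_price_per_mg = NULL,
                          first_cycle_mg = NULL,
                          maint_admin_per_cycle = 0,
                          maint_mg_per_admin = 0,
                          drug_cost_per_cycle = NULL,
                          admin_cost_per_visit = 0,
                          monitoring_first_cycle = 0,
                          monitoring_routine = 0,
                          ae = NULL,
                          subsequent_monthly_cost = 0,
                          subsequent_uptake = 0,
                          bsc_monthly_cost = 0) {
  if (is.null(drug_cost_per_cycle) &&
      (is.null(drug_price_per_mg) || is.null(first_cycle_mg)))
    stop("arm_economics: give either 'drug_cost_per_cycle' or a price and dosing schedule")
  if (is.null(ae))
    ae <- data.frame(item = character(0), incidence = numeric(0),
                     unit_cost = numeric(0), disutility = numeric(0),
                     class = character(0))
  stopifnot(all(c("item", "incidence", "unit_cost", "disutility", "class")
                %in% names(ae)))
  costs <- c(drug_price_per_mg %||% 0, drug_cost_per_cycle %||% 0,
             admin_cost_per_visit, monitoring_first_cycle,
             monitoring_routine, ae$unit_cost,
             subsequent_monthly_cost, bsc_monthly_cost)
  if (any(costs < 0)) stop("arm_economics: costs must be >= 0")
  if (any(ae$incidence < 0 | ae$incidence > 1))
    stop("arm_economics: AE incidences must lie in [0, 1]")
  if (subsequent_uptake < 0 || subsequent_uptake > 1)
    stop("arm_economics: 'subsequent_uptake' must lie in [0, 1]")
  structure(list(label = label,
                 drug_price_per_mg = drug_price_per_mg,
                 first_cycle_mg = first_cycle_mg,
                 maint_admin_per_cycle = maint_admin_per_cycle,
                 maint_mg_per_admin = maint_mg_per_admin,
                 drug_cost_per_cycle = drug_cost_per_cycle,
                 admin_cost_per_visit = admin_cost_per_visit,
                 monitoring_first_cycle = monitoring_first_cycle,
                 monitoring_routine = monitoring_routine,
                 ae = ae,
                 subsequent_monthly_cost = subsequent_monthly_cost,
                 subsequent_uptake = subsequent_uptake,
                 bsc_monthly_cost = bsc_monthly_cost),
            class = "arm_economics")
}

#' Economic inputs for a two-strategy comparison
#'
#' @param region `"US"` or `"China"` (free-form labels allowed).
#' @param arms named list of two [arm_economics()] objects.
#' @param utility_pfs,utility_pd health-state utilities (death is 0);
#'   `utility_pfs >= utility_pd` required.
#' @param discount_annual annual discount rate applied to both costs and
#'   effects.
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @param eol_cost one-time end-of-life care cost applied to new deaths.
#' @param currency_divisor exchange-rate divisor applied by
#'   [normalize_costs()] for inputs collected in another currency
#'   (1 when inputs are already USD).
#' @param inflation_factor multiplicative inflation adjustment to the
#'   costing year.
#' @param disutility_duration_months duration weight of one-time
#'   adverse-event disutility decrements, in months.
#' @return an object of class `economic_inputs`.
#' @export
economic_inputs <- function(region, arms, utility_pfs = 0.70,
                            utility_pd = 0.60, discount_annual = 0.03,
                            wtp = 150000, eol_cost = 0,
                            currency_divisor = 1, inflation_factor = 1,
                            disutility_duration_months = 1) {
  stopifnot(is.list(arms), length(arms) == 2L,
            all(vapply(arms, inherits, logical(1), "arm_economics")))
  if (utility_pfs < 0 || utility_pfs > 1 || utility_pd < 0 || utility_pd > 1)
    stop("economic_inputs: utilities must lie in [0, 1]")
  if (utility_pfs < utility_pd)
    stop("economic_inputs: 'utility_pfs' must be >= 'utility_pd'")
  if (discount_annual < 0) stop("economic_inputs: negative discount rate")
  if (eol_cost < 0) stop("economic_inputs: 'eol_cost' must be >= 0")
  if (currency_divisor <= 0 || inflation_factor <= 0)
    stop("economic_inputs: currency divisor and inflation factor must be > 0")
  structure(list(region = region, arms = arms,
                 utility_pfs = utility_pfs, utility_pd = utility_pd,
                 discount_annual = discount_annual, wtp = wtp,
                 eol_cost = eol_cost,
                 currency_divisor = currency_divisor,
                 inflation_factor = inflation_factor,
                 disutility_duration_months = disutility_duration_months),
            class = "economic_inputs")
}

#' Per-cycle state-cost schedule for one arm
#'
#' Applies the time-weighted costing rules: the first cycle carries the
#' step-up dosing (all first-cycle administrations) and intensive
#' monitoring; maintenance cycles carry the normalized monthly dosing and
#' routine monitoring.  Progressed-disease cycles carry the
#' uptake-weighted mix of subsequent therapy and best supportive care.
#' Adverse-event costs and disutilities are one-time cycle-0 items
#' weighted by incidence (per-cycle accruals in recurrent mode); grade
#' 1-2 CRS is excluded unless requested.  End-of-life cost attaches to
#' new deaths at accrual time.
#'
#' @param inputs an [economic_inputs()].
#' @param arm name of the arm in `inputs$arms`.
#' @param n_cycles schedule length.
#' @param recurrent_ae if `TRUE`, adverse-event costs/disutilities accrue
#'   every cycle spent progression-free instead of once.
#' @param include_crs_g12 include grade 1-2 CRS rows in costing.
#' @return an object of class `cost_schedule`.
#' @export
cycle_cost_schedule <- function(inputs, arm, n_cycles,
                                recurrent_ae = FALSE,
                                include_crs_g12 = FALSE) {
  stopifnot(inherits(inputs, "economic_inputs"))
  if (!arm %in% names(inputs$arms))
    stop("cycle_cost_schedule: unknown arm '", arm, "'")
  a <- inputs$arms[[arm]]

  drug <- numeric(n_cycles)
  if (!is.null(a$drug_cost_per_cycle)) {
    drug[] <- a$drug_cost_per_cycle
    n_admin_first <- 1
    n_admin_maint <- 1
  } else {
    drug[1] <- a$drug_price_per_mg * sum(a$first_cycle_mg)
    if (n_cycles > 1)
      drug[-1] <- a$drug_price_per_mg * a$maint_admin_per_cycle *
        a$maint_mg_per_admin
    n_admin_first <- length(a$first_cycle_mg)
    n_admin_maint <- a$maint_admin_per_cycle
  }
  admin <- c(a$admin_cost_per_visit * n_admin_first,
             rep(a$admin_cost_per_visit * n_admin_maint,
                 max(n_cycles - 1, 0)))
  monitoring <- c(a$monitoring_first_cycle,
                  rep(a$monitoring_routine, max(n_cycles - 1, 0)))

  included <- a$ae$class %in% c("grade3plus", "crs_ge3") |
    (include_crs_g12 & a$ae$class == "crs_g12")
  ae_cost <- sum(a$ae$incidence[included] * a$ae$unit_cost[included])
  ae_disutility <- sum(a$ae$incidence[included] * a$ae$disutility[included]) *
    inputs$disutility_duration_months / 12

  pd_cost <- rep(a$subsequent_uptake * a$subsequent_monthly_cost +
                   (1 - a$subsequent_uptake) * a$bsc_monthly_cost, n_cycles)
  pd_subsequent <- rep(a$subsequent_uptake * a$subsequent_monthly_cost,
                       n_cycles)
  pd_bsc <- pd_cost - pd_subsequent

  structure(list(arm = arm, n_cycles = n_cycles,
                 pfs_drug = drug, pfs_admin = admin,
                 pfs_monitoring = monitoring,
                 pd_subsequent = pd_subsequent, pd_bsc = pd_bsc,
                 onetime_cost = if (recurrent_ae) 0 else ae_cost,
                 onetime_disutility = if (recurrent_ae) 0 else ae_disutility,
                 percycle_ae_cost = if (recurrent_ae) ae_cost else 0,
                 percycle_ae_disutility = if (recurrent_ae) ae_disutility else 0,
                 eol_cost = inputs$eol_cost,
                 recurrent_ae = recurrent_ae,
                 include_crs_g12 = include_crs_g12),
            class = "cost_schedule")
}

#' Accrue discounted costs, life-years and QALYs over a cohort trace
#'
#' Cycle `m` contributions are weighted by start-of-cycle occupancy (or
#' the average of start and end when `half_cycle = TRUE`) and discounted
#' by `(1 + r)^(-m/12)`.  Utilities contribute `1/12` of their annual
#' value per monthly cycle; one-time adverse-event disutilities are
#' deducted at cycle 0; end-of-life cost attaches to the fraction newly
#' dead each cycle.
#'
#' @param trace a `cohort_trace`.
#' @param schedule a [cycle_cost_schedule()] for the same arm.
#' @param inputs the [economic_inputs()].
#' @param half_cycle use mid-cycle occupancy for accrual (the trace
#'   itself is never corrected, so trace validation is unaffected).
#' @return an object of class `strategy_result` with `cost`,
#'   `cost_undiscounted`, `ly`, `ly_undiscounted`, `qaly` and a
#'   per-category cost `breakdown`.
#' @export
accrue <- function(trace, schedule, inputs, half_cycle = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(schedule, "cost_schedule"),
            inherits(inputs, "economic_inputs"))
  n_cyc <- nrow(trace) - 1L
  if (schedule$n_cycles < n_cyc)
    stop("accrue: cost schedule shorter than the trace")
  m <- 0:(n_cyc - 1L)
  occ_pfs <- trace$pfs[m + 1L]
  occ_pd <- trace$pd[m + 1L]
  if (half_cycle) {
    occ_pfs <- (occ_pfs + trace$pfs[m + 2L]) / 2
    occ_pd <- (occ_pd + trace$pd[m + 2L]) / 2
  }
  new_death <- trace$new_death[m + 1L]
  disc <- (1 + inputs$discount_annual)^(-m / 12)

  idx <- m + 1L
  cat_disc <- function(x) sum(x * disc)
  drug <- occ_pfs * schedule$pfs_drug[idx]
  admin <- occ_pfs * schedule$pfs_admin[idx]
  monitoring <- occ_pfs * schedule$pfs_monitoring[idx]
  ae <- occ_pfs * schedule$percycle_ae_cost
  ae[1] <- ae[1] + schedule$onetime_cost
  subsequent <- occ_pd * schedule$pd_subsequent[idx]
  bsc <- occ_pd * schedule$pd_bsc[idx]
  eol <- new_death * schedule$eol_cost

  breakdown <- c(drug = cat_disc(drug), administration = cat_disc(admin),
                 monitoring = cat_disc(monitoring), ae = cat_disc(ae),
                 subsequent_therapy = cat_disc(subsequent),
                 bsc = cat_disc(bsc), eol = cat_disc(eol))
  cost_cycle <- drug + admin + monitoring + ae + subsequent + bsc + eol

  alive <- occ_pfs + occ_pd
  qaly_cycle <- (occ_pfs * inputs$utility_pfs +
                   occ_pd * inputs$utility_pd) / 12 -
    occ_pfs * schedule$percycle_ae_disutility
  qaly_cycle[1] <- qaly_cycle[1] - schedule$onetime_disutility

  structure(list(arm = schedule$arm,
                 cost = sum(cost_cycle * disc),
                 cost_undiscounted = sum(cost_cycle),
                 ly = sum(alive / 12 * disc),
                 ly_undiscounted = sum(alive / 12),
                 qaly = sum(qaly_cycle * disc),
                 breakdown = breakdown,
                 half_cycle = half_cycle),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Strategy '%s': cost $%.2f, LY %.4f (undisc. %.4f), QALY %.4f\n",
              x$arm, x$cost, x$ly, x$ly_undiscounted, x$qaly))
  invisible(x)
}

#' Incremental cost-effectiveness of one strategy against another
#'
#' @param a,b `strategy_result` objects (or lists with `cost` and `qaly`):
#'   `a` is the intervention, `b` the comparator.
#' @param wtp willingness-to-pay threshold (USD per QALY); optional.
#' @return an object of class `ce_result` with incremental cost
#'   (`d_cost`), incremental effect (`d_effect`), `icer` (`NA` when the
#'   incremental effect is zero or negative), a `dominance` label
#'   (`"dominant"`, `"dominated"` or `"none"`), and, when `wtp` is given,
#'   the `cost_effective` verdict `icer <= wtp`.
#' @export
icer <- function(a, b, wtp = NULL) {
  d_cost <- a$cost - b$cost
  d_effect <- a$qaly - b$qaly
  dominance <- "none"
  icer_val <- NA_real_
  undefined <- FALSE
  if (d_effect > 0) {
    icer_val <- d_cost / d_effect
    if (d_cost < 0) dominance <- "dominant"
  } else if (d_effect < 0) {
    if (d_cost >= 0) dominance <- "dominated"
    else icer_val <- d_cost / d_effect  # south-west quadrant
  } else {
    undefined <- d_cost != 0
    if (d_cost > 0) dominance <- "dominated"
  }
  cost_effective <- if (is.null(wtp)) NA else {
    if (dominance == "dominant") TRUE
    else if (dominance == "dominated") FALSE
    else if (is.na(icer_val)) !undefined
    else if (d_effect > 0) icer_val <= wtp
    else icer_val > wtp  # less effect, less cost: keep if savings justify
  }
  structure(list(intervention = a, comparator = b,
                 d_cost = d_cost, d_effect = d_effect,
                 icer = icer_val, dominance = dominance,
                 icer_undefined = undefined,
                 wtp = wtp, cost_effective = cost_effective),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Incremental cost-effectiveness\n")
  cat(sprintf("  incremental cost:   $%.2f\n", x$d_cost))
  cat(sprintf("  incremental effect: %.4f QALYs\n", x$d_effect))
  if (x$dominance != "none") cat("  dominance:", x$dominance, "\n")
  if (!is.na(x$icer)) cat(sprintf("  ICER: $%.2f per QALY\n", x$icer))
  if (x$icer_undefined) cat("  ICER undefined (zero incremental effect)\n")
  if (!is.null(x$wtp))
    cat(sprintf("  at WTP $%s per QALY: %s\n",
                format(x$wtp, big.mark = ","),
                if (isTRUE(x$cost_effective)) "cost-effective"
                else "not cost-effective"))
  invisible(x)
}

#' @export
summary.ce_result <- function(object, ...) {
  a <- object$intervention; b <- object$comparator
  df <- data.frame(
    strategy = c(a$arm %||% "intervention", b$arm %||% "comparator"),
    cost = c(a$cost, b$cost),
    ly = c(a$ly %||% NA, b$ly %||% NA),
    qaly = c(a$qaly, b$qaly))
  attr(df, "d_cost") <- object$d_cost
  attr(df, "d_effect") <- object$d_effect
  attr(df, "icer") <- object$icer
  df
}

#' Convert and inflate a cost to analysis-year USD
#'
#' @param raw cost in the source currency and year.
#' @param currency_divisor units of source currency per USD (> 0).
#' @param inflation_factor multiplicative inflation adjustment (> 0).
#' @return `raw * inflation_factor / currency_divisor`.
#' @export
normalize_costs <- function(raw, currency_divisor = 1, inflation_factor = 1) {
  if (currency_divisor <= 0) stop("normalize_costs: 'currency_divisor' must be > 0")
  if (inflation_factor <= 0) stop("normalize_costs: 'inflation_factor' must be > 0")
  raw * inflation_factor / currency_divisor
}
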