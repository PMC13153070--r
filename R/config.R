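#' Load and validate an analysis configuration
#'
#' Reads a YAML configuration, rejects unknown keys, fills region-aware
#' defaults (willingness-to-pay $150,000/QALY and 3% discounting for the
#' US; $40,247.01/QALY — three times per-capita GDP — and 5% for China)
#' and validates every field.
#'
#' Recognized keys: `region`, `wtp`, `horizon_cycles`, `discount_annual`,
#' `master_seed`, `background_mortality_monthly`, `output_dir`,
#' `half_cycle`, `dsa_exploratory`, `psa_iterations`, `price_grid_max`,
#' `scenarios` (named list of scenario override lists), `paths` (named
#' list of input files: `curves`, `risk`, `economics`, `mortality`; all
#' must exist when given), and `fixture` (generator settings:
#' `n_per_arm`, `os_median_tarlatamab`, `os_median_chemo`, `hr_os`,
#' `pfs_median_tarlatamab`, `pfs_median_chemo`, `hr_pfs`,
#' `admin_censor`, `censor_rate`).
#'
#' @param path YAML file path.
#' @return an object of class `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("load_config: parse error in ", path, ": ", conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  known <- c("region", "wtp", "horizon_cycles", "discount_annual",
             "master_seed", "background_mortality_monthly", "output_dir",
             "half_cycle", "dsa_exploratory", "psa_iterations",
             "price_grid_max", "scenarios", "paths", "fixture")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))
  region <- raw$region %||% "US"
  if (!region %in% c("US", "China"))
    stop("load_config: 'region' must be 'US' or 'China'")
  cfg <- list(
    region = region,
    wtp = raw$wtp %||% if (region == "US") 150000 else 40247.01,
    horizon_cycles = raw$horizon_cycles %||% 240L,
    discount_annual = raw$discount_annual %||%
      if (region == "US") 0.03 else 0.05,
    master_seed = raw$master_seed %||% 1L,
    background_mortality_monthly = raw$background_mortality_monthly %||% 0.001,
    output_dir = raw$output_dir %||% "sclcea-output",
    half_cycle = isTRUE(raw$half_cycle),
    dsa_exploratory = isTRUE(raw$dsa_exploratory),
    psa_iterations = raw$psa_iterations %||% 1000L,
    price_grid_max = raw$price_grid_max %||%
      if (region == "US") 2000 else 1567.49,
    scenarios = raw$scenarios %||% list(),
    paths = raw$paths %||% list(),
    fixture = utils::modifyList(list(
      n_per_arm = 254L, os_median_tarlatamab = 13.6, os_median_chemo = 8.3,
      hr_os = 0.60, pfs_median_tarlatamab = 4.2, pfs_median_chemo = 3.7,
      hr_pfs = 0.71, admin_censor = 36, censor_rate = 0.005),
      raw$fixture %||% list()))
  if (cfg$wtp <= 0) stop("load_config: 'wtp' must be > 0")
  if (cfg$horizon_cycles < 1) stop("load_config: 'horizon_cycles' must be >= 1")
  if (cfg$discount_annual < 0) stop("load_config: 'discount_annual' must be >= 0")
  if (cfg$psa_iterations < 1) stop("load_config: 'psa_iterations' must be >= 1")
  for (p in names(cfg$paths))
    if (!file.exists(cfg$paths[[p]]))
      stop("load_config: paths$", p, " does not exist: ", cfg$paths[[p]])
  structure(cfg, class = "analysis_config")
}

# plain deterministic hash of the config for the run manifest
.config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483629
  sprintf("%08x", h)
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

# build the full model from config-driven fixtures: synthetic trial arms,
# reconstruction, six-family fits, AIC-averaged curves
.build_model_from_config <- function(cfg) {
  fx <- cfg$fixture
  grid <- 0:cfg$horizon_cycles
  q_bg <- generate_background_mortality(cfg$background_mortality_monthly,
                                        cfg$horizon_cycles)
  ends <- list(
    list(endpoint = "OS", med = fx$os_median_chemo, hr = fx$hr_os),
    list(endpoint = "PFS", med = fx$pfs_median_chemo, hr = fx$hr_pfs))
  curves <- list(tarlatamab = list(), chemotherapy = list())
  sub <- 0L
  for (e in ends) {
    for (arm in c("chemotherapy", "tarlatamab")) {
      sub <- sub + 1L
      spec <- if (arm == "chemotherapy")
        arm_spec(endpoint = e$endpoint, arm = arm, n = fx$n_per_arm,
                 median = e$med, admin_censor = fx$admin_censor,
                 censor_rate = fx$censor_rate)
      else
        arm_spec(endpoint = e$endpoint, arm = arm, n = fx$n_per_arm,
                 ref_median = e$med, hr = e$hr,
                 admin_censor = fx$admin_censor,
                 censor_rate = fx$censor_rate)
      ipd <- generate_arm_ipd(spec, seed_stream(cfg$master_seed, sub))
      km <- ipd_to_km(ipd)
      rec <- reconstruct_ipd(km$curve, km$risk, arm = arm,
                             endpoint = e$endpoint)
      fits <- fit_all_parametric(rec)
      curves[[arm]][[tolower(e$endpoint)]] <-
        model_average(fits, grid = grid, arm = arm, endpoint = e$endpoint)
    }
  }
  inputs <- generate_economic_fixture(cfg$region, seed = cfg$master_seed)
  inputs$wtp <- cfg$wtp
  inputs$discount_annual <- cfg$discount_annual
  ce_model(curves, q_bg, inputs, horizon = cfg$horizon_cycles,
           half_cycle = cfg$half_cycle)
}

#' Run one pipeline stage and write its artifacts
#'
#' Executes a named stage of the analysis against the configured inputs
#' (all generated from the master seed when no input paths are given) and
#' writes CSV/YAML artifacts, a log and a reproducibility manifest into
#' the output directory.  Stages: `fixture`, `reconstruct`, `fit`,
#' `base-case`, `dsa`, `psa`, `price-sweep`, `threshold`, `subgroup`,
#' `scenario`, `report`.
#'
#' @param config an [load_config()] result (or path to a YAML config).
#' @param subcommand stage name.
#' @return invisibly, a list of the paths written.
#' @export
run_pipeline <- function(config, subcommand = "base-case") {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "analysis_config"))
  stages <- c("fixture", "reconstruct", "fit", "base-case", "dsa", "psa",
              "price-sweep", "threshold", "subgroup", "scenario", "report")
  if (!subcommand %in% stages)
    stop("run_pipeline: unknown subcommand '", subcommand, "'")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(config$output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    out <<- c(out, p)
    p
  }
  emit_yaml <- function(x, name) {
    p <- file.path(config$output_dir, name)
    yaml::write_yaml(x, p)
    out <<- c(out, p)
    p
  }
  log_path <- file.path(config$output_dir, paste0(subcommand, ".log"))
  con <- file(log_path, "w"); on.exit(close(con))
  .log_line(con, "stage ", subcommand, " (seed ", config$master_seed, ")")

  ce_summary <- function(r) list(
    intervention = list(cost = r$intervention$cost, ly = r$intervention$ly,
                        qaly = r$intervention$qaly),
    comparator = list(cost = r$comparator$cost, ly = r$comparator$ly,
                      qaly = r$comparator$qaly),
    incremental_cost = r$d_cost, incremental_effect = r$d_effect,
    icer = r$icer, dominance = r$dominance, wtp = r$wtp,
    cost_effective = r$cost_effective)

  if (subcommand == "fixture") {
    fx <- config$fixture
    spec <- arm_spec(endpoint = "OS", arm = "tarlatamab", n = fx$n_per_arm,
                     ref_median = fx$os_median_chemo, hr = fx$hr_os,
                     admin_censor = fx$admin_censor,
                     censor_rate = fx$censor_rate)
    ipd <- generate_arm_ipd(spec, seed_stream(config$master_seed, 2L))
    km <- ipd_to_km(ipd)
    emit_csv(ipd, "fixture_os_tarlatamab_ipd.csv")
    emit_csv(as.data.frame(km$curve), "fixture_os_tarlatamab_curve.csv")
    emit_csv(as.data.frame(km$risk), "fixture_os_tarlatamab_risk.csv")
    p <- file.path(config$output_dir, "economic_inputs.yaml")
    write_economic_yaml(generate_economic_fixture(config$region,
                                                  config$master_seed), p)
    out <- c(out, p)
  } else if (subcommand %in% c("reconstruct", "fit", "base-case", "dsa",
                               "psa", "price-sweep", "threshold",
                               "subgroup", "scenario")) {
    model <- .build_model_from_config(config)
    .log_line(con, "model built: horizon ", model$horizon, " cycles")
    if (subcommand == "reconstruct") {
      for (arm in names(model$curves))
        emit_csv(data.frame(month = model$curves[[arm]]$os$grid,
                            survival = model$curves[[arm]]$os$surv),
                 paste0("averaged_os_", arm, ".csv"))
    } else if (subcommand == "fit") {
      for (arm in names(model$curves))
        for (ep in c("pfs", "os")) {
          cu <- model$curves[[arm]][[ep]]
          emit_yaml(lapply(seq_along(cu$fits), function(i)
            list(family = cu$fits[[i]]$family, aic = cu$fits[[i]]$aic,
                 bic = cu$fits[[i]]$bic, weight = as.numeric(cu$weights[i]))),
            paste0("fits_", arm, "_", ep, ".yaml"))
        }
    } else if (subcommand == "base-case") {
      r <- evaluate(model)
      emit_yaml(ce_summary(r), "base_case.yaml")
      traces <- ce_traces(model)
      for (arm in names(traces))
        emit_csv(as.data.frame(traces[[arm]]), paste0("trace_", arm, ".csv"))
    } else if (subcommand == "dsa") {
      tor <- one_way_dsa(model, exploratory = config$dsa_exploratory)
      emit_csv(as.data.frame(tor), "tornado.csv")
    } else if (subcommand == "psa") {
      s <- psa(model, n_iter = config$psa_iterations,
               seed = seed_stream(config$master_seed, 101L))
      emit_csv(as.data.frame(s), "psa_samples.csv")
      grid <- seq(0, 4 * config$wtp, length.out = 81)
      emit_csv(ceac(s, grid), "ceac.csv")
    } else if (subcommand == "price-sweep") {
      grid <- seq(0, config$price_grid_max, by = 1)
      emit_csv(price_sweep(model, grid), "price_sweep.csv")
    } else if (subcommand == "threshold") {
      th <- threshold_price(model, config$wtp,
                            upper = config$price_grid_max)
      emit_yaml(list(wtp = th$wtp, price_per_mg = th$price,
                     icer = th$icer, flag = th$flag), "threshold_price.yaml")
    } else if (subcommand == "subgroup") {
      sg <- subgroup_spec("All patients", hr_os = c(0.60, 0.47, 0.77),
                          hr_pfs = c(0.71, 0.59, 0.86))
      r <- subgroup_analysis(model, sg, n_psa = config$psa_iterations)
      emit_yaml(list(label = r$label, icer = r$result$icer,
                     icer_range = as.list(r$icer_range),
                     ce_probability = r$ce_probability),
                "subgroup_all_patients.yaml")
    } else if (subcommand == "scenario") {
      res <- lapply(config$scenarios, function(sc) {
        r <- scenario_run(model, sc)
        ce_summary(r)
      })
      emit_yaml(res, "scenarios.yaml")
    }
  } else if (subcommand == "report") {
    files <- list.files(config$output_dir, pattern = "\\.(csv|yaml)$")
    files <- setdiff(files, "report.yaml")
    emit_yaml(list(artifacts = as.list(files)), "report.yaml")
  }

  manifest <- list(config_hash = .config_hash(config),
                   master_seed = config$master_seed,
                   package_version = as.character(
                     utils::packageVersion("sclcea")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  p <- file.path(config$output_dir, "manifest.yaml")
  yaml::write_yaml(manifest, p)
  .log_line(con, "wrote ", length(out), " artifact(s)")
  invisible(c(out, p, log_path))
}
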