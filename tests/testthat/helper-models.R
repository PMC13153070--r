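# Shared builders for small deterministic fixtures.

# Exponential survival values on a monthly grid, by median.
exp_surv <- function(median, grid = 0:120) exp(-log(2) / median * grid)

# A compact two-arm model with closed-form exponential curves calibrated
# to the trial summary statistics, US economics, and a flat background
# mortality; cheap enough to evaluate hundreds of times in tests.
toy_model <- function(horizon = 120, region = "US", q_bg = 0.001) {
  grid <- 0:horizon
  curves <- list(
    tarlatamab = list(pfs = exp_surv(4.2, grid), os = exp_surv(13.6, grid)),
    chemotherapy = list(pfs = exp_surv(3.7, grid), os = exp_surv(8.3, grid)))
  ce_model(curves, generate_background_mortality(q_bg, horizon),
           generate_economic_fixture(region), horizon = horizon)
}

# A consistent random transition schedule whose PFS death row equals the
# supplied background mortality; running a trace on it and reading the
# curves back off the trace gives clamp-free inputs for derivation tests.
random_schedule_curves <- function(n_cycles, seed, q_bg = 0.002) {
  set.seed(seed)
  pfs_pfs <- runif(n_cycles, 0.7, 0.98)
  pfs_death <- rep(q_bg, n_cycles)
  pfs_pd <- 1 - pfs_pfs - pfs_death
  pd_pd <- runif(n_cycles, 0.5, 0.95)
  sched <- structure(
    data.frame(cycle = 0:(n_cycles - 1), pfs_pfs = pfs_pfs,
               pfs_pd = pfs_pd, pfs_death = pfs_death,
               pd_pd = pd_pd, pd_death = 1 - pd_pd),
    clamp_log = data.frame(), clamp_mass = 0,
    class = c("transition_schedule", "data.frame"))
  trace <- run_trace(sched)
  list(schedule = sched, trace = trace,
       s_pfs = trace$pfs, s_os = trace$pfs + trace$pd,
       q_bg = rep(q_bg, n_cycles))
}

# Brute-force trace: explicit per-cycle transition-matrix products.
matrix_trace <- function(schedule, n_cycles = nrow(schedule)) {
  occ <- c(1, 0, 0)
  out <- matrix(NA_real_, n_cycles + 1, 3)
  out[1, ] <- occ
  for (m in seq_len(n_cycles)) {
    P <- rbind(
      c(schedule$pfs_pfs[m], schedule$pfs_pd[m], schedule$pfs_death[m]),
      c(0, schedule$pd_pd[m], schedule$pd_death[m]),
      c(0, 0, 1))
    occ <- as.numeric(occ %*% P)
    out[m + 1, ] <- occ
  }
  out
}
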