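#' Derive cycle-specific transition probabilities from PFS/OS curves
#'
#' Decomposes a pair of partitioned survival curves into the transition
#' probabilities of a three-state (progression-free / progressed / dead)
#' Markov cohort model with 1-month cycles:
#'
#' * staying progression-free follows the conditional survival of the PFS
#'   curve, `tp_PFS->PFS(m) = S_PFS(m+1) / S_PFS(m)`;
#' * death from the progression-free state is the background mortality
#'   probability (times an optional standardized mortality ratio), so
#'   cancer deaths are not double-counted before progression;
#' * progression is the residual exit probability from PFS;
#' * the probability of remaining progressed is derived algebraically at
#'   each cycle from the net cohort flow required to match the target
#'   prevalence of the progressed state, `P(m) = S_OS(m) - S_PFS(m)`:
#'   `tp_PD->PD(m) = (P(m+1) - occ_PFS(m) * tp_PFS->PD(m)) / P(m)`,
#'   with death from the progressed state as its complement.
#'
#' With this construction and no clamping, the cohort trace reproduces
#' the input curves exactly: trace PFS equals `S_PFS` and trace alive
#' equals `S_OS`.  Every probability is clamped to `[0, 1]` with row sums
#' restored through the death transition; each clamp is logged and the
#' total absolute adjustment reported as `clamp_mass`.
#'
#' @param s_pfs,s_os survival values on the monthly grid `0..T`
#'   (numeric vectors or `averaged_survival` objects of equal length).
#'   Cycles where `s_os < s_pfs` (possible when the curves are fitted
#'   independently) are reconciled by raising `s_os` to `s_pfs`, with a
#'   warning.
#' @param q_bg background-mortality schedule, length at least `T`.
#' @param smr standardized mortality ratio multiplying `q_bg` in the
#'   progression-free state (default 1; the pre-progression-mortality
#'   scenario uses 1.5).
#' @return an object of class `transition_schedule`: a data.frame with
#'   columns `cycle`, `pfs_pfs`, `pfs_pd`, `pfs_death`, `pd_pd`,
#'   `pd_death`, with attributes `clamp_log` and `clamp_mass`.
#' @export
derive_transitions <- function(s_pfs, s_os, q_bg, smr = 1) {
  if (inherits(s_pfs, "averaged_survival")) s_pfs <- s_pfs$surv
  if (inherits(s_os, "averaged_survival")) s_os <- s_os$surv
  if (length(s_pfs) != length(s_os))
    stop("derive_transitions: curve grids differ in length")
  n_cyc <- length(s_pfs) - 1L
  if (length(q_bg) < n_cyc)
    stop("derive_transitions: mortality schedule shorter than the horizon")
  if (smr < 0) stop("derive_transitions: 'smr' must be >= 0")
  zero_idx <- which(s_pfs == 0)
  if (length(zero_idx) && any(s_pfs[seq(min(zero_idx), length(s_pfs))] > 0))
    stop("derive_transitions: S_PFS hits 0 then becomes positive")
  if (any(s_os < s_pfs - 1e-9)) {
    warning("derive_transitions: S_OS < S_PFS on part of the grid; ",
            "raising S_OS to S_PFS")
  }
  s_os <- pmax(s_os, s_pfs)

  clamp_log <- list()
  log_clamp <- function(cycle, name, raw, clamped) {
    if (abs(raw - clamped) < 1e-12) return(invisible())  # floating noise
    clamp_log[[length(clamp_log) + 1L]] <<-
      data.frame(cycle = cycle, transition = name, raw = raw,
                 clamped = clamped, magnitude = abs(raw - clamped))
  }
  clamp01 <- function(x, cycle, name) {
    y <- min(max(x, 0), 1)
    if (y != x) log_clamp(cycle, name, x, y)
    y
  }

  pfs_pfs <- pfs_pd <- pfs_death <- pd_pd <- pd_death <- numeric(n_cyc)
  occ_pfs <- 1
  occ_pd <- 0
  for (m in seq_len(n_cyc)) {
    i <- m  # cycle index m-1 in 0-based terms; curves indexed i (=m), i+1
    cond <- if (s_pfs[i] > 0) s_pfs[i + 1] / s_pfs[i] else 0
    a <- clamp01(cond, m - 1L, "pfs_pfs")
    dth <- clamp01(smr * q_bg[m], m - 1L, "pfs_death")
    if (a + dth > 1) {  # restore row sum through the death transition
      log_clamp(m - 1L, "pfs_death", dth, 1 - a)
      dth <- 1 - a
    }
    pd <- 1 - a - dth
    if (pd < 0) { log_clamp(m - 1L, "pfs_pd", pd, 0); pd <- 0 }
    pfs_pfs[m] <- a; pfs_death[m] <- dth; pfs_pd[m] <- pd

    p_now <- s_os[i] - s_pfs[i]        # target PD prevalence this cycle
    p_next <- s_os[i + 1] - s_pfs[i + 1]
    inflow <- occ_pfs * pd
    if (p_now > 0) {
      stay <- clamp01((p_next - inflow) / p_now, m - 1L, "pd_pd")
    } else {
      # empty PD state: the stay probability is irrelevant to the trace,
      # but an inflow that misses the target prevalence is unachievable
      # and is logged as a flow clamp
      stay <- 0
      if (abs(p_next - inflow) > 1e-12)
        log_clamp(m - 1L, "pd_inflow", inflow, p_next)
    }
    pd_pd[m] <- stay
    pd_death[m] <- 1 - stay

    occ_pd <- occ_pd * stay + inflow
    occ_pfs <- occ_pfs * a
  }

  clamp_log <- if (length(clamp_log)) do.call(rbind, clamp_log)
    else data.frame(cycle = integer(0), transition = character(0),
                    raw = numeric(0), clamped = numeric(0),
                    magnitude = numeric(0))
  structure(data.frame(cycle = 0:(n_cyc - 1L),
                       pfs_pfs = pfs_pfs, pfs_pd = pfs_pd,
                       pfs_death = pfs_death,
                       pd_pd = pd_pd, pd_death = pd_death),
            clamp_log = clamp_log,
            clamp_mass = sum(clamp_log$magnitude),
            class = c("transition_schedule", "data.frame"))
}

#' Run the three-state Markov cohort trace
#'
#' Starts the whole cohort progression-free, `(1, 0, 0)`, and applies the
#' cycle-specific transition schedule.  Occupancy is read at cycle start;
#' no half-cycle correction is applied here so the trace can be validated
#' directly against the input survival curves.
#'
#' @param schedule a `transition_schedule`.
#' @param n_cycles number of cycles to run (defaults to the schedule
#'   length, which must be at least `n_cycles`).
#' @return an object of class `cohort_trace`: a data.frame with columns
#'   `cycle` (0..T), `pfs`, `pd`, `death`, and `new_death` (deaths during
#'   the cycle starting at that row's cycle; `NA` in the final row).
#' @export
run_trace <- function(schedule, n_cycles = nrow(schedule)) {
  stopifnot(inherits(schedule, "transition_schedule"))
  if (n_cycles > nrow(schedule))
    stop("run_trace: schedule shorter than requested horizon")
  occ <- matrix(0, nrow = n_cycles + 1L, ncol = 3,
                dimnames = list(NULL, c("pfs", "pd", "death")))
  occ[1, ] <- c(1, 0, 0)
  for (m in seq_len(n_cycles)) {
    p <- occ[m, ]
    occ[m + 1L, "pfs"] <- p["pfs"] * schedule$pfs_pfs[m]
    occ[m + 1L, "pd"] <- p["pfs"] * schedule$pfs_pd[m] +
      p["pd"] * schedule$pd_pd[m]
    occ[m + 1L, "death"] <- p["death"] +
      p["pfs"] * schedule$pfs_death[m] + p["pd"] * schedule$pd_death[m]
  }
  new_death <- c(diff(occ[, "death"]), NA_real_)
  structure(data.frame(cycle = 0:n_cycles, pfs = occ[, "pfs"],
                       pd = occ[, "pd"], death = occ[, "death"],
                       new_death = new_death),
            class = c("cohort_trace", "data.frame"))
}

#' Validate a cohort trace against its source survival curves
#'
#' Overlays the trace on the curves it was derived from and reports the
#' maximum absolute deviation of (a) the progression-free occupancy from
#' `S_PFS` and (b) the alive proportion (PFS + PD) from `S_OS`, together
#' with the cycles where they occur.  For a clamp-free schedule both are
#' at floating-point noise level.
#'
#' @param trace a `cohort_trace`.
#' @param s_pfs,s_os the source curves (vectors or `averaged_survival`).
#' @return list with `max_dev_pfs`, `cycle_pfs`, `max_dev_os`, `cycle_os`.
#' @export
validate_trace <- function(trace, s_pfs, s_os) {
  if (inherits(s_pfs, "averaged_survival")) s_pfs <- s_pfs$surv
  if (inherits(s_os, "averaged_survival")) s_os <- s_os$surv
  if (length(s_pfs) != nrow(trace) || length(s_os) != nrow(trace))
    stop("validate_trace: grid lengths do not match the trace")
  dev_pfs <- abs(trace$pfs - s_pfs)
  dev_os <- abs(trace$pfs + trace$pd - s_os)
  list(max_dev_pfs = max(dev_pfs), cycle_pfs = trace$cycle[which.max(dev_pfs)],
       max_dev_os = max(dev_os), cycle_os = trace$cycle[which.max(dev_os)])
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf("Transition schedule: %d cycles, clamp mass %.3g (%d clamps)\n",
              nrow(x), attr(x, "clamp_mass"), nrow(attr(x, "clamp_log"))))
  print.data.frame(utils::head(x, 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace over %d cycles; final occupancy PFS %.4f, PD %.4f, dead %.4f\n",
              nrow(x) - 1L, x$pfs[nrow(x)], x$pd[nrow(x)], x$death[nrow(x)]))
  invisible(x)
}
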