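---
title: "Model and methods: Markov cost-effectiveness of second-line tarlatamab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: Markov cost-effectiveness of second-line tarlatamab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The decision problem

Patients with small-cell lung cancer who relapse after platinum-based
chemotherapy have few options and short survival. Tarlatamab, a
DLL3-targeted bispecific T-cell engager, extends overall survival relative
to second-line chemotherapy (reported medians 13.6 versus 8.3 months,
hazard ratio 0.60; progression-free survival 4.2 versus 3.7 months, hazard
ratio 0.71), but at a high acquisition price. `sclcea` implements a payer-
perspective cost-utility comparison of the two strategies for the United
States and China, together with the uncertainty machinery a health-
technology assessment requires: one-way and probabilistic sensitivity
analysis, acceptability curves, value-based price thresholds, subgroup
hazard-ratio adjustment, and structural scenario analysis.

Because the trial's digitized survival coordinates and the supplementary
cost tables are not published, every input can be produced by the package's
own synthetic-fixture generators, calibrated to the printed summary
statistics. The pipeline is therefore fully testable end-to-end; the
absolute cost-effectiveness results it produces on synthetic fixtures are
structurally faithful but not a reproduction of the source analysis.

# Pipeline overview

1. **Synthetic trial data** (`arm_spec()`, `generate_arm_ipd()`): event
   times per arm/endpoint from an exponential (default) or Weibull
   distribution. A non-reference arm is generated through the
   proportional-hazards power transform `S(t) = S_ref(t)^HR`, so the
   hazard ratio holds exactly by construction and a Cox fit is a valid
   recovery oracle. Censoring is independent exponential plus an
   administrative cutoff.
2. **Digitized-curve emulation** (`ipd_to_km()`): Kaplan–Meier step
   coordinates plus a number-at-risk table — the same format a curve
   digitizer would produce from a published figure.
3. **Pseudo-IPD reconstruction** (`reconstruct_ipd()`): inversion of the
   product-limit estimator from coordinates and risk counts, in the style
   of the standard published reconstruction algorithm.
4. **Parametric extrapolation** (`fit_parametric()`, `aic_weights()`,
   `model_average()`): six families — exponential, Weibull, Gompertz,
   log-logistic, log-normal, generalized gamma — fitted by maximum
   likelihood under right censoring, scored by AIC/BIC, and combined by
   Akaike weights `w_i ∝ exp(−ΔAIC_i/2)` into a model-averaged survival
   function on a monthly grid. Averaging across families represents
   structural extrapolation uncertainty without committing to one shape.
5. **Markov engine** (`derive_transitions()`, `run_trace()`,
   `validate_trace()`): a three-state cohort model (progression-free /
   progressed / dead) with 1-month cycles.
6. **Economics** (`cycle_cost_schedule()`, `accrue()`, `icer()`):
   discounted costs, life-years and QALYs, and the incremental comparison.
7. **Uncertainty** (`one_way_dsa()`, `psa()`, `ceac()`, `price_sweep()`,
   `threshold_price()`, `subgroup_analysis()`, `scenario_run()`), all over
   the single deterministic evaluator `evaluate()`.

# The transition algebra

The engine decomposes the two partitioned survival curves into
cycle-specific transition probabilities:

* `tp_PFS→PFS(m) = S_PFS(m+1)/S_PFS(m)` — conditional survival of the
  progression-free curve;
* `tp_PFS→death(m) = SMR · q_bg(m)` — background mortality only, to avoid
  double-counting cancer deaths before progression (the standardized
  mortality ratio defaults to 1);
* `tp_PFS→PD(m)` — the residual exit probability;
* the progressed state is steered to its target prevalence
  `P(m) = S_OS(m) − S_PFS(m)`:
  `tp_PD→PD(m) = (P(m+1) − occ_PFS(m)·tp_PFS→PD(m)) / P(m)`, with
  `tp_PD→death` its complement.

Every probability is clamped to `[0, 1]`; after a clamp the row sum is
restored through the death transition, and each intervention is logged
with its magnitude (summarised as a "clamp mass"). Two degenerate
situations deserve note. When `P(m) = 0` the staying probability is
irrelevant to the trace and set to 0; if, in that situation, the
progression inflow misses the target prevalence, no transition value can
reconcile the curves — a three-state model whose pre-progression deaths
are background-only cannot kill progressors within their progression
cycle — and the mismatch is recorded as a clamp event. With that
convention the following holds as an identity, and is tested at
tolerance `1e-10`: *if no clamp events are logged, the trace's
progression-free occupancy equals `S_PFS` and its alive proportion equals
`S_OS` exactly*. Occupancies are additionally asserted to conserve mass
to `1e-12` at every cycle. Independently fitted curves that cross
(`S_OS < S_PFS`) are reconciled by raising OS to PFS, with a warning.

The trace itself applies no half-cycle correction — otherwise it could
not be validated against the input curves. A half-cycle switch exists at
the accrual stage only (`half_cycle = TRUE` averages start- and
end-of-cycle occupancy).

# Costing rules

The first tarlatamab cycle carries three administrations (1 mg on day 1,
then 10 mg on days 8 and 15) and intensive step-up monitoring; maintenance
cycles are normalized to two 10-mg administrations with routine
monitoring. Chemotherapy is standardized to one administration block per
month with a flat per-cycle acquisition cost (body-surface-area dosing is
collapsed into that unit cost at fixture level). Treatment costs accrue
while progression-free (treat-to-progression). Progressed-state cycles
carry an uptake-weighted mix of subsequent therapy and best supportive
care; a one-time end-of-life cost attaches to each cycle's new deaths.

Adverse events with grade ≥3 incidence ≥5%, and cytokine release
syndrome stratified into grade 1–2 (outpatient) versus grade ≥3
(inpatient plus tocilizumab), enter as one-time cycle-0 cost and QALY
decrements weighted by incidence. Grade 1–2 CRS is excluded from costing
by default and enabled by scenario. Disutility decrements use a duration
weight of 1 month (`disutility_duration_months`), since the source
describes one-time decrements without a duration. A recurrent-AE scenario
converts all one-time items to per-cycle accruals while progression-free.

Utilities are 0.70 (progression-free), 0.60 (progressed), 0 (dead).
Costs and effects are discounted at `(1+r)^(−m/12)` with r = 3% (US) or
5% (China). Costs in other currencies normalize through
`normalize_costs()` (divisor 7.1371 RMB/USD at fixture level, with a
multiplicative inflation factor).

# Uncertainty machinery

* **DSA**: each economic parameter is varied one at a time, ±20% by
  default (±50% in exploratory mode), with probabilities and utilities
  clamped to valid supports and the progressed-state utility capped at
  the progression-free utility so every probed model is well-formed.
  The intervention's per-mg price is excluded — its influence is examined
  by the dedicated price simulation. Entries are ranked by ICER span.
* **PSA** (default 1,000 iterations): gamma draws for costs and beta
  draws for probabilities/utilities, moment-matched to mean = base value
  and SE = 20% of base; infeasible beta moments fall back to a ±20%
  uniform with a warning; utility ordering is preserved draw-wise.
  Survival-curve (structural) uncertainty is deliberately left to the
  scenario analysis, and the intervention price and discount rate are
  held fixed, so acceptability curves refer to a stated price. A
  zero-variance PSA reproduces the base case exactly (tested).
* **CEAC**: the probability of cost-effectiveness at threshold λ is the
  fraction of draws with non-negative net monetary benefit
  `λ·ΔE − ΔC ≥ 0`, which stays well defined for dominated draws.
* **Price machinery**: `price_sweep()` asserts ICER monotonicity in
  price; `threshold_price()` bisects to $0.01/mg, returning flags rather
  than errors when the threshold is unattainable within the bracket.
* **Subgroups**: the comparator arm is held fixed; the intervention
  subgroup curves are `S_comp^HR` per endpoint. Hazard-ratio confidence
  bounds give an ICER range (dominance is reported as a flag when an
  upper bound reaches 1), and the cost-effectiveness probability comes
  from a PSA seeded deterministically from the subgroup label.
* **Scenarios**: single-family extrapolation (any of the six members, in
  place of the averaged curve), SMR 1.5 on pre-progression background
  mortality, recurrent adverse events, grade 1–2 CRS costing, and 60- or
  120-cycle horizons. An empty scenario is bit-identical to the base case.

# Numerical and design choices

* **Reconstruction rounding**: implied fractional event counts are
  integerized by remainder-carrying (half-up) cascade rounding, which
  preserves interval totals exactly; the iterative censor-count search
  keeps the candidate with the smallest residual when integer rounding
  makes the match oscillate, and adopts the implied count when the
  residual is small (digitization noise); a residual above max(3, 2% of
  n) raises an error naming the interval. Ties between events and
  censorings at one time put events first. A reported total event count
  is honoured by proportional rescaling before rounding. Without a risk
  table, zero censoring before last follow-up is assumed.
* **Optimization**: parametric likelihoods are maximized by
  `flexsurv::flexsurvreg`; on non-convergence the fit is retried from up
  to five jittered starting values seeded from an exponential baseline
  fit (Gompertz and generalized-gamma likelihoods can be awkward on small
  samples). The generalized gamma uses the log-time
  (location, scale, shape) form; the Gompertz rate parameter may be
  negative.
* **Grids**: survival is evaluated at integer months `0..horizon` with no
  interpolation; the default horizon is 240 cycles (20 years), beyond
  which residual survival in this disease is negligible.
* **Seeds**: every stochastic component draws its seed from a single
  master seed through `seed_stream()`, so partial reruns reproduce the
  values they had inside a full run; subgroup PSAs hash the subgroup
  label into a seed.

# What the synthetic fixtures do and do not show

The generators reproduce the *statistical structure* of the trial —
sample sizes (254 per arm), medians, hazard ratios, administrative
censoring — under the simplest family consistent with the printed
summaries (exponential by default; Weibull shape is an exposed knob).
They do not reproduce the true curve shapes, the censoring pattern
(unpublished; defaults: administrative cutoff at 36 months, random
censoring 0.005/month, both config-exposed), or the supplementary cost
tables, whose entries are synthetic stand-ins around the printed
conventions (one-third US price in China, $150,000 and $40,247.01
willingness-to-pay, 3%/5% discounting, step-up dosing). Passing tests
therefore demonstrate internal validity — round-trip reconstruction
accuracy, trace fidelity, estimator recovery of the calibration targets,
determinism — not agreement with the source analysis's headline ICERs,
which depend on inputs that are not printed. Problem sizes used by the
test-suite recovery checks are 500 replicates of n = 254 for the median
and hazard-ratio targets, n = 200 for reconstruction round-trips, and
n = 1000 for parameter recovery.

# Known limitations

* No spline or flexible-hazard extrapolation, and no formal
  proportional-hazards testing (summary hazard ratios are taken as
  given).
* The three-state structure cannot represent deaths among within-cycle
  progressors, which is exactly the first-cycle mismatch the clamp log
  surfaces; with monthly cycles the effect is small.
* The economic fixture is one plausible parameterization, not a
  jurisdictional costing study; absolute results on fixtures should be
  read as demonstrations of the machinery.
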