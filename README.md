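# sclcea

Markov cost-effectiveness modelling of tarlatamab versus chemotherapy for
small-cell lung cancer relapsing after platinum-based therapy, from United
States and Chinese payer perspectives.

Second-line tarlatamab extends overall survival (reported medians 13.6 vs
8.3 months, HR 0.60) at a high acquisition price. For analysts in health
technology assessment, `sclcea` provides the complete pipeline such an
evaluation needs, driven entirely by code (synthetic fixtures stand in for
unpublished trial curves and cost tables, so every stage is testable):

- **Pseudo-IPD reconstruction** — inverts the Kaplan–Meier estimator from
  digitized step coordinates `(t, S(t))` and number-at-risk tables.
- **Parametric extrapolation with model averaging** — exponential,
  Weibull, Gompertz, log-logistic, log-normal and generalized-gamma fits
  under right censoring, combined with Akaike weights
  `w_i ∝ exp(−ΔAIC_i / 2)` into `S̄(t) = Σ w_i S_i(t)`.
- **Three-state Markov cohort model** (progression-free → progressed →
  dead; 1-month cycles) whose transition probabilities are derived
  algebraically from the partitioned survival curves:
  `tp_PFS→PFS = S_PFS(m+1)/S_PFS(m)`, `tp_PFS→death = SMR·q_bg`,
  progression as the residual, and the progressed state steered to its
  target prevalence `P(m) = S_OS(m) − S_PFS(m)` so that a clamp-free
  trace reproduces the input curves to numerical noise.
- **Economic accrual** — step-up versus maintenance dosing, monitoring,
  one-time adverse-event and CRS costs/disutilities, subsequent therapy
  versus best supportive care after progression, end-of-life cost,
  discounting at `(1+r)^(−m/12)`, utilities 0.70/0.60/0.
- **Uncertainty machinery** — tornado-ordered one-way DSA, probabilistic
  SA (gamma costs, beta probabilities/utilities), acceptability curves by
  the net-monetary-benefit rule, monotone price sweeps with bisection
  threshold-price search, subgroup hazard-ratio adjustment
  (`S_sub = S_comp^HR`), and structural scenarios.

## Worked example

Generate a synthetic tarlatamab overall-survival arm calibrated to the
trial summaries, digitize it, reconstruct pseudo-IPD, and average the six
parametric fits:

```r
library(sclcea)
spec <- arm_spec("OS", "tarlatamab", n = 254, ref_median = 8.3, hr = 0.60,
                 admin_censor = 36, censor_rate = 0.005)
ipd  <- generate_arm_ipd(spec, seed = 1)
km   <- ipd_to_km(ipd)                     # step coordinates + risk table
rec  <- reconstruct_ipd(km$curve, km$risk) # pseudo-IPD, 254 subjects
fits <- fit_all_parametric(rec)
model_average(fits, grid = 0:240, arm = "tarlatamab", endpoint = "OS")
#> Model-averaged survival(tarlatamab OS)
#>   grid: 0..240 months
#>   members:
#>     exponential        w = 0.0844  AIC = 1695.40
#>     weibull            w = 0.3375  AIC = 1692.63
#>     gompertz           w = 0.4182  AIC = 1692.20
#>     log-logistic       w = 0.0000  AIC = 1711.29
#>     log-normal         w = 0.0000  AIC = 1724.35
#>     generalized-gamma  w = 0.1599  AIC = 1694.12
#>   median: 14 months
```

The weights say the Weibull and Gompertz shapes fit this replicate best;
the averaged curve's 14-month median sits near the 13.83-month generating
median (8.3/0.60 under the exact proportional-hazards construction).

The configured pipeline runs end-to-end from one master seed:

```r
writeLines(c("region: US", "master_seed: 1", "horizon_cycles: 240",
             "output_dir: demo"), "analysis.yaml")
run_pipeline(load_config("analysis.yaml"), "base-case")
yaml::read_yaml("demo/base_case.yaml")
#> $intervention   cost 307258.4  ly 1.499  qaly 0.959
#> $comparator     cost 101676.5  ly 1.103  qaly 0.694
#> $incremental_cost    205581.8
#> $incremental_effect  0.265
#> $icer                775809.9
#> $cost_effective      FALSE
```

On this synthetic fixture tarlatamab buys 0.265 QALYs at an ICER of about
$776k/QALY — far above the $150,000/QALY willingness-to-pay, echoing the
qualitative conclusion of the source analysis (absolute values differ
because the fixture's cost tables are synthetic). Other stages (`"dsa"`,
`"psa"`, `"price-sweep"`, `"threshold"`, `"subgroup"`, `"scenario"`,
`"report"`) write their artifacts the same way, and
`threshold_price(model, 150000)` returns the per-mg price at which the
verdict flips.

See `vignettes/cost-effectiveness-model.Rmd` for the model, its
assumptions, and every numerical choice.

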