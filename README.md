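# cmrctsim

Simulation and analysis tools for treatment refusal in individually
randomised **trials within cohorts** (cohort multiple randomised controlled
trials, cmRCT) with time-to-event outcomes.

In a cmRCT, a consented observational cohort is the sampling frame: a
random subset of eligible patients is *offered* an intervention; the rest
stay on standard of care and are followed through routine records. Only
the intervention arm can refuse treatment. When refusal is correlated with
a patient's underlying event risk, the usual analyses disagree:
intention-to-treat (ITT) is diluted towards the null, per-protocol (PP) is
confounded by the selective exclusion of refusers, and instrumental-variable
(IV) estimators trade bias for precision. `cmrctsim` is a laboratory for
quantifying those trade-offs and for sizing such trials realistically.

## The model

Each individual $i$ carries a frailty $\varepsilon_i \sim N(0, \sigma^2)$
shared by two Weibull proportional-hazards processes — time to the event of
interest and time to competing mortality:

$$H_c(t) = (t/\lambda_c)^{\gamma_c} e^{\beta X_i + \varepsilon_i}, \qquad
  H_m(t) = (t/\lambda_m)^{\gamma_m} e^{\varepsilon_i},$$

with administrative censoring at $T^{max}$, so the observed data are
$\{Y_i = \min(T_{ic}, T_{im}, T^{max}),\ C_i,\ Z_i,\ X_i\}$ — time,
censoring indicator, allocation, treatment received. Death censors the
event *informatively* through the shared frailty. Individual refusal
probabilities are laid on an equally spaced grid with mean $p$ and a
spread set by a correlation level (zero/low/medium/high), assigned in
frailty order, so the strength of the risk–refusal association is dialled
while the average refusal rate stays fixed. Four estimators — ITT, PP,
two-stage predictor substitution (2SPS) and two-stage residual inclusion
(2SRI) — are Cox model fits differing only in covariates and row
inclusion.

Defaults: $\lambda_c=36$, $\gamma_c=1.2$, $\lambda_m=55$, $\gamma_m=1.2$,
$\sigma=0.7$, $\beta=-0.32$ (about a 25% average reduction in ten-year
risk), $T^{max}=3$ years, 4:1 control:intervention allocation.

## Worked example

Simulate one trial with 20% average refusal, strongly positively
correlated with risk, and analyse it four ways:

```r
library(cmrctsim)
tr <- simulate_trial(cmrct_params(),
        cmrct_scenario(refusal_spec(p = 0.2, level = "high"),
                       n_obs = 10300, seed = 1))
cmrct_analyze(tr)
#> cmRCT analysis of one trial (n = 10300, intervention-arm uptake = 0.798)
#>  method estimate     se p_value n_used
#>     ITT  -0.1980 0.1072  0.0648  10300
#>      PP  -0.3131 0.1237  0.0114   9883
#>    2SPS  -0.2483 0.1344  0.0648  10300
#>    2SRI  -0.2710 0.1363  0.0468  10300
```

One trial is noisy; the replicate-level view shows the systematic picture
(true $\beta = -0.32$):

```r
scn <- cmrct_scenario(refusal_spec(p = 0.2, level = "high"),
                      n_obs = 10300, n_sim = 200, seed = 1)
run_scenario(cmrct_params(), scn)
#> cmRCT scenario result: p = 0.2 (high, positive), q = 0, without_refusal, n_obs = 10300, n_sim = 200
#>  method n_sim mean_estimate rel_bias_pct power empirical_se mc_se_of_mean
#>     ITT   200       -0.2219       -30.67 0.570       0.1176      0.008316
#>      PP   200       -0.4216        31.74 0.880       0.1441      0.010190
#>    2SPS   200       -0.2772       -13.36 0.570       0.1465      0.010360
#>    2SRI   200       -0.3410         6.55 0.695       0.1554      0.010990
```

ITT underestimates the effect by ~31% (dilution plus the risk makeup of
the refusers), PP overestimates by a similar magnitude (it drops the
high-risk refusers from the intervention arm only), while the IV methods
stay within ~13% (2SPS) and ~7% (2SRI) of the truth at the cost of larger
standard errors — 2SPS shares ITT's p-value exactly, so also its power.
`required_sample_size()` sizes a trial by simulation under recruitment
with or without expected refusal, `run_grid()` sweeps whole scenario
grids, and `inst/scripts/cmrctsim` exposes `simulate`, `analyze`, `power`,
`samplesize` and `grid` subcommands for shell use. The methods vignette
(`vignettes/refusal-bias-methods.Rmd`) documents the model, the estimators
and every numerical design choice.

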