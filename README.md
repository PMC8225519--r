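# uratesim

Simulation and population estimation for a semi-mechanistic model of serum
and urinary uric acid under treatment with the URAT1 inhibitor verinurad,
xanthine-oxidase inhibitors (XOIs: febuxostat, or allopurinol via its
active metabolite oxypurinol), or their combination.

Hyperuricemia is treated either by blocking uric acid production (XOIs) or
by blocking its renal reabsorption (URAT1 inhibitors, which raise the
fractional excretion of uric acid, FEUA). Combining the two lowers serum
uric acid (sUA) more than either drug alone while keeping the urinary
excretion rate — the safety-relevant quantity, since urate surges can
crystallise in renal tubules — near its untreated level. This package
implements the quantitative machinery needed to reason about that
trade-off.

## The model

Uric acid mass balance in a single systemic compartment (amount `A1`, mg;
volume `V1`, L; concentration `C_UA = A1/V1`, mg/L):

    dA1/dt = k_in (1 − Emax_X C_X/(EC50_X + C_X))   # production, XOI-inhibited
             − CL_I C_UA                            # intestinal elimination
             − eGFR · C_UA · FEUA_eff               # renal excretion
    dA2/dt = eGFR · C_UA · FEUA_eff                 # cumulative urine amount
    FEUA_eff = FEUA + Emax_V C_V/(EC50_V + C_V)     # URAT1 inhibition
    A1(0) = V1 k_in / (CL_I + eGFR·FEUA)            # drug-free steady state

eGFR enters as a filtration flow (0.06 L/h per mL/min/1.73 m²). On top of
the structural core sit multiplicative covariate models (hyperuricemia
status and Asian race on FEUA; gout on verinurad EC50), correlated
lognormal between-subject variability, additive/combined residual error
models, analytic two-compartment exposure drivers, clinical-trial
simulation with variability and with parameter uncertainty, and
Laplace-approximation nonlinear mixed-effects estimation with empirical
Bayes estimates and visual-predictive-check summaries. A virtual-study
generator produces NONMEM-style longitudinal CSV datasets with a truth
sidecar, so the whole pipeline is testable without clinical data.

## A worked example

```r
library(uratesim)

# typical asymptomatic hyperuricemic patient, eGFR 60 mL/min/1.73 m^2
pop  <- ua_params()
cov  <- subject_covariates(egfr = 60, status = "asymptomatic")
pat  <- apply_covariates(pop, cov)
100 * pat$feua                       # baseline FEUA, percent
#> [1] 7.700094
steady_state_sua(pat, renal_context(60))   # baseline sUA, mg/dL
#> [1] 8.679561

# one week of 12 mg verinurad QD + 80 mg febuxostat QD, 500 subjects
sp <- scenario_spec(
  regimens = list(dose_regimen("verinurad_ER8", 12, n_doses = 8),
                  dose_regimen("febuxostat", 80, n_doses = 8)),
  n_subjects = 500, seed = 11)
s <- simulate_with_variability(sp)
s$endpoints
#>            endpoint       q05      q50      q95
#> 1 max_sua_reduction 84.950681 93.14475 97.39037
#> 2      avg_feua_24h 33.651135 48.79347 64.36564
#> 3    max_renal_rate  7.227542 17.58376 34.97848
#> 4     baseline_rate 11.657074 24.30099 46.58903
```

Read: the combination reduces sUA by a median 93% from baseline, the
effective FEUA averages ~49% over the steady-state day (baseline 7.7%),
and the per-subject maximum urinary excretion rate at steady state (median
17.6 mg/h) stays below the untreated baseline band (median 24.3, 95th
quantile ~47 mg/h) — the XOI absorbs the urinary load that URAT1
inhibition alone would push above baseline.

Generate a virtual study and re-estimate its parameters:

```r
des <- design_from_template("combo_phase2a")
dat <- generate_virtual_study(des, seed = 1)
fit <- fit_population(dat, fit_spec())
fit$estimates
```

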