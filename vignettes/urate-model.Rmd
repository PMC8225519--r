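---
title: "A semi-mechanistic uric acid turnover model for URAT1 inhibitor / XOI combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-mechanistic uric acid turnover model for URAT1 inhibitor / XOI combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uratesim)
```

## The model

Serum uric acid (sUA) is treated as a single well-stirred compartment with
amount $A_1$ (mg) and volume $V_1$ (L). Three processes move urate:

* **Production** at rate $k_{in}$ (mg/h), catalysed by xanthine oxidase.
  A xanthine-oxidase inhibitor (XOI; febuxostat, or allopurinol acting
  through its metabolite oxypurinol) inhibits production through a
  saturable function
  $R_P = k_{in}\,\bigl(1 - E_{max} C_X /(EC_{50} + C_X)\bigr)$,
  with drug-specific $E_{max}$ and $EC_{50}$.
* **Intestinal elimination**, first order in the serum concentration
  $C_{UA} = A_1/V_1$ (mg/L): $R_I = CL_I\, C_{UA}$.
* **Renal excretion**: urate is freely filtered at the glomerulus (filtered
  load $= eGFR \cdot C_{UA}$, with eGFR expressed as a flow in L/h at
  0.06 L/h per mL/min/1.73 m²) and mostly reabsorbed in the proximal
  tubule by the URAT1 transporter. The fraction escaping reabsorption is
  the fractional excretion of uric acid, FEUA. Verinurad, a URAT1
  inhibitor, raises the effective FEUA through a second Emax model, so
  $R_R = eGFR\cdot C_{UA}\cdot\bigl(FEUA + E_{max,V} C_V/(EC_{50,V}+C_V)\bigr)$.

The cumulative amount excreted into urine, $A_2$ (mg), integrates $R_R$,
and interval urine collections are modelled as $A_2(t_{end}) -
A_2(t_{start})$. The system starts at the drug-free steady state
$A_1(0) = V_1 k_{in} / (CL_I + eGFR\cdot FEUA)$, which also yields the
closed-form baseline concentration used throughout
(`steady_state_sua()`). The two unit conventions to keep in mind: all
internal concentrations are mg/L, every user-facing sUA value is mg/dL
(mg/L divided by ten); drug concentrations are ng/mL.

The default parameters (`ua_params()`) are the published typical values of
the integrated verinurad/XOI model: $k_{in}$ 43.78 mg/h, healthy FEUA
0.0906, $CL_I$ 0.2272 L/h, $V_1$ 14.11 L, verinurad/febuxostat/oxypurinol
$EC_{50}$ 29.40 / 128.0 / 13030 ng/mL. The three maximum effects are fixed
quantities, not estimates: verinurad's maximum FEUA increase (0.7) comes
from the fractional excretion seen with inactivating URAT1 mutations, and
the XOI maxima (1.0, 0.84) were carried over from the earlier lesinurad
model of the same system.

## Covariates and between-subject variability

Baseline FEUA is multiplied by $(1 + HYPERFEUA)$ for hyperuricemic status
(−0.1501 asymptomatic, −0.3787 symptomatic/gout) and by $(1 + ASIANFEUA)$
(−0.2322) for Asian subjects; verinurad $EC_{50}$ gains $(1 + 0.2677)$ in
gout patients. The resulting strata — healthy 9.1%, asymptomatic 7.7%,
symptomatic 5.6%, Asian symptomatic 4.3%, gout $EC_{50}$ 37.3 ng/mL — are
exact arithmetic consequences that the test-suite pins down.

Between-subject variability is lognormal, $\theta_i = \theta_{pop}
e^{\eta}$, with the production-rate and FEUA effects drawn jointly
(correlation 0.76) and independent effects on each dosed drug's
$EC_{50}$. Table CVs are converted with the exact lognormal relation
$\omega = \sqrt{\log(1 + CV^2)}$; the source material reports "CV%"
without stating a convention, so the exact transform was chosen for
self-consistency (the small-CV approximation is available via
`exact_transform = FALSE`; the difference is below 5% at these CVs).
Covariate models apply **before** the random effect, so the stratum median
equals the covariate-adjusted typical value. Residual error is additive
for serum (0.4107 mg/dL; one study has a documented alternative of 0.9524)
and combined additive + proportional for urine interval amounts (3.054 mg,
0.3806).

## Exposure drivers

The published popPK parameter estimates live in supplementary material
that is not publicly available, so `default_pk_catalog()` ships documented
stand-ins with the *structural* forms reported for each drug: two
compartment disposition with zero-order infusion into the depot followed
by first-order absorption for verinurad (ER8 and MR4 formulations), and
plain first-order two-compartment models for febuxostat and oxypurinol.
Allopurinol is represented directly by oxypurinol exposure with the
conversion folded into bioavailability, since only oxypurinol concentration
enters the pharmacodynamics. Profiles are exact analytic superpositions of
single-dose solutions (sums of three exponentials; the zero-order phase is
the closed-form convolution with a rectangular pulse), evaluated inside
the ODE right-hand side with no interpolation error. A removable
singularity when $k_a$ collides with a disposition exponent is handled by
a documented relative nudge of 1e−5 on $k_a$.

The verinurad ER8 values were calibrated once so that 12 mg once daily
produces steady-state concentrations bracketing the verinurad $EC_{50}$
(trough ≈ 27, peak ≈ 45 ng/mL around 29.4), the regime in which the
published simulations operate; covariate effects on PK (eGFR and weight
power models on clearance, weight on oxypurinol volume, and a proportional
reduction of oxypurinol exposure under co-dosed verinurad) are assumption
defaults, clearly non-published, and fully overridable. Quantities that
depend on the actual exposure magnitudes are therefore checked as
*properties* (orderings, monotonicity, band containment), never as
numerical reproductions.

## Trial simulation

`simulate_with_variability()` draws subjects (covariates fixed or
per-subject), simulates each on a 0.1 h grid by default, computes
endpoints per subject, and reports 5/50/95% quantiles; 500 subjects is the
default, matching the published simulation size. Endpoints follow the
published definitions: maximum sUA reduction (% of baseline over the whole
run), 24 h average effective FEUA over the steady-state window, and the
maximum renal excretion rate. The steady-state window defaults to the
24 h after the 7th daily dose, by which time the combination effect has
fully developed. The maximum excretion rate is computed per subject and
then summarised — exceedance fractions against the baseline 95th quantile
require subject-level maxima, not quantiles of a median curve.

`simulate_with_uncertainty()` instead propagates estimation uncertainty:
population parameter vectors are drawn on the log scale (positive
parameters) using a diagonal covariance built from the published RSE%
values by default — the estimation covariance itself was not published — or
any user-supplied covariance, and the typical-subject endpoint is computed
per draw. Log-scale sampling was chosen over natural-scale sampling
because it respects positivity and keeps the median draw at the typical
value; the source does not state which scale was used.

`dose_response_grid()` and `combination_selection()` wrap these engines
for the two decision questions the model serves: verinurad dose-response
on a fixed XOI background (dose 0 = XOI monotherapy, plus a placebo
reference), and choosing the febuxostat dose that keeps the steady-state
maximum urinary excretion within the drug-free baseline band.

## Estimation

`fit_population()` maximises a Laplace-approximated marginal likelihood —
the same approximate-likelihood family as the FOCEI method used for the
original analysis. Per subject, the joint log-likelihood is maximised over
the active random effects by a damped Newton ascent with *analytic*
gradients: the model co-integrates sensitivity states
$\partial(A_1,A_2)/\partial\eta$ for each random effect, so a single
integration yields prediction, gradient, and a Fisher (Gauss–Newton)
curvature. The Laplace correction uses that Fisher curvature by default
(`hessian = "gn"`, the FOCE-style linearisation, computed at no extra
cost); an exact central-difference Hessian of the analytic gradient is
available (`hessian = "fd"`) and is what the quadrature-oracle tests
exercise. On one-random-effect test subjects the Laplace value agrees
with adaptive quadrature of the marginal integrand to better than 0.1%.

The inner problem is solved in compiled code with an embedded
Dormand–Prince 5(4) integrator that lands exactly on dosing kinks and
observation times; the deSolve path (lsoda, rtol 1e−8 / atol 1e−10)
remains the reference integrator for simulation, and the two agree to
solver tolerance. Random effects are box-bounded at $|\eta| \le 5$ (a
factor $e^5$ on the parameter) — far outside any plausible mode but
protective against overflow during line searches. The outer problem runs
L-BFGS-B on transformed parameters (log for positive parameters and
variance components, Fisher-z for the correlation, logit for the fixed
Emax values if unfixed) within ±3 of the start. Stale warm starts for the
inner modes are detected by probing the prior mode and re-solving when it
scores better. EC50s of drugs never dosed in a dataset are automatically
fixed with a warning. Approximate standard errors come from the inverse
Hessian of the objective (`se = TRUE`).

Urine residual error applies to interval amounts rather than running
cumulative amounts — the collection-interval structure of the designs
makes interval amounts the observed quantity, and this choice also
isolates the known overnight-interval misfit rather than letting it
propagate through a cumulative series.

## The virtual-study generator

`generate_virtual_study()` emulates the statistical structure the analysis
assumes: truncated lognormal covariate distributions matched to a
median/range triple (the log-SD comes from the narrower half-range over
2.5, so truncation barely displaces the median), status and race by stated
fractions, deterministic arm assignment by fraction, true individual
parameters via the population layer, exposures from the subject's dose
records, and observations through the residual model. The truth sidecar
(`attr(x, "truth")`) records the simulated individual parameters for
recovery testing and is never read by the estimation code. Design
templates mirror arm structures and dose levels of the clinical program at
reduced sampling density; the real per-study sampling schedules are not
public, and the templates say so in their documentation. What passing
recovery tests on these data show is that the estimator inverts the
model's own data-generating process at realistic designs and noise — they
cannot show robustness to model misspecification, dropout, censoring, or
adherence patterns, none of which the generator emulates.

## Numerical and test-design choices

* Simulation tolerances rtol 1e−8 / atol 1e−10 everywhere; mass balance
  (production = circulating + excreted + intestinal loss, audited through
  two extra cumulative states) holds to 1e−6 relative on every test
  trajectory.
* Problem sizes: trial-simulation tests use 300–500 subjects over 8 days;
  the parameter-recovery check uses the full prescribed scale — 200
  subjects, verinurad 2.5–20 mg ± 80 mg febuxostat, eleven serum samples
  and eight 6 h urine intervals over three days, three seeds — and runs in
  a few minutes; Monte Carlo quantile checks use 2·10⁴–10⁵ draws.
* Recovery starts are deliberately displaced from the truth (+25% kin,
  −20% FEUA, +30% EC50, detuned variability with correlation 0.3) so the
  optimiser must travel.
* Degenerate inputs: zero CVs and zero residual SDs are exact limits, not
  special cases; a subject with no observations gets the prior mode (zero)
  as its empirical Bayes estimate; both XOIs in one run is a validation
  error, matching the source analyses which never combine them.

## Known limitations

The exposure stand-ins make absolute PK-dependent magnitudes (e.g. the
printed excretion-rate traces of the original figures) non-reproducible by
construction; only their qualitative structure is claimed. eGFR is a
constant per subject; circadian sUA rhythm, food effects, crystallisation
kinetics and renal-impairment misfit are out of scope. The additive urine
SD is weakly identified when the proportional component dominates, and
recovery tests do not constrain it.
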