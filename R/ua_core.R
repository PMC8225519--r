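# Structural model: mass balance, drug-effect functions, steady states and
# ODE simulation. Internal concentrations are mg/L; user-facing serum uric
# acid is mg/dL (mg/L divided by 10).

#' Uric acid production rate under XOI inhibition
#'
#' Saturable inhibition of the production rate by a xanthine oxidase
#' inhibitor: `kin * (1 - emax * cx / (ec50 + cx))`.
#'
#' @param kin Drug-free production rate, mg/h.
#' @param cx XOI plasma concentration, ng/mL (non-negative).
#' @param emax Maximum fractional inhibition in `[0, 1]`.
#' @param ec50 Concentration of half-maximal inhibition, ng/mL.
#' @return Production rate, mg/h.
#' @examples
#' production_rate(43.78, 128, 1, 128) # half-maximal: 21.89
#' @export
production_rate <- function(kin, cx, emax, ec50) {
  if (any(cx < 0)) stop("XOI concentration must be non-negative")
  if (kin <= 0 || ec50 <= 0) stop("'kin' and 'ec50' must be positive")
  if (emax < 0 || emax > 1) stop("'emax' must lie in [0, 1]")
  kin * (1 - emax * cx / (ec50 + cx))
}

#' Effective fractional excretion under verinurad
#'
#' Stimulation of the fractional excretion of uric acid by verinurad:
#' `feua + emax_ver * cv / (ec50_ver + cv)`.
#'
#' @param feua Baseline FEUA, fraction in (0,1).
#' @param cv Verinurad plasma concentration, ng/mL (non-negative).
#' @param emax_ver Maximum FEUA increase, fraction.
#' @param ec50_ver Verinurad EC50, ng/mL.
#' @return Effective FEUA (fraction).
#' @examples
#' effective_feua(0.077, 29.4, 0.7, 29.4) # feua + emax/2 = 0.427
#' @export
effective_feua <- function(feua, cv, emax_ver, ec50_ver) {
  if (any(cv < 0)) stop("verinurad concentration must be non-negative")
  if (feua <= 0 || feua >= 1) stop("'feua' must lie in (0, 1)")
  if (ec50_ver <= 0) stop("'ec50_ver' must be positive")
  feua + emax_ver * cv / (ec50_ver + cv)
}

#' Renal excretion rate of uric acid
#'
#' Product of the filtered load (filtration flow times serum concentration)
#' and the effective fractional excretion.
#'
#' @param c_ua Serum uric acid concentration, mg/L.
#' @param renal A [renal_context()].
#' @param feua_eff Effective FEUA (fraction).
#' @return Renal excretion rate, mg/h.
#' @export
renal_excretion_rate <- function(c_ua, renal, feua_eff) {
  if (any(c_ua < 0)) stop("'c_ua' must be non-negative")
  renal$egfr_flow * c_ua * feua_eff
}

#' Drug-free steady-state serum uric acid
#'
#' Closed-form baseline: `kin / (cl_i + egfr_flow * feua)` in mg/L,
#' reported in mg/dL.
#'
#' @param params A [ua_params()] (individual or typical values; apply
#'   covariate models first for patient strata).
#' @param renal A [renal_context()].
#' @return Baseline serum uric acid, mg/dL.
#' @examples
#' p <- ua_params(feua = 0.077)
#' steady_state_sua(p, renal_context(60)) # about 8.7 mg/dL
#' @export
steady_state_sua <- function(params, renal) {
  params$kin / (params$cl_i + renal$egfr_flow * params$feua) / 10
}

#' Steady-state serum uric acid under constant drug exposure
#'
#' Closed-form equilibrium of the turnover system when verinurad and/or one
#' XOI concentration is held constant; equals the long-time limit of
#' [simulate_ua()] under the same constant exposures.
#'
#' @inheritParams steady_state_sua
#' @param cv Constant verinurad concentration, ng/mL.
#' @param cx Constant XOI concentration, ng/mL.
#' @param xoi Which XOI `cx` refers to: `"none"`, `"febuxostat"`, or
#'   `"oxypurinol"`.
#' @return Steady-state serum uric acid, mg/dL.
#' @export
steady_state_constant_exposure <- function(params, renal, cv = 0, cx = 0,
                                           xoi = c("none", "febuxostat",
                                                   "oxypurinol")) {
  xoi <- match.arg(xoi)
  if (cv < 0 || cx < 0) stop("concentrations must be non-negative")
  if (xoi == "none" && cx > 0)
    stop("'cx' given but 'xoi' is \"none\"")
  prod <- switch(xoi,
    none = params$kin,
    febuxostat = production_rate(params$kin, cx, params$emax_feb,
                                 params$ec50_feb),
    oxypurinol = production_rate(params$kin, cx, params$emax_oxy,
                                 params$ec50_oxy))
  fe <- effective_feua(params$feua, cv, params$emax_ver, params$ec50_ver)
  prod / (params$cl_i + renal$egfr_flow * fe) / 10
}

#' Initial state at the drug-free steady state
#'
#' @inheritParams steady_state_sua
#' @return List with `a1` (mg, systemic amount), `a2` (0, cumulative urine
#'   amount) and `t` (0 h).
#' @export
initial_state <- function(params, renal) {
  a1 <- params$v1 * params$kin /
    (params$cl_i + renal$egfr_flow * params$feua)
  list(a1 = a1, a2 = 0, t = 0)
}

# Assemble the padded parameter vector consumed by the compiled RHS.
# exposures: list with optional $verinurad and at most one XOI entry.
ua_build_parms <- function(params, renal, exposures) {
  xoi_names <- intersect(names(exposures), c("febuxostat", "oxypurinol"))
  if (length(xoi_names) > 1)
    stop("at most one XOI exposure may be active per simulation")
  extra <- setdiff(names(exposures), c("verinurad", "febuxostat",
                                       "oxypurinol"))
  if (length(extra))
    stop("unknown exposure drug(s): ", paste(extra, collapse = ", "))
  empty <- numeric(138)
  ver_block <- if (!is.null(exposures$verinurad))
    exposures$verinurad$block else empty
  if (length(xoi_names) == 1) {
    xoi_block <- exposures[[xoi_names]]$block
    emax_x <- if (xoi_names == "febuxostat") params$emax_feb else
      params$emax_oxy
    ec50_x <- if (xoi_names == "febuxostat") params$ec50_feb else
      params$ec50_oxy
  } else {
    xoi_block <- empty
    emax_x <- 0
    ec50_x <- 1
  }
  c(params$kin, params$feua, params$cl_i, params$v1, renal$egfr_flow,
    params$emax_ver, params$ec50_ver, emax_x, ec50_x, ver_block, xoi_block)
}

#' Simulate the uric acid turnover model
#'
#' Integrates the two-state mass-balance system (systemic amount `A1`,
#' cumulative urinary amount `A2`) driven by analytic plasma-concentration
#' profiles, starting by default from the drug-free steady state. Two audit
#' states (cumulative intestinal elimination and cumulative production) and
#' sensitivity states with respect to the log of the individual production
#' rate, FEUA and potencies are co-integrated; the former support exact
#' mass-balance checks, the latter the mixed-effects machinery.
#'
#' @inheritParams steady_state_sua
#' @param exposures Named list of [exposure_profile()] objects; allowed names
#'   are `"verinurad"` and exactly one of `"febuxostat"`/`"oxypurinol"`.
#'   An empty list simulates the drug-free system.
#' @param times Strictly increasing time grid, h (first element is the
#'   initial time).
#' @param init Optional initial state as returned by [initial_state()].
#' @param rtol,atol Solver tolerances (stiff-capable lsoda).
#' @return An object of class `ua_sim`: a data.frame with columns `time`,
#'   `sua` (mg/dL), `cum_uua` (mg), `feua_eff`, `renal_rate` (mg/h),
#'   `production` (mg/h), `conc_ver`, `conc_xoi` (ng/mL), plus attributes
#'   `state` (raw state matrix incl. audit and sensitivity states) and
#'   `a1_0`.
#' @examples
#' p <- ua_params(feua = 0.077)
#' sim <- simulate_ua(p, renal_context(60), list(), times = 0:24)
#' range(sim$sua)
#' @export
simulate_ua <- function(params, renal, exposures = list(),
                        times, init = NULL, rtol = 1e-8, atol = 1e-10) {
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  parms <- ua_build_parms(params, renal, exposures)
  if (is.null(init)) init <- initial_state(params, renal)
  a1_0 <- init$a1
  denom <- params$cl_i + renal$egfr_flow * params$feua
  # sensitivities of the steady-state A1(0) w.r.t. log kin / log feua
  s1k0 <- params$v1 * params$kin / denom
  s1f0 <- -params$v1 * params$kin * renal$egfr_flow * params$feua / denom^2
  y0 <- c(a1 = init$a1, a2 = init$a2, cum_i = 0, cum_p = 0,
          s1k = s1k0, s2k = 0, s1f = s1f0, s2f = 0,
          s1e = 0, s2e = 0, s1x = 0, s2x = 0)
  out <- deSolve::lsoda(y = y0, times = times, func = "ua_derivs",
                        parms = parms, dllname = "uratesim",
                        initfunc = "ua_init", nout = 5,
                        outnames = c("conc_ver", "conc_xoi", "feua_eff",
                                     "renal_rate", "production"),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE integration failed (istate = ", diagn[1], ")")
  out <- as.data.frame(out)
  res <- data.frame(time = out$time,
                    sua = out$a1 / params$v1 / 10,
                    cum_uua = out$a2,
                    feua_eff = out$feua_eff,
                    renal_rate = out$renal_rate,
                    production = out$production,
                    conc_ver = out$conc_ver,
                    conc_xoi = out$conc_xoi)
  attr(res, "state") <- out
  attr(res, "a1_0") <- a1_0
  attr(res, "params") <- params
  class(res) <- c("ua_sim", "data.frame")
  res
}

#' Mass-balance residual of a simulated trajectory
#'
#' For every time point, `a1 + a2 + cumulative intestinal elimination -
#' cumulative production` must equal the initial systemic amount. Returns
#' the maximum relative deviation, a direct audit of the integrator.
#'
#' @param sim A `ua_sim` object from [simulate_ua()].
#' @return Maximum relative mass-balance error (dimensionless).
#' @export
mass_balance_error <- function(sim) {
  st <- attr(sim, "state")
  a1_0 <- attr(sim, "a1_0")
  max(abs(st$a1 + st$a2 + st$cum_i - st$cum_p - a1_0)) / a1_0
}
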