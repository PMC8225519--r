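# Trial-simulation engines: simulation with between-subject variability,
# simulation with parameter uncertainty, derived endpoints, dose-response
# grids and XOI-dose selection for the verinurad/XOI combination.

#' Scenario specification for trial simulation
#'
#' @param regimens List of [dose_regimen()] objects (possibly empty for a
#'   drug-free baseline scenario).
#' @param covariates A single [subject_covariates()] (typical subject) or a
#'   list with one entry per subject.
#' @param n_subjects Subjects for simulation with variability.
#' @param n_param_draws Parameter vectors for simulation with uncertainty.
#' @param duration Simulated span, h. The default (192 h) covers seven once
#'   daily doses plus a full steady-state interval.
#' @param ss_window Steady-state window `(start, end)` in h; default the
#'   24 h following the 7th daily dose.
#' @param quantiles Reported quantiles, sorted, in (0,1).
#' @param dt Output grid resolution, h.
#' @param seed RNG seed; every stochastic engine sets it on entry.
#' @return Object of class `ua_scenario`.
#' @export
scenario_spec <- function(regimens = list(),
                          covariates = subject_covariates(
                            egfr = 60, status = "asymptomatic"),
                          n_subjects = 500, n_param_draws = 500,
                          duration = 192, ss_window = c(144, 168),
                          quantiles = c(0.05, 0.5, 0.95), dt = 0.1,
                          seed = 1L) {
  if (n_subjects < 1) stop("'n_subjects' must be at least 1")
  if (any(quantiles <= 0) || any(quantiles >= 1) ||
      is.unsorted(quantiles, strictly = TRUE))
    stop("'quantiles' must be sorted and lie in (0, 1)")
  if (ss_window[2] > duration || ss_window[1] < 0)
    stop("'ss_window' must lie within the simulated span")
  structure(list(regimens = regimens, covariates = covariates,
                 n_subjects = n_subjects, n_param_draws = n_param_draws,
                 duration = duration, ss_window = ss_window,
                 quantiles = quantiles, dt = dt, seed = as.integer(seed)),
            class = "ua_scenario")
}

# Dosed PD drugs implied by a regimen list
regimen_drugs <- function(regimens) {
  if (!length(regimens)) return(character(0))
  unique(vapply(regimens, function(r) switch(r$drug,
    verinurad_ER8 = , verinurad_MR4 = "verinurad",
    febuxostat = "febuxostat", allopurinol = "oxypurinol"),
    character(1)))
}

#' Build the exposure list for one subject
#'
#' Expands a list of regimens into named [exposure_profile()]s with
#' covariate-individualised PK, applying the verinurad-oxypurinol
#' interaction when both are dosed.
#'
#' @param regimens List of [dose_regimen()] objects.
#' @param cov A [subject_covariates()].
#' @param pk_catalog PK catalogue.
#' @return Named list of `ua_exposure` objects keyed by PD drug.
#' @export
build_exposures <- function(regimens, cov, pk_catalog = default_pk_catalog()) {
  if (!length(regimens)) return(list())
  drugs <- regimen_drugs(regimens)
  ver_codosed <- "verinurad" %in% drugs
  out <- list()
  for (r in regimens) {
    if (r$dose <= 0) next
    pk <- pk_apply_covariates(pk_catalog[[r$drug]], cov,
                              ver_codosed = ver_codosed)
    ex <- exposure_profile(r, pk)
    if (!is.null(out[[ex$drug]]))
      stop("duplicate exposure for drug ", ex$drug)
    out[[ex$drug]] <- ex
  }
  out
}

#' Derived endpoints from one simulated trajectory
#'
#' @param sim A `ua_sim` object.
#' @param baseline Baseline serum uric acid, mg/dL.
#' @param ss_window Steady-state window `(start, end)`, h.
#' @param rate_window Window for the maximum renal excretion rate; defaults
#'   to the steady-state window (use `c(0, max(time))` for onset analyses).
#' @return List with `max_sua_reduction` (percent change from baseline over
#'   the whole run), `avg_feua_24h` (time-averaged effective FEUA over
#'   `ss_window`, percent), `max_renal_rate` (mg/h over `rate_window`),
#'   `baseline_rate` (mg/h at the initial state) and `daily_max_rate`
#'   (per-24h-day maxima over the whole run, mg/h).
#' @export
compute_endpoints <- function(sim, baseline, ss_window,
                              rate_window = ss_window) {
  tt <- sim$time
  if (ss_window[1] < tt[1] || ss_window[2] > tt[length(tt)])
    stop("'ss_window' outside the simulated span")
  max_red <- 100 * (baseline - min(sim$sua)) / baseline
  in_ss <- tt >= ss_window[1] & tt <= ss_window[2]
  # trapezoidal time average
  tw <- tt[in_ss]
  fw <- sim$feua_eff[in_ss]
  avg_feua <- sum(diff(tw) * (head(fw, -1) + tail(fw, -1)) / 2) /
    (tw[length(tw)] - tw[1])
  in_rw <- tt >= rate_window[1] & tt <= rate_window[2]
  max_rate <- max(sim$renal_rate[in_rw])
  day <- floor(tt / 24)
  daily <- tapply(sim$renal_rate, day, max)
  list(max_sua_reduction = max_red,
       avg_feua_24h = 100 * avg_feua,
       max_renal_rate = max_rate,
       baseline_rate = sim$renal_rate[1],
       daily_max_rate = as.numeric(daily))
}

quantile_bands <- function(x, probs) {
  q <- quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
  setNames(q, paste0("q", sprintf("%02d", round(100 * probs))))
}

#' Simulation with between-subject variability
#'
#' Draws `n_subjects` individuals (correlated lognormal random effects on
#' production rate and FEUA, independent ones on the dosed drugs' EC50s),
#' simulates each under the scenario's regimens, and summarises endpoints
#' and time courses as quantile bands. Per-subject integration failures are
#' logged and skipped; the run continues.
#'
#' @param spec A [scenario_spec()].
#' @param pop Population-typical [ua_params()].
#' @param re A [random_effects_spec()].
#' @param coef A [covariate_coefficients()].
#' @param pk_catalog PK parameter catalogue.
#' @param keep_subjects Keep the per-subject endpoint table in the result.
#' @return Object of class `ua_summary`: list with `endpoints` (data.frame
#'   endpoint x quantile bands), `timecourse` (long data.frame of quantile
#'   bands for sUA, effective FEUA and renal rate), `daily_max_rate`
#'   (median per day), `subjects` (optional per-subject endpoints),
#'   `n_failed`, and `seed`.
#' @export
simulate_with_variability <- function(spec, pop = ua_params(),
                                      re = random_effects_spec(),
                                      coef = covariate_coefficients(),
                                      pk_catalog = default_pk_catalog(),
                                      keep_subjects = TRUE) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  cov_list <- if (inherits(spec$covariates, "ua_covariates"))
    rep(list(spec$covariates), n) else spec$covariates
  if (length(cov_list) != n)
    stop("per-subject covariate list must have length n_subjects")
  drugs <- regimen_drugs(spec$regimens)
  etas <- sample_etas(n, re, drugs = if (length(drugs)) drugs else "verinurad")
  if (!length(drugs)) etas <- etas[, c("kin", "feua"), drop = FALSE]
  times <- seq(0, spec$duration, by = spec$dt)
  shared_cov <- inherits(spec$covariates, "ua_covariates")
  exposures <- if (shared_cov)
    build_exposures(spec$regimens, cov_list[[1]], pk_catalog)
  ep_names <- c("max_sua_reduction", "avg_feua_24h", "max_renal_rate",
                "baseline_rate")
  eps <- matrix(NA_real_, n, length(ep_names),
                dimnames = list(NULL, ep_names))
  tc <- list(sua = matrix(NA_real_, n, length(times)),
             feua_eff = matrix(NA_real_, n, length(times)),
             renal_rate = matrix(NA_real_, n, length(times)))
  daily <- NULL
  n_failed <- 0L
  for (i in seq_len(n)) {
    cov_i <- cov_list[[i]]
    renal <- renal_context(cov_i$egfr)
    p_i <- individual_params(pop, cov_i, etas[i, ], coef)
    ex_i <- if (shared_cov) exposures else
      build_exposures(spec$regimens, cov_i, pk_catalog)
    baseline_i <- steady_state_sua(p_i, renal)
    sim <- tryCatch(simulate_ua(p_i, renal, ex_i, times),
                    error = function(e) NULL)
    if (is.null(sim)) { n_failed <- n_failed + 1L; next }
    e <- compute_endpoints(sim, baseline_i, spec$ss_window)
    eps[i, ] <- c(e$max_sua_reduction, e$avg_feua_24h, e$max_renal_rate,
                  e$baseline_rate)
    if (is.null(daily)) daily <- matrix(NA_real_, n, length(e$daily_max_rate))
    daily[i, seq_along(e$daily_max_rate)] <- e$daily_max_rate
    tc$sua[i, ] <- sim$sua
    tc$feua_eff[i, ] <- sim$feua_eff
    tc$renal_rate[i, ] <- sim$renal_rate
  }
  probs <- spec$quantiles
  endpoints <- do.call(rbind, lapply(ep_names, function(nm) {
    data.frame(endpoint = nm, t(quantile_bands(eps[, nm], probs)))
  }))
  timecourse <- do.call(rbind, lapply(names(tc), function(v) {
    qb <- apply(tc[[v]], 2, quantile_bands, probs = probs)
    df <- data.frame(time = times, variable = v)
    cbind(df, as.data.frame(t(qb)))
  }))
  rownames(timecourse) <- NULL
  structure(list(endpoints = endpoints, timecourse = timecourse,
                 daily_max_rate = apply(daily, 2, median, na.rm = TRUE),
                 subjects = if (keep_subjects) as.data.frame(eps),
                 n_failed = n_failed, seed = spec$seed,
                 quantiles = probs),
            class = "ua_summary")
}

#' Simulation with parameter uncertainty
#'
#' Draws population-parameter vectors from the estimation uncertainty
#' (default: independent lognormal draws for the positive structural
#' parameters using the catalogue RSE\%, normal draws for the covariate
#' coefficients), computes the typical-subject endpoint for each draw, and
#' summarises the draws as quantile bands. Draws violating parameter bounds
#' are rejected and resampled (count reported).
#'
#' @inheritParams simulate_with_variability
#' @param rse Named RSE\% vector (see [ua_catalog()]); ignored when
#'   `param_cov` is supplied.
#' @param param_cov Optional full covariance matrix of
#'   `log(kin, feua, cl_i, v1, ec50_ver, ec50_feb, ec50_oxy)` (named).
#' @param inflate Scalar multiplier on the uncertainty covariance.
#' @return Object of class `ua_summary` (endpoint bands across draws;
#'   `n_rejected` counts resampled draws).
#' @export
simulate_with_uncertainty <- function(spec, pop = ua_params(),
                                      coef = covariate_coefficients(),
                                      rse = ua_catalog()$rse,
                                      param_cov = NULL, inflate = 1,
                                      pk_catalog = default_pk_catalog()) {
  set.seed(spec$seed)
  cov <- if (inherits(spec$covariates, "ua_covariates")) spec$covariates
  else spec$covariates[[1]]
  renal <- renal_context(cov$egfr)
  exposures <- build_exposures(spec$regimens, cov, pk_catalog)
  times <- seq(0, spec$duration, by = spec$dt)
  pos_names <- c("kin", "feua", "cl_i", "v1", "ec50_ver", "ec50_feb",
                 "ec50_oxy")
  if (is.null(param_cov)) {
    sds <- rse[pos_names] / 100
    param_cov <- diag((sds * sqrt(inflate))^2, nrow = length(pos_names))
    dimnames(param_cov) <- list(pos_names, pos_names)
  } else {
    param_cov <- param_cov[pos_names, pos_names] * inflate
  }
  coef_names <- c("hyperfeua_asym", "hyperfeua_sym", "asianfeua",
                  "hyperec50")
  coef_sd <- abs(unlist(coef)[coef_names]) * rse[coef_names] / 100 *
    sqrt(inflate)
  mu <- log(unlist(pop[pos_names]))
  n <- spec$n_param_draws
  ep_names <- c("max_sua_reduction", "avg_feua_24h", "max_renal_rate")
  eps <- matrix(NA_real_, n, length(ep_names),
                dimnames = list(NULL, ep_names))
  n_rejected <- 0L
  for (i in seq_len(n)) {
    repeat {
      th <- exp(MASS::mvrnorm(1, mu, param_cov))
      co <- unlist(coef)[coef_names] + rnorm(4, 0, coef_sd)
      ok <- th[["feua"]] < 1 && all(co > -1)
      if (ok) break
      n_rejected <- n_rejected + 1L
    }
    p_i <- ua_params(kin = th[["kin"]], feua = th[["feua"]],
                     cl_i = th[["cl_i"]], v1 = th[["v1"]],
                     ec50_ver = th[["ec50_ver"]],
                     ec50_feb = th[["ec50_feb"]],
                     ec50_oxy = th[["ec50_oxy"]],
                     emax_ver = pop$emax_ver, emax_feb = pop$emax_feb,
                     emax_oxy = pop$emax_oxy)
    coef_i <- covariate_coefficients(co[["hyperfeua_asym"]],
                                     co[["hyperfeua_sym"]],
                                     co[["asianfeua"]], co[["hyperec50"]])
    p_i <- apply_covariates(p_i, cov, coef_i)
    baseline_i <- steady_state_sua(p_i, renal)
    sim <- tryCatch(simulate_ua(p_i, renal, exposures, times),
                    error = function(e) NULL)
    if (is.null(sim)) next
    e <- compute_endpoints(sim, baseline_i, spec$ss_window)
    eps[i, ] <- c(e$max_sua_reduction, e$avg_feua_24h, e$max_renal_rate)
  }
  probs <- spec$quantiles
  endpoints <- do.call(rbind, lapply(ep_names, function(nm) {
    data.frame(endpoint = nm, t(quantile_bands(eps[, nm], probs)))
  }))
  structure(list(endpoints = endpoints, timecourse = NULL,
                 subjects = as.data.frame(eps), n_failed = sum(is.na(eps[, 1])),
                 n_rejected = n_rejected, seed = spec$seed,
                 quantiles = probs),
            class = "ua_summary")
}

#' Dose-response grid for verinurad on top of a fixed XOI regimen
#'
#' One simulation per verinurad dose (dose 0 = XOI monotherapy), plus a
#' placebo (no-drug) reference row.
#'
#' @param doses_ver Verinurad doses, mg; must include 0.
#' @param xoi_regimen An XOI [dose_regimen()] (or `NULL` for verinurad
#'   monotherapy grids).
#' @param spec A [scenario_spec()] (its `regimens` field is ignored).
#' @param ver_drug Verinurad formulation for the grid.
#' @param method `"uncertainty"` (default) or `"variability"`.
#' @param ... Passed to the underlying simulation engine.
#' @return data.frame with one row per (dose, endpoint) carrying quantile
#'   bands; placebo rows carry `dose = NA`.
#' @export
dose_response_grid <- function(doses_ver, xoi_regimen, spec,
                               ver_drug = "verinurad_ER8",
                               method = c("uncertainty", "variability"),
                               ...) {
  method <- match.arg(method)
  if (!0 %in% doses_ver)
    stop("'doses_ver' must include 0 (XOI monotherapy reference)")
  n_doses <- ceiling(spec$duration / 24)
  run1 <- function(regs) {
    sp <- spec
    sp$regimens <- regs
    s <- if (method == "uncertainty")
      simulate_with_uncertainty(sp, ...) else
      simulate_with_variability(sp, ...)
    s$endpoints
  }
  rows <- lapply(sort(doses_ver), function(d) {
    regs <- list()
    if (d > 0) regs <- c(regs, list(dose_regimen(ver_drug, d,
                                                 n_doses = n_doses)))
    if (!is.null(xoi_regimen)) regs <- c(regs, list(xoi_regimen))
    cbind(dose = d, run1(regs))
  })
  placebo <- cbind(dose = NA_real_, run1(list()))
  out <- do.call(rbind, c(rows, list(placebo)))
  rownames(out) <- NULL
  out
}

#' XOI-dose selection for combination with a fixed verinurad dose
#'
#' Simulates (with variability) a fixed verinurad dose combined with each
#' febuxostat dose (0 = verinurad monotherapy) and reports, per
#' combination, quantile bands of the per-subject steady-state maximum
#' renal excretion rate and maximum sUA reduction plus the fraction of
#' subjects whose maximum excretion exceeds the 95th quantile of the
#' drug-free baseline.
#'
#' @param ver_dose Verinurad dose, mg.
#' @param feb_doses Febuxostat doses, mg; must include 0.
#' @param spec A [scenario_spec()] (its `regimens` field is ignored).
#' @param ver_drug Verinurad formulation.
#' @param ... Passed to [simulate_with_variability()].
#' @return List with `table` (per-combination bands and exceedance
#'   fraction) and `baseline` (quantile band of the per-subject baseline
#'   excretion rate, whose upper value is the exceedance threshold).
#' @export
combination_selection <- function(ver_dose, feb_doses, spec,
                                  ver_drug = "verinurad_ER8", ...) {
  if (!0 %in% feb_doses) stop("'feb_doses' must include 0")
  n_doses <- ceiling(spec$duration / 24)
  base_spec <- spec
  base_spec$regimens <- list()
  base <- simulate_with_variability(base_spec, ...)
  thr <- base$subjects$baseline_rate
  base_band <- quantile_bands(thr, spec$quantiles)
  thr95 <- quantile(thr, 0.95, names = FALSE)
  rows <- lapply(sort(feb_doses), function(fd) {
    regs <- list(dose_regimen(ver_drug, ver_dose, n_doses = n_doses))
    if (fd > 0) regs <- c(regs, list(dose_regimen("febuxostat", fd,
                                                  n_doses = n_doses)))
    sp <- spec
    sp$regimens <- regs
    s <- simulate_with_variability(sp, ...)
    mx <- s$subjects$max_renal_rate
    red <- s$subjects$max_sua_reduction
    data.frame(ver_dose = ver_dose, feb_dose = fd,
               t(setNames(quantile_bands(mx, spec$quantiles),
                          paste0("rate_", names(quantile_bands(mx, spec$quantiles))))),
               t(setNames(quantile_bands(red, spec$quantiles),
                          paste0("red_", names(quantile_bands(red, spec$quantiles))))),
               exceed_frac = mean(mx > thr95, na.rm = TRUE))
  })
  list(table = do.call(rbind, rows), baseline = base_band,
       threshold_q95 = thr95)
}

#' Analytic 95th-quantile baseline excretion (lognormal linearization)
#'
#' First-order approximation to a quantile of the drug-free baseline renal
#' excretion rate `kin * x / (cl_i + x)`, `x = egfr_flow * feua`, under
#' correlated lognormal variability on `kin` and `feua`: the log of the
#' rate is linearized in the two random effects (the FEUA elasticity is
#' `cl_i / (cl_i + x)`), giving a lognormal whose quantile is closed-form.
#' Serves as the independent cross-check of the Monte Carlo quantile.
#'
#' @param params Covariate-adjusted [ua_params()].
#' @param renal A [renal_context()].
#' @param re A [random_effects_spec()].
#' @param q Quantile (default 0.95).
#' @return Approximate quantile of the baseline excretion rate, mg/h.
#' @export
baseline_rate_quantile_linearized <- function(params, renal,
                                              re = random_effects_spec(),
                                              q = 0.95) {
  x0 <- renal$egfr_flow * params$feua
  r0 <- params$kin * x0 / (params$cl_i + x0)
  elast <- params$cl_i / (params$cl_i + x0)
  ok <- cv_to_omega(re$cv_kin, re$exact_transform)
  of <- cv_to_omega(re$cv_feua, re$exact_transform)
  sdl <- sqrt(ok^2 + elast^2 * of^2 +
                2 * re$corr_kin_feua * elast * ok * of)
  r0 * exp(qnorm(q) * sdl)
}
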