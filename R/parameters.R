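#' Structural uric acid model parameters
#'
#' Constructs the parameter set of the uric acid turnover model for one
#' (virtual) individual or the population typical subject. Defaults are the
#' published typical values of the integrated verinurad/XOI uric acid model;
#' the three maximum drug effects are fixed values, not estimated ones
#' (verinurad Emax from FEUA observed with loss-of-function URAT1 mutations,
#' XOI Emax values carried over from the earlier lesinurad model).
#'
#' @param kin Uric acid production rate in absence of drug, mg/h.
#' @param feua Baseline fractional excretion of uric acid (fraction in (0,1));
#'   the default is the healthy-volunteer typical value. Use
#'   [apply_covariates_feua()] for patient strata.
#' @param cl_i Intestinal clearance of uric acid, L/h.
#' @param v1 Volume of distribution of uric acid, L.
#' @param ec50_ver,ec50_feb,ec50_oxy Drug potencies, ng/mL: plasma
#'   concentration giving half the maximal effect.
#' @param emax_ver Maximum achievable increase in FEUA under verinurad
#'   (fraction, fixed at 0.7).
#' @param emax_feb,emax_oxy Maximum fractional inhibition of uric acid
#'   production for febuxostat (1.0) and oxypurinol (0.84), fixed.
#' @return An object of class `ua_params` (named list).
#' @examples
#' p <- ua_params()
#' p$kin
#' @export
ua_params <- function(kin = 43.78, feua = 0.0906, cl_i = 0.2272, v1 = 14.11,
                      ec50_ver = 29.40, ec50_feb = 128.0, ec50_oxy = 13030,
                      emax_ver = 0.7, emax_feb = 1.0, emax_oxy = 0.84) {
  p <- list(kin = kin, feua = feua, cl_i = cl_i, v1 = v1,
            ec50_ver = ec50_ver, ec50_feb = ec50_feb, ec50_oxy = ec50_oxy,
            emax_ver = emax_ver, emax_feb = emax_feb, emax_oxy = emax_oxy)
  for (nm in c("kin", "feua", "cl_i", "v1", "ec50_ver", "ec50_feb",
               "ec50_oxy", "emax_ver")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("'", nm, "' must be a single positive number")
  }
  if (feua >= 1) stop("'feua' must be a fraction in (0, 1)")
  if (emax_feb < 0 || emax_feb > 1) stop("'emax_feb' must lie in [0, 1]")
  if (emax_oxy < 0 || emax_oxy > 1) stop("'emax_oxy' must lie in [0, 1]")
  structure(p, class = "ua_params")
}

#' Convert eGFR to a glomerular filtration flow
#'
#' The model works with a filtration flow in L/h; estimated glomerular
#' filtration rate reported in mL/min/1.73 m^2 is converted at exactly
#' 0.06 L/h per unit.
#'
#' @param egfr eGFR in mL/min/1.73 m^2; strictly positive.
#' @return Filtration flow in L/h.
#' @examples
#' egfr_to_flow(60) # 3.6 L/h
#' @export
egfr_to_flow <- function(egfr) {
  if (!is.numeric(egfr) || any(!is.finite(egfr)) || any(egfr <= 0))
    stop("'egfr' must be positive and finite")
  egfr * 0.06
}

#' Renal context for one subject
#'
#' Wraps the subject's constant glomerular filtration flow. eGFR is treated
#' as fixed per subject (baseline renal function); time-varying renal
#' function is out of scope.
#'
#' @param egfr eGFR in mL/min/1.73 m^2.
#' @return Object of class `ua_renal` with element `egfr_flow` (L/h).
#' @export
renal_context <- function(egfr = 60) {
  structure(list(egfr = egfr, egfr_flow = egfr_to_flow(egfr)),
            class = "ua_renal")
}

#' Subject covariates
#'
#' @param egfr eGFR, mL/min/1.73 m^2.
#' @param weight Body weight, kg.
#' @param asian Logical; Asian race.
#' @param status Hyperuricemia status: `"healthy"`, `"asymptomatic"`, or
#'   `"symptomatic"` (gout).
#' @return Object of class `ua_covariates`.
#' @export
subject_covariates <- function(egfr = 60, weight = 80, asian = FALSE,
                               status = c("healthy", "asymptomatic",
                                          "symptomatic")) {
  status <- match.arg(status)
  if (egfr <= 0) stop("'egfr' must be positive")
  if (weight <= 0) stop("'weight' must be positive")
  structure(list(egfr = egfr, weight = weight, asian = isTRUE(asian),
                 status = status),
            class = "ua_covariates")
}

#' Covariate coefficients for FEUA and verinurad EC50
#'
#' Multiplicative covariate effects: FEUA is the healthy-volunteer typical
#' value times `(1 + hyperfeua_status)` times `(1 + asianfeua)` for Asian
#' subjects; verinurad EC50 gains a factor `(1 + hyperec50)` in symptomatic
#' (gout) patients only. Defaults are the published estimates.
#'
#' @param hyperfeua_asym FEUA covariate, asymptomatic hyperuricemia.
#' @param hyperfeua_sym FEUA covariate, symptomatic hyperuricemia (gout).
#' @param asianfeua FEUA covariate, Asian race.
#' @param hyperec50 Verinurad EC50 covariate, symptomatic hyperuricemia.
#' @return Object of class `ua_covcoef`.
#' @export
covariate_coefficients <- function(hyperfeua_asym = -0.1501,
                                   hyperfeua_sym = -0.3787,
                                   asianfeua = -0.2322,
                                   hyperec50 = 0.2677) {
  co <- list(hyperfeua_asym = hyperfeua_asym, hyperfeua_sym = hyperfeua_sym,
             asianfeua = asianfeua, hyperec50 = hyperec50)
  if (any(unlist(co) <= -1))
    stop("covariate coefficients must exceed -1 (multiplicative factors)")
  structure(co, class = "ua_covcoef")
}

#' Between-subject variability specification
#'
#' Lognormal interindividual variability, reported as CV%. Production rate
#' and FEUA random effects are correlated; each EC50 has an independent
#' random effect drawn only when the corresponding drug is dosed.
#'
#' @param cv_kin,cv_feua,cv_ec50_ver,cv_ec50_feb,cv_ec50_oxy CV% values.
#' @param corr_kin_feua Correlation between the production-rate and FEUA
#'   random effects on the log scale.
#' @param exact_transform Logical; if `TRUE` (default) the log-scale standard
#'   deviation is `sqrt(log(1 + (cv/100)^2))`, the exact lognormal relation.
#'   If `FALSE`, the small-CV approximation `cv/100` is used.
#' @return Object of class `ua_iiv`.
#' @export
random_effects_spec <- function(cv_kin = 27.76, cv_feua = 42.54,
                                cv_ec50_ver = 57.00, cv_ec50_feb = 89.96,
                                cv_ec50_oxy = 65.44, corr_kin_feua = 0.76,
                                exact_transform = TRUE) {
  cvs <- c(cv_kin = cv_kin, cv_feua = cv_feua, cv_ec50_ver = cv_ec50_ver,
           cv_ec50_feb = cv_ec50_feb, cv_ec50_oxy = cv_ec50_oxy)
  if (any(cvs < 0)) stop("CV% values must be non-negative")
  if (abs(corr_kin_feua) >= 1) stop("|corr_kin_feua| must be < 1")
  structure(list(cv_kin = cv_kin, cv_feua = cv_feua,
                 cv_ec50_ver = cv_ec50_ver, cv_ec50_feb = cv_ec50_feb,
                 cv_ec50_oxy = cv_ec50_oxy, corr_kin_feua = corr_kin_feua,
                 exact_transform = exact_transform),
            class = "ua_iiv")
}

#' Residual error specification
#'
#' Observations follow `y = f + sqrt(a^2 + (b f)^2) * eps` with standard
#' normal `eps`. Serum uric acid uses a purely additive error (`b = 0`);
#' interval urine amounts use a combined additive and proportional error.
#' `a_serum_override` carries the distinct additive serum error estimated
#' for one validation-style study and can be applied per dataset.
#'
#' @param a_serum Additive serum SD, mg/dL.
#' @param a_urine Additive urine SD, mg.
#' @param b_urine Proportional urine SD, fraction.
#' @param a_serum_override Optional alternative additive serum SD, mg/dL.
#' @return Object of class `ua_residual`.
#' @export
residual_spec <- function(a_serum = 0.4107, a_urine = 3.054,
                          b_urine = 0.3806, a_serum_override = 0.9524) {
  if (a_serum < 0 || a_urine < 0 || b_urine < 0)
    stop("residual SDs must be non-negative")
  structure(list(a_serum = a_serum, a_urine = a_urine, b_urine = b_urine,
                 a_serum_override = a_serum_override),
            class = "ua_residual")
}

#' Default parameter catalogue
#'
#' The typical values, relative standard errors (RSE%), variability and
#' residual-error components of the integrated uric acid model, bundled with
#' the covariate coefficients. RSEs feed the default diagonal uncertainty
#' covariance used by [simulate_with_uncertainty()].
#'
#' @return A list with elements `params` ([ua_params()]), `coef`
#'   ([covariate_coefficients()]), `iiv` ([random_effects_spec()]), `res`
#'   ([residual_spec()]) and `rse` (named RSE% vector for the estimated
#'   fixed effects).
#' @export
ua_catalog <- function() {
  list(params = ua_params(),
       coef = covariate_coefficients(),
       iiv = random_effects_spec(),
       res = residual_spec(),
       rse = c(kin = 1.75, feua = 3.18, cl_i = 12.8, v1 = 0.661,
               ec50_ver = 4.73, ec50_feb = 7.16, ec50_oxy = 12,
               hyperfeua_asym = 32.2, hyperfeua_sym = 6.06,
               asianfeua = 11.5, hyperec50 = 33.5))
}

#' Read or write a parameter catalogue as JSON
#'
#' All catalogue values are overridable; these helpers let a catalogue be
#' versioned as a plain-text config file.
#'
#' @param catalog A catalogue as returned by [ua_catalog()].
#' @param path File path.
#' @return `read_ua_catalog()` returns a catalogue list; `write_ua_catalog()`
#'   returns `path` invisibly.
#' @export
write_ua_catalog <- function(catalog, path) {
  plain <- lapply(catalog, function(x) as.list(unclass(x)))
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ua_catalog
#' @export
read_ua_catalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(params = do.call(ua_params, as.list(raw$params)),
       coef = do.call(covariate_coefficients, as.list(raw$coef)),
       iiv = do.call(random_effects_spec, as.list(raw$iiv)),
       res = do.call(residual_spec, as.list(raw$res)),
       rse = unlist(raw$rse))
}
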