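# Mixed-effects layer: covariate models, lognormal between-subject
# variability with one correlation, and the residual-error model.

#' Covariate model for baseline FEUA
#'
#' Multiplicative model: the healthy-volunteer typical FEUA times
#' `(1 + HYPERFEUA)` for hyperuricemic status (separate coefficients for
#' asymptomatic and symptomatic patients) times `(1 + ASIANFEUA)` for Asian
#' subjects. Healthy status contributes a factor of 1. The status and race
#' factors commute.
#'
#' @param feua_typ Typical healthy-volunteer FEUA (fraction).
#' @param cov A [subject_covariates()] object.
#' @param coef A [covariate_coefficients()] object.
#' @return Covariate-adjusted FEUA (fraction).
#' @examples
#' cc <- covariate_coefficients()
#' apply_covariates_feua(0.0906, subject_covariates(status = "symptomatic"), cc)
#' @export
apply_covariates_feua <- function(feua_typ, cov,
                                  coef = covariate_coefficients()) {
  hyper <- switch(cov$status,
                  healthy = 0,
                  asymptomatic = coef$hyperfeua_asym,
                  symptomatic = coef$hyperfeua_sym)
  feua_typ * (1 + hyper) * (1 + coef$asianfeua * as.numeric(cov$asian))
}

#' Covariate model for verinurad EC50
#'
#' `EC50_TYP * (1 + HYPEREC50)` for symptomatic (gout) patients; healthy
#' and asymptomatic subjects keep the typical value.
#'
#' @param ec50_typ Typical verinurad EC50, ng/mL.
#' @inheritParams apply_covariates_feua
#' @return Covariate-adjusted EC50, ng/mL.
#' @export
apply_covariates_ec50 <- function(ec50_typ, cov,
                                  coef = covariate_coefficients()) {
  ec50_typ * (1 + coef$hyperec50 *
                as.numeric(cov$status == "symptomatic"))
}

#' Apply all covariate models to a typical parameter set
#'
#' @param params Population-typical [ua_params()].
#' @inheritParams apply_covariates_feua
#' @return A `ua_params` object with covariate-adjusted `feua` and
#'   `ec50_ver`.
#' @export
apply_covariates <- function(params, cov, coef = covariate_coefficients()) {
  params$feua <- apply_covariates_feua(params$feua, cov, coef)
  params$ec50_ver <- apply_covariates_ec50(params$ec50_ver, cov, coef)
  params
}

#' Convert a CV\% to a log-scale standard deviation
#'
#' Exact lognormal relation `omega = sqrt(log(1 + (cv/100)^2))`; the
#' small-CV approximation `cv/100` is available for compatibility with
#' tools that report CV\% that way.
#'
#' @param cv_percent CV in percent (> 0).
#' @param exact Use the exact transform (default) or the approximation.
#' @return Log-scale standard deviation.
#' @examples
#' cv_to_omega(27.76)
#' @export
cv_to_omega <- function(cv_percent, exact = TRUE) {
  if (any(cv_percent < 0)) stop("'cv_percent' must be non-negative")
  if (exact) sqrt(log(1 + (cv_percent / 100)^2)) else cv_percent / 100
}

# Inverse: omega -> CV% (exponent capped to stay finite for the extreme
# omega values an optimiser line search may visit)
omega_to_cv <- function(omega, exact = TRUE) {
  if (exact) 100 * sqrt(expm1(pmin(omega^2, 500))) else 100 * omega
}

#' Log-scale covariance matrix of the correlated random effects
#'
#' @param re A [random_effects_spec()].
#' @param drugs Character vector of dosed drugs (subset of `"verinurad"`,
#'   `"febuxostat"`, `"oxypurinol"`); EC50 random effects are included only
#'   for dosed drugs.
#' @return Positive-definite covariance matrix with named rows/columns
#'   (`kin`, `feua`, and the active `ec50_*`).
#' @export
omega_matrix <- function(re, drugs = "verinurad") {
  ex <- re$exact_transform
  om <- c(kin = cv_to_omega(re$cv_kin, ex),
          feua = cv_to_omega(re$cv_feua, ex),
          ec50_ver = cv_to_omega(re$cv_ec50_ver, ex),
          ec50_feb = cv_to_omega(re$cv_ec50_feb, ex),
          ec50_oxy = cv_to_omega(re$cv_ec50_oxy, ex))
  keep <- c("kin", "feua",
            if ("verinurad" %in% drugs) "ec50_ver",
            if ("febuxostat" %in% drugs) "ec50_feb",
            if ("oxypurinol" %in% drugs) "ec50_oxy")
  om <- om[keep]
  mat <- diag(om^2, nrow = length(om))
  dimnames(mat) <- list(keep, keep)
  mat["kin", "feua"] <- mat["feua", "kin"] <-
    re$corr_kin_feua * om[["kin"]] * om[["feua"]]
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  # tolerance guards the check against floating-point noise at tiny CVs
  if (min(ev) < -1e-10 * max(abs(ev)))
    stop("implied random-effects covariance is not positive definite")
  mat
}

#' Sample individual random effects
#'
#' Draws `(eta_kin, eta_feua)` from a correlated bivariate normal and an
#' independent eta for the EC50 of each dosed drug. Draws are keyed by
#' parameter name in a fixed order, so adding or removing a drug does not
#' reshuffle the other parameters' draws for a given RNG state.
#'
#' @param n Number of subjects.
#' @param re A [random_effects_spec()].
#' @param drugs Dosed drugs (see [omega_matrix()]).
#' @return `n` x k matrix of random effects with named columns.
#' @export
sample_etas <- function(n, re, drugs = "verinurad") {
  om <- omega_matrix(re, drugs)
  k <- ncol(om)
  etas <- matrix(0, n, k, dimnames = list(NULL, colnames(om)))
  etas[, c("kin", "feua")] <- MASS::mvrnorm(
    n, mu = c(0, 0), Sigma = om[c("kin", "feua"), c("kin", "feua")])
  for (nm in setdiff(colnames(om), c("kin", "feua")))
    etas[, nm] <- rnorm(n, 0, sqrt(om[nm, nm]))
  etas
}

#' Sample an individual parameter set
#'
#' Applies the covariate models to the population-typical values first,
#' then multiplies by `exp(eta)`; the population median within any
#' covariate stratum therefore equals the covariate-adjusted typical value.
#'
#' @param pop Population-typical [ua_params()].
#' @param cov A [subject_covariates()].
#' @param eta Named random-effect vector (a row of [sample_etas()]); zero
#'   for missing names.
#' @param coef A [covariate_coefficients()].
#' @return Individual `ua_params`.
#' @export
individual_params <- function(pop, cov, eta = numeric(0),
                              coef = covariate_coefficients()) {
  p <- apply_covariates(pop, cov, coef)
  g <- function(nm) if (nm %in% names(eta)) exp(eta[[nm]]) else 1
  p$kin <- p$kin * g("kin")
  p$feua <- min(p$feua * g("feua"), 0.999)
  p$ec50_ver <- p$ec50_ver * g("ec50_ver")
  p$ec50_feb <- p$ec50_feb * g("ec50_feb")
  p$ec50_oxy <- p$ec50_oxy * g("ec50_oxy")
  p
}

#' Add residual error to model predictions
#'
#' `y = f + sqrt(a^2 + (b f)^2) * eps`, `eps ~ N(0,1)`. Serum uses the
#' additive component only; urine the combined model. Negative observations
#' are possible, as under the error model.
#'
#' @param f Model prediction(s): serum mg/dL or urine interval amount mg.
#' @param kind `"serum"` or `"urine"`.
#' @param res A [residual_spec()].
#' @param use_override Use the per-study alternative serum additive SD.
#' @return Observed value(s) with noise added.
#' @export
observe <- function(f, kind = c("serum", "urine"), res = residual_spec(),
                    use_override = FALSE) {
  kind <- match.arg(kind)
  if (any(f < 0)) stop("predictions must be non-negative")
  sdv <- residual_sd(f, kind, res, use_override)
  f + sdv * rnorm(length(f))
}

#' Residual standard deviation at a prediction
#'
#' @inheritParams observe
#' @return Standard deviation(s) on the observation scale.
#' @export
residual_sd <- function(f, kind = c("serum", "urine"),
                        res = residual_spec(), use_override = FALSE) {
  kind <- match.arg(kind)
  if (kind == "serum") {
    a <- if (use_override) res$a_serum_override else res$a_serum
    rep(a, length(f))
  } else {
    sqrt(res$a_urine^2 + (res$b_urine * f)^2)
  }
}
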