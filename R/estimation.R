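# Nonlinear mixed-effects estimation of the uric acid model by
# Laplace-approximated marginal likelihood (the same approximate-likelihood
# family as FOCEI). The inner step maximises each subject's joint
# log-likelihood over its random effects using analytic gradients obtained
# from co-integrated sensitivity states; the curvature correction uses a
# finite-difference Hessian of that analytic gradient. The outer step
# maximises the summed Laplace marginal over transformed population
# parameters (log for positive parameters, Fisher z for the correlation).

#' Estimation specification
#'
#' Controls which parameters are estimated, which random effects the model
#' carries, and optimiser settings. The values inside `pop`, `re`, `res`
#' and `coef` serve both as initial values for estimated parameters and as
#' fixed values for the rest. The three maximum drug effects are fixed by
#' default and may be unfixed explicitly by naming them in `estimate`.
#'
#' @param estimate Fixed effects to estimate: subset of `"kin"`, `"feua"`,
#'   `"cl_i"`, `"v1"`, `"ec50_ver"`, `"ec50_feb"`, `"ec50_oxy"`,
#'   `"emax_ver"`, `"emax_feb"`, `"emax_oxy"`, and the covariate
#'   coefficients `"hyperfeua_asym"`, `"hyperfeua_sym"`, `"asianfeua"`,
#'   `"hyperec50"`.
#' @param eta_names Random effects carried by the model (subset of
#'   `"kin"`, `"feua"`, `"ec50_ver"`, `"ec50_feb"`, `"ec50_oxy"`); EC50
#'   effects are active only in subjects actually dosed with that drug.
#' @param estimate_omega Random-effect SDs to estimate (subset of
#'   `eta_names`); the rest stay fixed at the values in `re`.
#' @param estimate_corr Estimate the production-FEUA correlation.
#' @param estimate_sigma Residual components to estimate (subset of
#'   `"a_serum"`, `"a_urine"`, `"b_urine"`).
#' @param pop,coef,re,res Initial/fixed values ([ua_params()],
#'   [covariate_coefficients()], [random_effects_spec()],
#'   [residual_spec()]).
#' @param pk_catalog PK catalogue used to reconstruct exposures from dose
#'   records.
#' @param outer_maxit,outer_reltol Outer quasi-Newton settings.
#' @param inner_maxit,inner_reltol Inner (per-subject) settings.
#' @param se Compute approximate standard errors from the inverse Hessian
#'   of the objective at the optimum.
#' @return Object of class `ua_fitspec`.
#' @export
fit_spec <- function(estimate = c("kin", "feua", "ec50_ver"),
                     eta_names = c("kin", "feua", "ec50_ver", "ec50_feb",
                                   "ec50_oxy"),
                     estimate_omega = c("kin", "feua", "ec50_ver"),
                     estimate_corr = TRUE,
                     estimate_sigma = c("a_serum", "a_urine", "b_urine"),
                     pop = ua_params(), coef = covariate_coefficients(),
                     re = random_effects_spec(), res = residual_spec(),
                     pk_catalog = default_pk_catalog(),
                     outer_maxit = 150, outer_reltol = 1e-8,
                     inner_maxit = 100, inner_reltol = 1e-10,
                     hessian = c("gn", "fd"), se = FALSE) {
  hessian <- match.arg(hessian)
  if (missing(estimate_omega))
    estimate_omega <- intersect(estimate_omega, eta_names)
  if (missing(estimate_corr))
    estimate_corr <- all(c("kin", "feua") %in% eta_names)
  theta_ok <- c("kin", "feua", "cl_i", "v1", "ec50_ver", "ec50_feb",
                "ec50_oxy", "emax_ver", "emax_feb", "emax_oxy",
                "hyperfeua_asym", "hyperfeua_sym", "asianfeua", "hyperec50")
  if (!all(estimate %in% theta_ok))
    stop("unknown parameter(s) in 'estimate'")
  eta_ok <- c("kin", "feua", "ec50_ver", "ec50_feb", "ec50_oxy")
  if (!all(eta_names %in% eta_ok)) stop("unknown eta name(s)")
  if (!all(estimate_omega %in% eta_names))
    stop("'estimate_omega' must be a subset of 'eta_names'")
  if (estimate_corr && !all(c("kin", "feua") %in% eta_names))
    stop("correlation requires both kin and feua random effects")
  structure(list(estimate = estimate, eta_names = eta_names,
                 estimate_omega = estimate_omega,
                 estimate_corr = estimate_corr,
                 estimate_sigma = estimate_sigma,
                 pop = pop, coef = coef, re = re, res = res,
                 pk_catalog = pk_catalog,
                 outer_maxit = outer_maxit, outer_reltol = outer_reltol,
                 inner_maxit = inner_maxit, inner_reltol = inner_reltol,
                 hessian = hessian, se = se),
            class = "ua_fitspec")
}

# ---- dataset preparation ---------------------------------------------------

# Split a ua_dataset into per-subject structures with prebuilt exposures.
prepare_subjects <- function(dataset, pk_catalog = default_pk_catalog(),
                             use_serum_override = FALSE) {
  ids <- unique(dataset$ID)
  lapply(ids, function(id) {
    d <- dataset[dataset$ID == id, , drop = FALSE]
    cov <- subject_covariates(egfr = d$EGFR[1], weight = d$WEIGHT[1],
                              asian = d$ASIAN[1] > 0,
                              status = c("healthy", "asymptomatic",
                                         "symptomatic")[d$STATUS[1] + 1])
    doses <- d[d$EVID == 1, , drop = FALSE]
    drugs_dosed <- unique(doses$DRUG)
    ver_codosed <- any(grepl("^verinurad", drugs_dosed))
    exposures <- list()
    for (dr in drugs_dosed) {
      dd <- doses[doses$DRUG == dr, , drop = FALSE]
      pk <- pk_apply_covariates(pk_catalog[[dr]], cov,
                                ver_codosed = ver_codosed)
      ex <- exposure_from_doses(dr, dd$TIME, dd$AMT, pk)
      exposures[[ex$drug]] <- ex
    }
    obs <- d[d$EVID == 0, , drop = FALSE]
    serum <- obs[obs$CMT == 1, , drop = FALSE]
    urine <- obs[obs$CMT == 2, , drop = FALSE]
    times <- sort(unique(c(0, serum$TIME, urine$TSTART, urine$TIME)))
    list(id = id, cov = cov, renal = renal_context(cov$egfr),
         exposures = exposures,
         pd_drugs = names(exposures),
         serum_t = serum$TIME, serum_y = serum$DV,
         urine_t0 = urine$TSTART, urine_t1 = urine$TIME,
         urine_y = urine$DV,
         sim_times = times,
         serum_idx = match(serum$TIME, times),
         urine_idx0 = match(urine$TSTART, times),
         urine_idx1 = match(urine$TIME, times),
         serum_override = use_serum_override)
  })
}

# Exposure profile from explicit dose records (irregular times allowed).
exposure_from_doses <- function(drug, times, amounts, pk) {
  if (length(times) > 64)
    stop("at most 64 dose records per drug per subject are supported")
  mode <- if (pk$dur0 > 0) 2 else 1
  co <- pk_impulse_coefs(pk)
  block <- numeric(138)
  block[1] <- mode
  block[2] <- pk$lag
  block[3] <- max(pk$dur0, 1e-8)
  block[4:6] <- co$cc
  block[7:9] <- co$mu
  block[10] <- length(times)
  idx <- seq_along(times)
  block[10 + 2 * idx - 1] <- times
  block[10 + 2 * idx] <- amounts
  pd_drug <- switch(drug,
                    verinurad_ER8 = , verinurad_MR4 = "verinurad",
                    febuxostat = "febuxostat",
                    allopurinol = "oxypurinol")
  structure(list(drug = pd_drug, regimen = NULL, pk = pk, block = block),
            class = "ua_exposure")
}

# Active random-effect names for one subject given the model's eta set
subject_eta_names <- function(sub, eta_names) {
  keep <- intersect(eta_names, c("kin", "feua"))
  if ("ec50_ver" %in% eta_names && "verinurad" %in% sub$pd_drugs)
    keep <- c(keep, "ec50_ver")
  if ("ec50_feb" %in% eta_names && "febuxostat" %in% sub$pd_drugs)
    keep <- c(keep, "ec50_feb")
  if ("ec50_oxy" %in% eta_names && "oxypurinol" %in% sub$pd_drugs)
    keep <- c(keep, "ec50_oxy")
  keep
}

# Sensitivity-state column indices (A1-, A2-sensitivity) in the raw lsoda
# output matrix: time, 12 states, 5 outputs.
eta_sens_cols <- function(nm) {
  switch(nm,
         kin = c(6L, 7L),
         feua = c(8L, 9L),
         ec50_ver = c(10L, 11L),
         ec50_feb = , ec50_oxy = c(12L, 13L))
}

# Joint log-likelihood, analytic eta-gradient and Fisher (Gauss-Newton)
# curvature for one prepared subject. Returns a closure evaluating at a
# named eta vector. Calls the compiled model directly (no simulate_ua
# wrapper) since this is the estimation hot path.
make_subject_nll <- function(sub, pop, coef, omega, res,
                             rtol = 1e-8, atol = 1e-10) {
  enames <- colnames(omega)
  k <- length(enames)
  oinv <- if (k) solve(omega) else matrix(0, 0, 0)
  const_pr <- if (k)
    -0.5 * (k * log(2 * pi) +
              as.numeric(determinant(omega, logarithm = TRUE)$modulus))
  else 0
  a_serum <- if (sub$serum_override) res$a_serum_override else res$a_serum
  p_adj <- apply_covariates(pop, sub$cov, coef)
  template <- ua_build_parms(p_adj, sub$renal, sub$exposures)
  scols <- lapply(enames, eta_sens_cols)
  ikin <- match("kin", enames)
  ifeua <- match("feua", enames)
  iec50v <- match("ec50_ver", enames)
  iec50x <- match(c("ec50_feb", "ec50_oxy"), enames)
  iec50x <- iec50x[!is.na(iec50x)][1]
  egfr <- sub$renal$egfr_flow
  times <- sub$sim_times
  function(eta) {
    parms <- template
    if (!is.na(ikin)) parms[1] <- parms[1] * exp(eta[ikin])
    if (!is.na(ifeua))
      parms[2] <- min(parms[2] * exp(eta[ifeua]), 0.999)
    if (!is.na(iec50v)) parms[7] <- parms[7] * exp(eta[iec50v])
    if (!is.na(iec50x)) parms[9] <- parms[9] * exp(eta[iec50x])
    kin_i <- parms[1]; feua_i <- parms[2]
    cl_i <- parms[3]; v1 <- parms[4]
    denom <- cl_i + egfr * feua_i
    a1_0 <- v1 * kin_i / denom
    y0 <- c(a1_0, 0, 0, 0,
            a1_0, 0, -a1_0 * egfr * feua_i / denom, 0,
            0, 0, 0, 0)
    st <- tryCatch(
      suppressWarnings(
        deSolve::lsoda(y0, times, func = "ua_derivs", parms = parms,
                       dllname = "uratesim", initfunc = "ua_init",
                       nout = 5, rtol = rtol, atol = atol,
                       maxsteps = 20000)),
      error = function(e) NULL)
    if (is.null(st) || attr(st, "istate")[1] < 0 ||
        nrow(st) < length(times))
      return(list(ll = -1e10, grad = rep(0, k),
                  hess = diag(1, k), ok = FALSE))
    grad <- rep(0, k)
    hess <- oinv
    ll <- 0
    if (length(sub$serum_t)) {
      f <- st[sub$serum_idx, 2L] / v1 / 10
      r <- sub$serum_y - f
      ll <- ll + sum(dnorm(r, 0, a_serum, log = TRUE))
      J <- vapply(scols, function(cc) st[sub$serum_idx, cc[1]] / v1 / 10,
                  numeric(length(sub$serum_t)))
      J <- matrix(J, ncol = k)
      grad <- grad + drop(crossprod(J, r)) / a_serum^2
      hess <- hess + crossprod(J) / a_serum^2
    }
    if (length(sub$urine_t0)) {
      f <- st[sub$urine_idx1, 3L] - st[sub$urine_idx0, 3L]
      sd2 <- res$a_urine^2 + (res$b_urine * f)^2
      sdv <- sqrt(sd2)
      r <- sub$urine_y - f
      ll <- ll + sum(dnorm(r, 0, sdv, log = TRUE))
      J <- vapply(scols, function(cc)
        st[sub$urine_idx1, cc[2]] - st[sub$urine_idx0, cc[2]],
        numeric(length(sub$urine_t0)))
      J <- matrix(J, ncol = k)
      dsd <- res$b_urine^2 * f / sdv  # dsigma/df
      grad <- grad +
        drop(crossprod(J, r / sd2 + (r^2 / sdv^3 - 1 / sdv) * dsd))
      # Fisher information: J'J/sigma^2 + 2 (dsigma)(dsigma)'/sigma^2
      w <- 1 / sd2 + 2 * dsd^2 / sd2
      hess <- hess + crossprod(J * sqrt(w))
    }
    if (k) {
      ll <- ll + const_pr - 0.5 * drop(eta %*% oinv %*% eta)
      grad <- grad - drop(oinv %*% eta)
    }
    list(ll = ll, grad = grad, hess = hess, ok = TRUE)
  }
}

#' Joint log-likelihood of one subject's data and random effects
#'
#' `log p(y | eta, theta) + log p(eta)`: Gaussian observation terms with
#' the serum additive and urine combined residual models (urine records are
#' compared with the predicted interval amount `A2(end) - A2(start)`), plus
#' the multivariate normal prior over the subject's active random effects.
#'
#' @param dataset A `ua_dataset` (see [read_ua_dataset()]).
#' @param id Subject identifier.
#' @param eta Named random-effect vector over the subject's active effects
#'   (missing names are taken as 0).
#' @param spec A [fit_spec()] supplying parameter values and structure.
#' @return The joint log-likelihood (scalar); attribute `"gradient"` holds
#'   the analytic gradient with respect to `eta`.
#' @export
subject_joint_loglik <- function(dataset, id, eta = numeric(0),
                                 spec = fit_spec()) {
  subs <- prepare_subjects(dataset, spec$pk_catalog)
  sub <- subs[[match(id, vapply(subs, `[[`, numeric(1), "id"))]]
  enames <- subject_eta_names(sub, spec$eta_names)
  omega <- omega_matrix(spec$re,
                        drugs = if (length(sub$pd_drugs)) sub$pd_drugs
                                else "verinurad")
  omega <- omega[intersect(rownames(omega), enames),
                 intersect(rownames(omega), enames), drop = FALSE]
  ev <- setNames(rep(0, ncol(omega)), colnames(omega))
  ev[intersect(names(eta), names(ev))] <-
    eta[intersect(names(eta), names(ev))]
  nll <- make_subject_nll(sub, spec$pop, spec$coef, omega, spec$res)
  out <- nll(ev)
  structure(out$ll, gradient = setNames(out$grad, colnames(omega)))
}

# Inner step: maximise the joint log-likelihood over eta, then apply the
# Laplace curvature correction. Hessian of the joint log-likelihood is a
# central finite difference of the analytic gradient.
laplace_subject <- function(sub, pop, coef, omega, res, eta_start = NULL,
                            inner_maxit = 100, inner_reltol = 1e-10,
                            hess_h = 1e-3, hessian = "fd") {
  k <- ncol(omega)
  f <- make_subject_nll(sub, pop, coef, omega, res)
  if (is.null(eta_start)) eta_start <- rep(0, k)
  cache <- new.env(parent = emptyenv())
  evalf <- function(eta) {
    key <- paste(format(eta, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- f(eta)
      cache$key <- key
    }
    cache$val
  }
  # Damped Newton ascent with the analytic gradient and the positive
  # definite Fisher curvature; the box |eta| <= 5 (a factor e^5 on the
  # parameter) keeps line searches away from overflow regimes of the ODE.
  # Self-contained so the outer quasi-Newton optimiser can never be
  # re-entered from inside its own objective.
  newton <- function(eta) {
    ev <- evalf(eta)
    if (!ev$ok) return(NULL)
    for (it in seq_len(inner_maxit)) {
      step <- tryCatch(solve(ev$hess, ev$grad), error = function(e) NULL)
      if (is.null(step)) step <- ev$grad / (max(abs(diag(ev$hess))) + 1)
      lam <- 1
      improved <- FALSE
      for (ls in 1:12) {
        eta_new <- pmin(pmax(eta + lam * step, -5), 5)
        ev_new <- evalf(eta_new)
        if (ev_new$ok && ev_new$ll >= ev$ll) { improved <- TRUE; break }
        lam <- lam / 2
      }
      if (!improved) break
      delta <- ev_new$ll - ev$ll
      eta <- eta_new
      ev <- ev_new
      if (delta < inner_reltol * (abs(ev$ll) + 1) || delta < 1e-10) break
    }
    list(eta = eta, ev = ev)
  }
  sol <- newton(pmin(pmax(eta_start, -4.9), 4.9))
  if (any(eta_start != 0)) {
    # a stale warm start (from a discarded outer trial point) can strand
    # the mode search; restart from the prior mode when that looks better
    ev0 <- evalf(rep(0, k))
    if (is.null(sol) || (ev0$ok && ev0$ll > sol$ev$ll))
      sol <- newton(rep(0, k))
  }
  if (is.null(sol)) return(list(lmarg = -1e8, eta = rep(0, k), ok = FALSE))
  eta_hat <- sol$eta
  ev <- sol$ev
  ll_hat <- ev$ll
  if (hessian == "gn") {
    # Fisher/Gauss-Newton curvature from the sensitivities at the mode
    # (FOCE-style linearisation; no extra model evaluations)
    hess <- evalf(eta_hat)$hess
  } else {
    # exact joint-likelihood Hessian by central differences of the
    # analytic gradient
    hess <- matrix(0, k, k)
    for (j in seq_len(k)) {
      ep <- eta_hat; ep[j] <- ep[j] + hess_h
      em <- eta_hat; em[j] <- em[j] - hess_h
      hess[j, ] <- -(f(ep)$grad - f(em)$grad) / (2 * hess_h)
    }
    hess <- (hess + t(hess)) / 2
  }
  evals <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
  if (min(evals) <= 0)  # guard against indefinite curvature away from a max
    hess <- hess + diag(abs(min(evals)) + 1e-6, k)
  ldet <- determinant(hess, logarithm = TRUE)$modulus
  list(lmarg = ll_hat + 0.5 * k * log(2 * pi) - 0.5 * as.numeric(ldet),
       eta = eta_hat, ok = TRUE)
}

#' Laplace marginal log-likelihood of a dataset
#'
#' Per subject, maximises the joint log-likelihood over the subject's
#' active random effects and applies the Laplace curvature correction
#' (`+ k/2 log(2 pi) - 1/2 log det H` with `H` the negative Hessian at the
#' mode), then sums over subjects. Subjects whose inner optimisation fails
#' are penalised and counted.
#'
#' @inheritParams subject_joint_loglik
#' @param eta_start Optional matrix of warm-start random effects (subjects
#'   in rows).
#' @return The marginal log-likelihood; attributes `"etas"` (empirical
#'   Bayes modes) and `"n_failed"`.
#' @export
laplace_marginal_loglik <- function(dataset, spec = fit_spec(),
                                    eta_start = NULL, hessian = "fd") {
  subs <- prepare_subjects(dataset, spec$pk_catalog)
  out <- marginal_over_subjects(subs, spec$pop, spec$coef, spec$re,
                                spec$res, spec$eta_names,
                                eta_start = eta_start,
                                inner_maxit = spec$inner_maxit,
                                inner_reltol = spec$inner_reltol,
                                hessian = hessian)
  structure(out$total, etas = out$etas, n_failed = out$n_failed)
}

# Shared driver for laplace_marginal_loglik / fit_population.
# hessian = "gn" runs entirely in compiled code (embedded integrator,
# Newton inner step, Fisher curvature); "fd" uses the R path with an exact
# finite-difference Hessian of the analytic gradient.
marginal_over_subjects <- function(subs, pop, coef, re, res, eta_names,
                                   eta_start = NULL, inner_maxit = 100,
                                   inner_reltol = 1e-10, hessian = "fd") {
  if (hessian == "gn")
    return(marginal_compiled(subs, pop, coef, re, res, eta_names,
                             eta_start = eta_start,
                             inner_maxit = inner_maxit,
                             inner_reltol = inner_reltol))
  total <- 0
  n_failed <- 0L
  etas <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    enames <- subject_eta_names(sub, eta_names)
    if (!length(enames)) {
      # no random effects: the marginal is the plain data likelihood
      nll0 <- make_subject_nll(sub, pop, coef,
                               matrix(0, 0, 0,
                                      dimnames = list(NULL, NULL)), res)
      total <- total + nll0(numeric(0))$ll
      etas[[i]] <- numeric(0)
      next
    }
    om_full <- omega_matrix(re, drugs = if (length(sub$pd_drugs))
      sub$pd_drugs else "verinurad")
    keep <- intersect(rownames(om_full), enames)
    om <- om_full[keep, keep, drop = FALSE]
    st <- if (!is.null(eta_start) && !is.null(eta_start[[i]]) &&
              length(eta_start[[i]]) == ncol(om)) eta_start[[i]]
    lp <- laplace_subject(sub, pop, coef, om, res, eta_start = st,
                          inner_maxit = inner_maxit,
                          inner_reltol = inner_reltol, hessian = hessian)
    if (!lp$ok) n_failed <- n_failed + 1L
    total <- total + lp$lmarg
    etas[[i]] <- setNames(lp$eta, colnames(om))
  }
  list(total = total, etas = etas, n_failed = n_failed)
}

# Compiled per-subject marginal (Fisher-curvature Laplace)
marginal_compiled <- function(subs, pop, coef, re, res, eta_names,
                              eta_start = NULL, inner_maxit = 100,
                              inner_reltol = 1e-10,
                              rtol = 1e-8, atol = 1e-10) {
  slot_code <- c(kin = 1L, feua = 2L, ec50_ver = 3L, ec50_feb = 4L,
                 ec50_oxy = 4L)
  om_cache <- new.env(parent = emptyenv())
  total <- 0
  n_failed <- 0L
  etas <- vector("list", length(subs))
  ctrl_base <- c(rtol, atol, inner_maxit, inner_reltol)
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    enames <- subject_eta_names(sub, eta_names)
    p_adj <- apply_covariates(pop, sub$cov, coef)
    template <- ua_build_parms(p_adj, sub$renal, sub$exposures)
    a_ser <- if (sub$serum_override) res$a_serum_override else res$a_serum
    if (!length(enames)) {
      nll0 <- make_subject_nll(sub, pop, coef,
                               matrix(0, 0, 0,
                                      dimnames = list(NULL, NULL)), res)
      total <- total + nll0(numeric(0))$ll
      etas[[i]] <- numeric(0)
      next
    }
    key <- paste(enames, collapse = ",")
    oc <- om_cache[[key]]
    if (is.null(oc)) {
      om_full <- omega_matrix(re, drugs = if (length(sub$pd_drugs))
        sub$pd_drugs else "verinurad")
      keep <- intersect(rownames(om_full), enames)
      om <- om_full[keep, keep, drop = FALSE]
      oc <- list(keep = keep, oinv = solve(om),
                 pconst = -0.5 * (ncol(om) * log(2 * pi) +
                   as.numeric(determinant(om, logarithm = TRUE)$modulus)))
      om_cache[[key]] <- oc
    }
    k <- length(oc$keep)
    st <- if (!is.null(eta_start) && !is.null(eta_start[[i]]) &&
              length(eta_start[[i]]) == k) as.double(eta_start[[i]])
          else double(k)
    out <- .Call(C_ua_marginal, template, slot_code[oc$keep],
                 as.double(sub$sim_times), sub$serum_idx - 1L,
                 as.double(sub$serum_y), sub$urine_idx0 - 1L,
                 sub$urine_idx1 - 1L, as.double(sub$urine_y),
                 c(a_ser, res$a_urine, res$b_urine),
                 oc$oinv, oc$pconst, st, ctrl_base)
    if (out[2] < 1) n_failed <- n_failed + 1L
    total <- total + out[1]
    etas[[i]] <- setNames(out[-(1:2)], oc$keep)
  }
  list(total = total, etas = etas, n_failed = n_failed)
}

# ---- outer parameterisation ------------------------------------------------

theta_transform <- function(nm, value) {
  if (nm %in% c("hyperfeua_asym", "hyperfeua_sym", "asianfeua",
                "hyperec50")) log1p(value)
  else if (nm %in% c("emax_ver", "emax_feb", "emax_oxy"))
    qlogis(value)
  else log(value)
}

theta_untransform <- function(nm, x) {
  if (nm %in% c("hyperfeua_asym", "hyperfeua_sym", "asianfeua",
                "hyperec50")) expm1(x)
  else if (nm %in% c("emax_ver", "emax_feb", "emax_oxy")) plogis(x)
  else exp(x)
}

pack_fit_par <- function(spec) {
  vals <- c(unclass(spec$pop),
            unclass(spec$coef))
  par <- c()
  for (nm in spec$estimate)
    par[paste0("t_", nm)] <- theta_transform(nm, vals[[nm]])
  ex <- spec$re$exact_transform
  for (nm in spec$estimate_omega) {
    cvnm <- paste0("cv_", nm)
    par[paste0("lom_", nm)] <- log(cv_to_omega(spec$re[[cvnm]], ex))
  }
  if (spec$estimate_corr) par["zcorr"] <- atanh(spec$re$corr_kin_feua)
  for (nm in spec$estimate_sigma)
    par[paste0("lsig_", nm)] <- log(spec$res[[nm]])
  par
}

unpack_fit_par <- function(par, spec) {
  pop <- spec$pop
  coef <- spec$coef
  re <- spec$re
  res <- spec$res
  coef_names <- c("hyperfeua_asym", "hyperfeua_sym", "asianfeua",
                  "hyperec50")
  for (nm in spec$estimate) {
    v <- theta_untransform(nm, par[[paste0("t_", nm)]])
    if (nm %in% coef_names) coef[[nm]] <- v else pop[[nm]] <- v
  }
  ex <- re$exact_transform
  for (nm in spec$estimate_omega) {
    om <- exp(par[[paste0("lom_", nm)]])
    re[[paste0("cv_", nm)]] <- omega_to_cv(om, ex)
  }
  if (spec$estimate_corr) re$corr_kin_feua <- tanh(par[["zcorr"]])
  for (nm in spec$estimate_sigma) res[[nm]] <- exp(par[[paste0("lsig_", nm)]])
  list(pop = pop, coef = coef, re = re, res = res)
}

#' Fit the population model to a longitudinal dataset
#'
#' Maximises the Laplace marginal log-likelihood over the transformed
#' population parameters with a quasi-Newton (BFGS) outer optimiser.
#' EC50s of drugs never dosed in the dataset are automatically removed
#' from the estimated set with a warning.
#'
#' @param dataset A `ua_dataset` data.frame (see [read_ua_dataset()]).
#' @param spec A [fit_spec()].
#' @param verbose Print objective values during optimisation.
#' @return Object of class `ua_fit`: list with `pop`, `coef`, `re`, `res`
#'   (estimated objects), `estimates` (named vector on the natural scale),
#'   `objective` (-2 log marginal likelihood), `convergence` (logical),
#'   `counts`, `etas` (per-subject empirical Bayes estimates at the
#'   optimum), `se`/`rse_percent` (when requested), and `spec`.
#' @export
fit_population <- function(dataset, spec = fit_spec(), verbose = FALSE) {
  subs <- prepare_subjects(dataset, spec$pk_catalog)
  dosed <- unique(unlist(lapply(subs, `[[`, "pd_drugs")))
  drop_map <- c(ec50_ver = "verinurad", ec50_feb = "febuxostat",
                ec50_oxy = "oxypurinol")
  for (nm in intersect(names(drop_map), spec$estimate)) {
    if (!(drop_map[[nm]] %in% dosed)) {
      warning("'", nm, "' is not identifiable (drug never dosed); ",
              "fixed at its initial value")
      spec$estimate <- setdiff(spec$estimate, nm)
      spec$estimate_omega <- setdiff(spec$estimate_omega, nm)
    }
  }
  par0 <- pack_fit_par(spec)
  warm <- new.env(parent = emptyenv())
  warm$etas <- NULL
  neval <- 0L
  obj <- function(par) {
    names(par) <- names(par0)
    cur <- unpack_fit_par(par, spec)
    out <- marginal_over_subjects(subs, cur$pop, cur$coef, cur$re,
                                  cur$res, spec$eta_names,
                                  eta_start = warm$etas,
                                  inner_maxit = spec$inner_maxit,
                                  inner_reltol = spec$inner_reltol,
                                  hessian = spec$hessian)
    warm$etas <- out$etas
    neval <<- neval + 1L
    val <- -2 * out$total
    if (verbose && neval %% 10 == 1)
      message("eval ", neval, ": -2LL = ", format(val, digits = 10))
    val
  }
  # box of +-3 on the transformed scale (a factor ~20 on natural-scale
  # parameters) keeps line searches finite; optimum is interior in any
  # reasonably identified problem
  safe_obj <- function(par) {
    v <- tryCatch(obj(par), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- optim(par0, safe_obj, method = "L-BFGS-B",
               lower = par0 - 3, upper = par0 + 3,
               control = list(maxit = spec$outer_maxit,
                              factr = spec$outer_reltol /
                                .Machine$double.eps,
                              ndeps = rep(1e-4, length(par0))))
  names(opt$par) <- names(par0)
  fin <- unpack_fit_par(opt$par, spec)
  final <- tryCatch(
    marginal_over_subjects(subs, fin$pop, fin$coef, fin$re, fin$res,
                           spec$eta_names, eta_start = warm$etas,
                           inner_maxit = spec$inner_maxit,
                           inner_reltol = spec$inner_reltol,
                           hessian = spec$hessian),
    error = function(e) list(total = NA_real_, etas = warm$etas,
                             n_failed = NA_integer_))
  estimates <- c(
    setNames(vapply(spec$estimate, function(nm) {
      v <- c(unclass(fin$pop), unclass(fin$coef))[[nm]]
      as.numeric(v)
    }, numeric(1)), spec$estimate),
    setNames(vapply(spec$estimate_omega, function(nm)
      cv_to_omega(fin$re[[paste0("cv_", nm)]], fin$re$exact_transform),
      numeric(1)),
      if (length(spec$estimate_omega))
        paste0("omega_", spec$estimate_omega) else character(0)),
    if (spec$estimate_corr) c(corr_kin_feua = fin$re$corr_kin_feua),
    setNames(vapply(spec$estimate_sigma, function(nm) fin$res[[nm]],
                    numeric(1)), spec$estimate_sigma))
  se <- rse <- NULL
  if (isTRUE(spec$se)) {
    H <- optimHess(opt$par, obj)
    # obj is -2LL, so the information matrix is H/2
    vc <- tryCatch(solve(H / 2), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) {
      se <- setNames(sqrt(diag(vc)), names(opt$par))
      # on the log/z transformed scale the SD is approximately the relative
      # standard error of the natural-scale parameter
      rse <- 100 * se
    }
  }
  structure(list(pop = fin$pop, coef = fin$coef, re = fin$re, res = fin$res,
                 estimates = estimates, objective = opt$value,
                 convergence = opt$convergence == 0, counts = opt$counts,
                 n_failed = final$n_failed,
                 etas = final$etas, par = opt$par, se = se,
                 rse_percent = rse, n_subjects = length(subs),
                 spec = spec),
            class = "ua_fit")
}

#' @export
print.ua_fit <- function(x, ...) {
  cat("Population uric acid model fit (Laplace)\n")
  cat("  subjects:", x$n_subjects, " -2LL:",
      format(x$objective, digits = 10), "\n")
  cat("  converged:", x$convergence, "\n")
  print(signif(x$estimates, 5))
  invisible(x)
}

#' Empirical Bayes estimates of the random effects
#'
#' Posterior modes of each subject's random effects at fixed population
#' parameters. A subject without observations has mode zero (the prior
#' mode); modes shrink toward zero as data thin.
#'
#' @inheritParams subject_joint_loglik
#' @return data.frame with `ID` and one column per random effect (NA when
#'   a subject does not carry that effect).
#' @export
empirical_bayes <- function(dataset, spec = fit_spec()) {
  subs <- prepare_subjects(dataset, spec$pk_catalog)
  out <- marginal_over_subjects(subs, spec$pop, spec$coef, spec$re,
                                spec$res, spec$eta_names,
                                inner_maxit = spec$inner_maxit,
                                inner_reltol = spec$inner_reltol,
                                hessian = "gn")
  all_names <- spec$eta_names
  df <- data.frame(ID = vapply(subs, `[[`, numeric(1), "id"))
  for (nm in all_names) {
    df[[nm]] <- vapply(seq_along(subs), function(i) {
      e <- out$etas[[i]]
      if (!is.null(e) && nm %in% names(e)) e[[nm]] else NA_real_
    }, numeric(1))
  }
  df
}

#' Visual-predictive-check summary table
#'
#' Simulates `n_rep` replicate datasets under given population parameters
#' and the observed design (same subjects, dose records and sampling
#' times), then compares observed quantiles per time bin with the
#' distribution of the same quantiles across replicates.
#'
#' @inheritParams subject_joint_loglik
#' @param fit A `ua_fit` object (or a [fit_spec()] holding the parameters
#'   to simulate from).
#' @param n_rep Number of replicate datasets.
#' @param probs Quantiles summarised per bin.
#' @param ci Coverage of the replicate band (default 0.90).
#' @param seed RNG seed.
#' @return data.frame with one row per (observation type, time bin,
#'   quantile): observed quantile, replicate-band bounds and median.
#' @export
predictive_check <- function(dataset, fit, n_rep = 100,
                             probs = c(0.05, 0.5, 0.95), ci = 0.90,
                             seed = 1L) {
  spec <- if (inherits(fit, "ua_fit"))
    fit_spec(pop = fit$pop, coef = fit$coef, re = fit$re, res = fit$res,
             eta_names = fit$spec$eta_names,
             pk_catalog = fit$spec$pk_catalog)
  else fit
  set.seed(seed)
  subs <- prepare_subjects(dataset, spec$pk_catalog)
  obs_rows <- dataset[dataset$EVID == 0, , drop = FALSE]
  sim_one_rep <- function() {
    dv <- numeric(nrow(obs_rows))
    pos <- 1L
    for (sub in subs) {
      enames <- subject_eta_names(sub, spec$eta_names)
      eta <- numeric(0)
      if (length(enames)) {
        om_full <- omega_matrix(spec$re, drugs = if (length(sub$pd_drugs))
          sub$pd_drugs else "verinurad")
        keep <- intersect(rownames(om_full), enames)
        om <- om_full[keep, keep, drop = FALSE]
        eta <- setNames(drop(MASS::mvrnorm(1, rep(0, ncol(om)), om)), keep)
      }
      p_i <- individual_params(spec$pop, sub$cov, eta, spec$coef)
      sim <- simulate_ua(p_i, sub$renal, sub$exposures, sub$sim_times)
      st <- attr(sim, "state")
      n_s <- length(sub$serum_t)
      n_u <- length(sub$urine_t0)
      if (n_s) {
        f <- st$a1[sub$serum_idx] / p_i$v1 / 10
        dv[pos:(pos + n_s - 1)] <- observe(f, "serum", spec$res,
                                           sub$serum_override)
        pos <- pos + n_s
      }
      if (n_u) {
        f <- st$a2[sub$urine_idx1] - st$a2[sub$urine_idx0]
        dv[pos:(pos + n_u - 1)] <- observe(f, "urine", spec$res)
        pos <- pos + n_u
      }
    }
    dv
  }
  # observed DV in the same subject-major order as sim_one_rep fills
  ord <- order(match(obs_rows$ID, vapply(subs, `[[`, numeric(1), "id")),
               obs_rows$CMT, obs_rows$TIME)
  obs_rows <- obs_rows[ord, , drop = FALSE]
  bins <- interaction(obs_rows$CMT, obs_rows$TIME, drop = TRUE)
  reps <- replicate(n_rep, sim_one_rep())
  alpha <- (1 - ci) / 2
  rows <- list()
  for (b in levels(bins)) {
    sel <- bins == b
    cmt <- obs_rows$CMT[sel][1]
    tt <- obs_rows$TIME[sel][1]
    for (p in probs) {
      oq <- quantile(obs_rows$DV[sel], p, names = FALSE)
      rq <- apply(reps[sel, , drop = FALSE], 2, quantile, probs = p,
                  names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        type = if (cmt == 1) "serum" else "urine", time = tt,
        n = sum(sel), prob = p, observed = oq,
        sim_lo = quantile(rq, alpha, names = FALSE),
        sim_med = median(rq),
        sim_hi = quantile(rq, 1 - alpha, names = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$type, out$time, out$prob), ]
}
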