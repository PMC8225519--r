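test_that("concentration is zero before first dose plus lag", {
  reg <- dose_regimen("febuxostat", 80, n_doses = 3, start = 10)
  ex <- exposure_profile(reg)
  expect_equal(eval_conc(ex, c(0, 5, 10, 10.29)), rep(0, 4))
  expect_gt(eval_conc(ex, 10.4), 0)
})

test_that("concentrations scale linearly with dose", {
  for (drug in c("verinurad_ER8", "febuxostat", "allopurinol")) {
    ex1 <- exposure_profile(dose_regimen(drug, 10, n_doses = 4))
    ex2 <- exposure_profile(dose_regimen(drug, 20, n_doses = 4))
    tt <- c(1, 7, 25, 60, 90)
    expect_equal(eval_conc(ex2, tt), 2 * eval_conc(ex1, tt),
                 tolerance = 1e-12)
  }
})

test_that("multi-dose profile equals the sum of shifted single doses", {
  set.seed(42)
  tt <- sort(runif(20, 0, 120))
  for (drug in c("verinurad_ER8", "febuxostat")) {
    multi <- exposure_profile(dose_regimen(drug, 12, n_doses = 4))
    singles <- lapply(0:3, function(k)
      exposure_profile(dose_regimen(drug, 12, n_doses = 1, start = 24 * k)))
    sum_single <- Reduce(`+`, lapply(singles, eval_conc, t = tt))
    expect_equal(eval_conc(multi, tt), sum_single, tolerance = 1e-10)
  }
})

test_that("analytic single-dose profile matches a numerical ODE oracle", {
  # independent oracle: integrate the linear depot/central/peripheral
  # system directly with deSolve and compare concentrations
  pk <- pk_params(cl = 7.5, vc = 35, vp = 15, q = 4, ka = 1.5, dur0 = 0,
                  f = 1, lag = 0)
  ex <- exposure_profile(dose_regimen("febuxostat", 80), pk)
  rhs <- function(t, y, parms) {
    with(as.list(parms), {
      list(c(-ka * y[1],
             ka * y[1] - (cl / vc + q / vc) * y[2] + (q / vp) * y[3],
             (q / vc) * y[2] - (q / vp) * y[3]))
    })
  }
  tt <- seq(0, 72, by = 0.5)
  num <- deSolve::lsoda(c(80, 0, 0), tt, rhs,
                        parms = c(cl = 7.5, vc = 35, vp = 15, q = 4,
                                  ka = 1.5),
                        rtol = 1e-10, atol = 1e-12)
  conc_num <- 1000 * num[, 3] / 35   # ng/mL
  expect_equal(eval_conc(ex, tt)[-1], conc_num[-1], tolerance = 1e-4)
})

test_that("zero-order-into-depot profile conserves dose mass", {
  pk <- pk_params(cl = 14, vc = 80, vp = 250, q = 15, ka = 0.15,
                  dur0 = 12, f = 1, lag = 0)
  ex <- exposure_profile(dose_regimen("verinurad_ER8", 12), pk)
  # total eliminated = CL * AUC must equal dose * F (in ng*h/mL * L/h = ug)
  auc <- integrate(function(t) eval_conc(ex, t), 0, Inf,
                   rel.tol = 1e-9)$value
  expect_equal(14 * auc, 12 * 1 * 1000, tolerance = 1e-5)
})

test_that("zero-order duration shrinking recovers first-order absorption", {
  base <- list(cl = 14, vc = 80, vp = 250, q = 15, ka = 0.15, f = 1,
               lag = 0.3)
  pk_fo <- do.call(pk_params, c(base, dur0 = 0))
  pk_zo <- do.call(pk_params, c(base, dur0 = 1e-4))
  ex_fo <- exposure_profile(dose_regimen("verinurad_ER8", 12), pk_fo)
  ex_zo <- exposure_profile(dose_regimen("verinurad_ER8", 12), pk_zo)
  tt <- c(1, 4, 10, 24, 48)
  expect_equal(eval_conc(ex_zo, tt), eval_conc(ex_fo, tt),
               tolerance = 1e-3)
})

test_that("one-compartment cmax occurs at the closed-form tmax", {
  ka <- 1.2
  pk <- pk_params(cl = 6, vc = 30, vp = 0, q = 0, ka = ka, dur0 = 0,
                  f = 1, lag = 0)
  ke <- 6 / 30
  ex <- exposure_profile(dose_regimen("febuxostat", 80, n_doses = 1), pk)
  m <- steady_state_metrics(ex)
  tmax_cf <- log(ka / ke) / (ka - ke)
  expect_equal(m$tmax, tmax_cf, tolerance = 1e-4)
  cmax_cf <- 80 * 1000 / 30 * ka / (ka - ke) *
    (exp(-ke * tmax_cf) - exp(-ka * tmax_cf))
  expect_equal(m$cmax, cmax_cf, tolerance = 1e-6)
})

test_that("steady-state interval AUC equals single-dose total AUC", {
  ex_ss <- exposure_profile(dose_regimen("verinurad_ER8", 12, n_doses = 14))
  ex_1 <- exposure_profile(dose_regimen("verinurad_ER8", 12, n_doses = 1))
  m <- steady_state_metrics(ex_ss)
  auc_inf <- integrate(function(t) eval_conc(ex_1, t), 0, Inf,
                       rel.tol = 1e-9)$value
  expect_equal(m$auc_tau, auc_inf, tolerance = 1e-3)
  expect_lt(abs(m$ss_ratio - 1), 0.01)
})

test_that("a profile far from steady state warns", {
  ex <- exposure_profile(dose_regimen("allopurinol", 300, n_doses = 2))
  expect_warning(steady_state_metrics(ex), "not at steady state")
})

test_that("default verinurad ER8 exposure brackets its EC50 at 12 mg QD", {
  ex <- exposure_profile(dose_regimen("verinurad_ER8", 12, n_doses = 10))
  m <- suppressWarnings(steady_state_metrics(ex))
  trough <- eval_conc(ex, 9 * 24 + 24)
  expect_gt(m$cmax, 29.4)
  expect_lt(trough, 29.4 * 1.2)
  expect_gt(trough, 29.4 * 0.5)
})

test_that("PK covariate models scale clearance and interaction", {
  pk <- default_pk_catalog()$allopurinol
  cov <- subject_covariates(egfr = 45, weight = 100)
  pki <- pk_apply_covariates(pk, cov, ver_codosed = TRUE)
  expect_equal(pki$cl, pk$cl * (45 / 90)^0.6)
  expect_equal(pki$vc, pk$vc * (100 / 80))
  expect_equal(pki$f, pk$f * 0.8)
})
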