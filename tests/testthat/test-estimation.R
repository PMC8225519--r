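test_that("joint log-likelihood matches hand-computed Gaussian terms", {
  dat <- one_eta_dataset(seed = 11)
  spec <- fit_spec(eta_names = "kin")
  ll <- subject_joint_loglik(dat, 1, c(kin = 0), spec)
  # hand computation: drug-free steady state prediction for this subject
  row <- dat[dat$EVID == 0, ][1, ]
  cov <- subject_covariates(egfr = row$EGFR, weight = row$WEIGHT,
                            status = "healthy")
  f <- steady_state_sua(apply_covariates(ua_params(), cov),
                        renal_context(row$EGFR))
  y <- dat$DV[dat$EVID == 0]
  omega <- cv_to_omega(27.76)
  want <- sum(dnorm(y, f, 0.4107, log = TRUE)) +
    dnorm(0, 0, omega, log = TRUE)
  expect_equal(as.numeric(ll), want, tolerance = 1e-6)
  # eta = 0 prior term equals the normal log-density at zero
  ll1 <- subject_joint_loglik(dat, 1, c(kin = 1), spec)
  expect_lt(as.numeric(ll1), as.numeric(ll))
})

test_that("analytic eta-gradient agrees with finite differences", {
  dat <- generate_virtual_study(small_combo_design(n = 2), seed = 19)
  spec <- fit_spec()
  eta <- c(kin = 0.12, feua = -0.21, ec50_ver = 0.07, ec50_feb = -0.1)
  g <- attr(subject_joint_loglik(dat, 2, eta, spec), "gradient")
  # step balances finite-difference truncation against integrator noise
  h <- 1e-3
  for (nm in names(g)) {
    ep <- eta; ep[nm] <- ep[nm] + h
    em <- eta; em[nm] <- em[nm] - h
    fd <- (as.numeric(subject_joint_loglik(dat, 2, ep, spec)) -
             as.numeric(subject_joint_loglik(dat, 2, em, spec))) / (2 * h)
    expect_equal(unname(g[nm]), fd, tolerance = 0.02)
  }
})

test_that("Laplace marginal matches adaptive quadrature on a 1-eta toy", {
  dat <- one_eta_dataset(seed = 11)
  spec <- fit_spec(eta_names = "kin")
  lap <- laplace_marginal_loglik(dat, spec, hessian = "fd")
  integrand <- Vectorize(function(eta)
    exp(as.numeric(subject_joint_loglik(dat, 1, c(kin = eta), spec))))
  quad <- integrate(integrand, -2, 2, rel.tol = 1e-10)$value
  expect_equal(exp(as.numeric(lap)) / quad, 1, tolerance = 1e-3)
  # compiled Fisher-curvature path agrees with the exact-Hessian path here
  gn <- laplace_marginal_loglik(dat, spec, hessian = "gn")
  expect_equal(as.numeric(gn), as.numeric(lap), tolerance = 1e-3)
})

test_that("vanishing Omega reduces the marginal to the joint at eta = 0", {
  dat <- one_eta_dataset(seed = 23)
  spec0 <- fit_spec(eta_names = "kin",
                    re = random_effects_spec(cv_kin = 1e-2))
  lap <- laplace_marginal_loglik(dat, spec0, hessian = "fd")
  ll0 <- as.numeric(subject_joint_loglik(dat, 1, c(kin = 0), spec0))
  prior0 <- dnorm(0, 0, cv_to_omega(1e-2), log = TRUE)
  expect_equal(as.numeric(lap), ll0 - prior0, tolerance = 1e-4)
})

test_that("empirical Bayes estimates are zero without observations and
          track the truth with rich data", {
  dat <- generate_virtual_study(small_combo_design(n = 24), seed = 3)
  # strip subject 1 of all observations (dose rows only)
  dat1 <- dat[!(dat$ID == 1 & dat$EVID == 0), ]
  class(dat1) <- class(dat)
  spec <- fit_spec()
  ebe <- empirical_bayes(dat1, spec)
  expect_equal(unlist(ebe[ebe$ID == 1, c("kin", "feua")]),
               c(kin = 0, feua = 0), tolerance = 1e-8)
  # with data, EBEs correlate strongly with the simulated truth
  ebe_full <- empirical_bayes(dat, spec)
  tr <- attr(dat, "truth")
  expect_gt(cor(ebe_full$kin, tr$eta_kin), 0.7)
  expect_gt(cor(ebe_full$feua, tr$eta_feua), 0.7)
  # and average near zero across subjects
  expect_lt(abs(mean(ebe_full$kin)), 0.3)
})

test_that("rich low-noise data recovers individual random effects", {
  des <- study_design(n_subjects = 4,
                      egfr_range = c(90, 90, 90),
                      weight_range = c(80, 80, 80), frac_asian = 0,
                      status_mix = c(healthy = 1, asymptomatic = 0,
                                     symptomatic = 0),
                      arms = list(list(name = "v12", fraction = 1,
                                       regimens = list(
                                         dose_regimen("verinurad_ER8", 12,
                                                      n_doses = 3)))),
                      serum_times = seq(0, 71, by = 3),
                      urine_intervals = cbind(seq(0, 66, 6),
                                              seq(6, 72, 6)),
                      duration = 72)
  res_small <- residual_spec(a_serum = 0.004, a_urine = 0.03,
                             b_urine = 0.004)
  dat <- generate_virtual_study(des, res = res_small, seed = 12)
  spec <- fit_spec(res = res_small)
  ebe <- empirical_bayes(dat, spec)
  tr <- attr(dat, "truth")
  for (i in seq_len(4)) {
    expect_equal(ebe$kin[i], tr$eta_kin[i], tolerance = 0.01)
    expect_equal(ebe$feua[i], tr$eta_feua[i], tolerance = 0.015)
  }
})

test_that("estimating an undosed drug's EC50 is refused with a warning", {
  dat <- generate_virtual_study(small_combo_design(n = 4), seed = 6)
  spec <- fit_spec(estimate = c("kin", "ec50_oxy"),
                   estimate_omega = character(0), estimate_corr = FALSE,
                   estimate_sigma = character(0), outer_maxit = 1)
  expect_warning(fit_population(dat, spec), "not identifiable")
})

test_that("predictive check is calibrated on model-simulated data and
          collapses at one replicate", {
  dat <- generate_virtual_study(small_combo_design(n = 12), seed = 21)
  spec <- fit_spec()
  pc <- predictive_check(dat, spec, n_rep = 60, seed = 2)
  # observed quantiles should mostly fall inside the 90% replicate bands
  inside <- mean(pc$observed >= pc$sim_lo & pc$observed <= pc$sim_hi)
  expect_gt(inside, 0.75)
  # time bins reproduce the design grid
  expect_setequal(unique(pc$time[pc$type == "serum"]),
                  small_combo_design(1)$serum_times)
  pc1 <- predictive_check(dat, spec, n_rep = 1, seed = 2)
  expect_equal(pc1$sim_lo, pc1$sim_hi)
})
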