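test_that("zero-dose scenario returns the baseline at every quantile", {
  re0 <- random_effects_spec(cv_kin = 1e-6, cv_feua = 1e-6,
                             cv_ec50_ver = 1e-6, corr_kin_feua = 0)
  sp <- scenario_spec(n_subjects = 5, duration = 48, ss_window = c(24, 48),
                      dt = 1, seed = 2)
  s <- simulate_with_variability(sp, re = re0)
  base <- steady_state_sua(typical_asym60(), renal_context(60))
  ep <- s$endpoints
  red <- ep[ep$endpoint == "max_sua_reduction", c("q05", "q50", "q95")]
  expect_equal(unlist(red, use.names = FALSE), rep(0, 3), tolerance = 1e-6)
  sua_band <- s$timecourse[s$timecourse$variable == "sua", ]
  expect_equal(sua_band$q50, rep(base, nrow(sua_band)), tolerance = 1e-5)
})

test_that("quantile bands are ordered at every output point", {
  sp <- scenario_spec(
    regimens = list(dose_regimen("verinurad_ER8", 12, n_doses = 4)),
    n_subjects = 60, duration = 96, ss_window = c(72, 96), dt = 0.5,
    seed = 9)
  s <- simulate_with_variability(sp)
  expect_true(all(s$timecourse$q05 <= s$timecourse$q50 + 1e-12))
  expect_true(all(s$timecourse$q50 <= s$timecourse$q95 + 1e-12))
  expect_true(all(s$endpoints$q05 <= s$endpoints$q50))
  expect_true(all(s$endpoints$q50 <= s$endpoints$q95))
})

test_that("identical scenario and seed reproduce the summary exactly", {
  sp <- scenario_spec(
    regimens = list(dose_regimen("verinurad_ER8", 12, n_doses = 4)),
    n_subjects = 30, duration = 96, ss_window = c(72, 96), dt = 1,
    seed = 123)
  s1 <- simulate_with_variability(sp)
  s2 <- simulate_with_variability(sp)
  expect_identical(s1$endpoints, s2$endpoints)
  expect_identical(s1$timecourse, s2$timecourse)
})

test_that("endpoints on a drug-free run are the baseline values", {
  p <- typical_asym60()
  r <- renal_context(60)
  sim <- simulate_ua(p, r, list(), times = seq(0, 192, 0.5))
  base <- steady_state_sua(p, r)
  e <- compute_endpoints(sim, base, ss_window = c(144, 168))
  expect_equal(e$max_sua_reduction, 0, tolerance = 1e-6)
  expect_equal(e$avg_feua_24h, 100 * p$feua, tolerance = 1e-6)
  expect_equal(e$max_renal_rate, e$baseline_rate, tolerance = 1e-6)
})

test_that("saturating exposures reach the closed-form maximum reductions", {
  p <- typical_asym60()
  r <- renal_context(60)
  base <- steady_state_sua(p, r)
  tt <- seq(0, 2000, 2)
  sim_v <- simulate_ua(p, r,
                       list(verinurad = constant_exposure("verinurad",
                                                          1e9)), tt)
  e_v <- compute_endpoints(sim_v, base, ss_window = c(1900, 2000))
  want <- 100 * (1 - 0.5044 / 3.0244)
  expect_equal(e_v$max_sua_reduction, want, tolerance = 1e-3)
  sim_f <- simulate_ua(p, r,
                       list(febuxostat = constant_exposure("febuxostat",
                                                           1e9)), tt)
  e_f <- compute_endpoints(sim_f, base, ss_window = c(1900, 2000))
  expect_gt(e_f$max_sua_reduction, 99)
})

test_that("uncertainty simulation collapses to the point prediction at
          zero covariance", {
  sp <- scenario_spec(
    regimens = list(dose_regimen("verinurad_ER8", 12, n_doses = 4)),
    n_subjects = 5, n_param_draws = 8, duration = 96,
    ss_window = c(72, 96), dt = 1, seed = 4)
  rse0 <- ua_catalog()$rse
  rse0[] <- 1e-9
  s <- simulate_with_uncertainty(sp, rse = rse0)
  ep <- s$endpoints
  for (i in seq_len(nrow(ep)))
    expect_equal(ep$q05[i], ep$q95[i], tolerance = 1e-5)
})

test_that("uncertainty bands widen monotonically with covariance inflation", {
  sp <- scenario_spec(
    regimens = list(dose_regimen("verinurad_ER8", 12, n_doses = 4)),
    n_param_draws = 60, duration = 96, ss_window = c(72, 96), dt = 1,
    seed = 10)
  widths <- vapply(c(0.5, 2, 8), function(infl) {
    s <- simulate_with_uncertainty(sp, inflate = infl)
    ep <- s$endpoints
    ep$q95[ep$endpoint == "max_sua_reduction"] -
      ep$q05[ep$endpoint == "max_sua_reduction"]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("uncertainty median endpoint sits near the point prediction", {
  sp <- scenario_spec(
    regimens = list(dose_regimen("verinurad_ER8", 12, n_doses = 4)),
    n_param_draws = 150, duration = 96, ss_window = c(72, 96), dt = 0.5,
    seed = 12)
  s <- simulate_with_uncertainty(sp)
  # point prediction from a deterministic run
  p <- typical_asym60()
  r <- renal_context(60)
  ex <- build_exposures(sp$regimens, subject_covariates(
    egfr = 60, status = "asymptomatic"))
  sim <- simulate_ua(p, r, ex, seq(0, 96, 0.5))
  e <- compute_endpoints(sim, steady_state_sua(p, r), c(72, 96))
  ep <- s$endpoints
  med <- ep$q50[ep$endpoint == "max_sua_reduction"]
  expect_equal(med, e$max_sua_reduction, tolerance = 0.05)
})

test_that("dose-response grid is monotone and anchored", {
  feb <- dose_regimen("febuxostat", 80, n_doses = 4)
  sp <- scenario_spec(n_subjects = 5, n_param_draws = 40, duration = 96,
                      ss_window = c(72, 96), dt = 1, seed = 21)
  tab <- dose_response_grid(c(0, 3, 12), feb, sp, method = "uncertainty")
  red <- tab[tab$endpoint == "max_sua_reduction" & !is.na(tab$dose), ]
  expect_true(all(diff(red$q50[order(red$dose)]) > 0))
  placebo <- tab[tab$endpoint == "max_sua_reduction" & is.na(tab$dose), ]
  expect_equal(placebo$q50, 0, tolerance = 1e-6)
  # dose 0 row equals XOI monotherapy
  sp0 <- sp
  sp0$regimens <- list(feb)
  mono <- simulate_with_uncertainty(sp0)
  d0 <- tab[tab$endpoint == "max_sua_reduction" & !is.na(tab$dose) &
              tab$dose == 0, ]
  m0 <- mono$endpoints[mono$endpoints$endpoint == "max_sua_reduction", ]
  expect_equal(d0$q50, m0$q50)
})

test_that("febuxostat dose escalation lowers excretion and exceedance", {
  sp <- scenario_spec(n_subjects = 80, duration = 96, ss_window = c(72, 96),
                      dt = 0.5, seed = 31)
  sel <- combination_selection(12, c(0, 40, 80), sp)
  tab <- sel$table
  expect_true(all(diff(tab$rate_q50) < 0))
  expect_true(all(diff(tab$exceed_frac) <= 0))
  expect_equal(tab$rate_q50[1], max(tab$rate_q50))
  # baseline band upper edge is the exceedance threshold
  expect_equal(unname(sel$baseline["q95"]), sel$threshold_q95)
})

test_that("analytic baseline-rate quantile approximates the Monte Carlo
          quantile within 5%", {
  p <- typical_asym60()
  r <- renal_context(60)
  re <- random_effects_spec()
  q_lin <- baseline_rate_quantile_linearized(p, r, re, 0.95)
  set.seed(88)
  et <- sample_etas(4e4, re, drugs = character(0))
  kin <- p$kin * exp(et[, "kin"])
  x <- r$egfr_flow * p$feua * exp(et[, "feua"])
  q_mc <- quantile(kin * x / (p$cl_i + x), 0.95, names = FALSE)
  expect_equal(q_lin, q_mc, tolerance = 0.05)
})
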