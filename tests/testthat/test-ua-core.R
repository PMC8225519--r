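test_that("eGFR converts to filtration flow at 0.06 L/h per unit", {
  expect_equal(egfr_to_flow(60), 3.6)
  expect_equal(egfr_to_flow(100), 6.0)
  expect_equal(egfr_to_flow(1), 0.06)
  expect_error(egfr_to_flow(0), "positive")
  expect_error(egfr_to_flow(-5), "positive")
})

test_that("XOI production inhibition follows the saturable Emax model", {
  expect_equal(production_rate(43.78, 0, 1.0, 128.0), 43.78)
  expect_equal(production_rate(43.78, 128.0, 1.0, 128.0), 21.89)
  # asymptote kin * (1 - emax), checked at an enormous concentration
  expect_equal(production_rate(43.78, 1e9, 0.84, 13030), 43.78 * 0.16,
               tolerance = 1e-4)
  expect_error(production_rate(43.78, -1, 1, 128), "non-negative")
})

test_that("verinurad stimulation of FEUA follows the additive Emax model", {
  expect_equal(effective_feua(0.077, 0, 0.7, 29.40), 0.077)
  expect_equal(effective_feua(0.077, 29.40, 0.7, 29.40), 0.427)
  expect_equal(effective_feua(0.0906, 1e9, 0.7, 29.40), 0.7906,
               tolerance = 1e-6)
  expect_error(effective_feua(0.077, -2, 0.7, 29.4), "non-negative")
})

test_that("renal excretion is filtered load times effective FEUA", {
  r <- renal_context(60)
  expect_equal(renal_excretion_rate(86.8, r, 0.077), 3.6 * 86.8 * 0.077)
  expect_equal(renal_excretion_rate(0, r, 0.5), 0)
  expect_equal(renal_excretion_rate(100, r, 0.777), 279.72)
})

test_that("drug-free steady state reproduces the closed-form baseline", {
  p <- typical_asym60()
  r <- renal_context(60)
  expect_equal(round(steady_state_sua(p, r), 1), 8.7)
  # healthy subject, eGFR 100
  p2 <- ua_params(feua = 0.0906)
  expect_equal(steady_state_sua(p2, renal_context(100)),
               43.78 / (0.2272 + 6 * 0.0906) / 10, tolerance = 1e-12)
  expect_equal(round(steady_state_sua(p2, renal_context(100)), 2), 5.68)
  # linear in the production rate
  p3 <- p
  p3$kin <- 2 * p$kin
  expect_equal(steady_state_sua(p3, r), 2 * steady_state_sua(p, r))
})

test_that("constant-exposure steady state matches hand arithmetic", {
  p <- typical_asym60()
  r <- renal_context(60)
  expect_equal(steady_state_constant_exposure(p, r, cv = 0, cx = 0),
               steady_state_sua(p, r))
  expect_equal(steady_state_constant_exposure(p, r, cv = 29.40),
               43.78 / (0.2272 + 3.6 * (p$feua + 0.35)) / 10,
               tolerance = 1e-10)
  expect_equal(round(steady_state_constant_exposure(p, r, cv = 29.40), 2),
               2.48)
  expect_equal(
    round(steady_state_constant_exposure(p, r, cv = 29.40, cx = 128,
                                         xoi = "febuxostat"), 2), 1.24)
})

test_that("initial state sits at the drug-free steady state", {
  p <- typical_asym60()
  r <- renal_context(60)
  s0 <- initial_state(p, r)
  expect_equal(s0$a1 / p$v1, steady_state_sua(p, r) * 10)
  expect_equal(s0$a1, 14.11 * 86.8, tolerance = 1e-3)
  expect_equal(s0$a2, 0)
})

test_that("drug-free simulation stays at equilibrium to 1e-6 relative", {
  p <- typical_asym60()
  r <- renal_context(60)
  sim <- simulate_ua(p, r, list(), times = seq(0, 168, by = 1))
  expect_lt(max(abs(sim$sua - sim$sua[1])) / sim$sua[1], 1e-6)
})

test_that("mass balance holds to 1e-6 relative on simulated trajectories", {
  p <- typical_asym60()
  r <- renal_context(60)
  cases <- list(
    list(),
    list(verinurad = constant_exposure("verinurad", 29.4)),
    list(verinurad = exposure_profile(
      dose_regimen("verinurad_ER8", 12, n_doses = 7)),
      febuxostat = exposure_profile(
        dose_regimen("febuxostat", 80, n_doses = 7))),
    list(oxypurinol = exposure_profile(
      dose_regimen("allopurinol", 300, n_doses = 7))))
  for (ex in cases) {
    sim <- simulate_ua(p, r, ex, times = seq(0, 168, by = 0.5))
    expect_lt(mass_balance_error(sim), 1e-6)
    expect_true(all(diff(sim$cum_uua) >= -1e-9))
  }
})

test_that("ODE long-time limit agrees with the closed form to 0.1%", {
  p <- typical_asym60()
  r <- renal_context(60)
  tt <- c(seq(0, 100, 5), seq(150, 2000, 50))
  for (cv in c(0, 29.4)) {
    for (cx in c(0, 400)) {
      ex <- list()
      if (cv > 0) ex$verinurad <- constant_exposure("verinurad", cv)
      if (cx > 0) ex$febuxostat <- constant_exposure("febuxostat", cx)
      sim <- simulate_ua(p, r, ex, tt)
      want <- steady_state_constant_exposure(
        p, r, cv = cv, cx = cx,
        xoi = if (cx > 0) "febuxostat" else "none")
      expect_equal(tail(sim$sua, 1), want, tolerance = 1e-3)
    }
  }
})

test_that("steady-state sUA decreases in drug exposure, renal rate behaves", {
  p <- typical_asym60()
  r <- renal_context(60)
  cvs <- c(0, 5, 15, 30, 60)
  ss_v <- vapply(cvs, function(cv)
    steady_state_constant_exposure(p, r, cv = cv), numeric(1))
  expect_true(all(diff(ss_v) < 0))
  cxs <- c(0, 50, 150, 400, 1000)
  ss_x <- vapply(cxs, function(cx)
    steady_state_constant_exposure(p, r, cx = cx, xoi = "febuxostat"),
    numeric(1))
  expect_true(all(diff(ss_x) < 0))
  # equilibrium renal rate: increasing in verinurad, decreasing in XOI
  rate_v <- vapply(cvs, function(cv) {
    fe <- effective_feua(p$feua, cv, p$emax_ver, p$ec50_ver)
    renal_excretion_rate(
      10 * steady_state_constant_exposure(p, r, cv = cv), r, fe)
  }, numeric(1))
  expect_true(all(diff(rate_v) > 0))
  rate_x <- vapply(cxs, function(cx) {
    renal_excretion_rate(
      10 * steady_state_constant_exposure(p, r, cx = cx,
                                          xoi = "febuxostat"),
      r, p$feua)
  }, numeric(1))
  expect_true(all(diff(rate_x) < 0))
})

test_that("verinurad onset raises FEUA and renal rate, sUA declines", {
  p <- typical_asym60()
  r <- renal_context(60)
  ex <- list(verinurad = constant_exposure("verinurad", 29.4))
  sim <- simulate_ua(p, r, ex, times = seq(0, 300, 0.5))
  # the exposure is on from t = 0 while the state starts at the drug-free
  # steady state: FEUA and the excretion rate jump, sUA then declines
  base_rate <- renal_excretion_rate(10 * steady_state_sua(p, r), r, p$feua)
  expect_gt(sim$feua_eff[1], p$feua + 0.3)
  expect_gt(sim$renal_rate[1], base_rate * 1.5)
  # strictly decreasing towards the new equilibrium
  expect_true(all(diff(sim$sua[1:200]) < 0))
})

test_that("both XOIs at once are rejected", {
  p <- typical_asym60()
  r <- renal_context(60)
  ex <- list(febuxostat = constant_exposure("febuxostat", 100),
             oxypurinol = constant_exposure("oxypurinol", 1000))
  expect_error(simulate_ua(p, r, ex, 0:10), "at most one XOI")
})
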