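test_that("degenerate covariate ranges give constant covariates", {
  des <- study_design(n_subjects = 6,
                      egfr_range = c(90, 90, 90),
                      weight_range = c(70, 70, 70), frac_asian = 1,
                      status_mix = c(healthy = 1, asymptomatic = 0,
                                     symptomatic = 0),
                      arms = list(list(name = "p", fraction = 1,
                                       regimens = list())),
                      serum_times = c(0, 24), urine_intervals = cbind(0, 24),
                      duration = 24)
  set.seed(3)
  covs <- sample_covariates(des)
  expect_true(all(vapply(covs, `[[`, numeric(1), "egfr") == 90))
  expect_true(all(vapply(covs, `[[`, numeric(1), "weight") == 70))
  expect_true(all(vapply(covs, `[[`, logical(1), "asian")))
})

test_that("sampled eGFR median matches the target demographics", {
  des <- study_design(n_subjects = 434,
                      egfr_range = c(12.3, 97, 138.3),
                      weight_range = c(52.6, 84, 147.6),
                      arms = list(list(name = "p", fraction = 1,
                                       regimens = list())),
                      serum_times = c(0, 24), urine_intervals = cbind(0, 24),
                      duration = 24)
  set.seed(7)
  covs <- sample_covariates(des)
  med <- median(vapply(covs, `[[`, numeric(1), "egfr"))
  expect_lt(abs(med - 97) / 97, 0.10)
  rng <- range(vapply(covs, `[[`, numeric(1), "egfr"))
  expect_gte(rng[1], 12.3)
  expect_lte(rng[2], 138.3)
})

test_that("noise-free undosed study reproduces the covariate-specific
          baseline at every serum sample", {
  des <- study_design(n_subjects = 8,
                      egfr_range = c(40, 70, 120),
                      weight_range = c(60, 80, 110), frac_asian = 0.5,
                      status_mix = c(healthy = 0.4, asymptomatic = 0.3,
                                     symptomatic = 0.3),
                      arms = list(list(name = "p", fraction = 1,
                                       regimens = list())),
                      serum_times = c(0, 12, 36),
                      urine_intervals = cbind(0, 24), duration = 48)
  re0 <- random_effects_spec(cv_kin = 1e-8, cv_feua = 1e-8,
                             cv_ec50_ver = 1e-8, corr_kin_feua = 0)
  res0 <- residual_spec(a_serum = 0, a_urine = 0, b_urine = 0)
  dat <- generate_virtual_study(des, re = re0, res = res0, seed = 42)
  serum <- dat[dat$EVID == 0 & dat$CMT == 1, ]
  for (id in unique(serum$ID)) {
    rows <- serum[serum$ID == id, ]
    cov <- subject_covariates(egfr = rows$EGFR[1], weight = rows$WEIGHT[1],
                              asian = rows$ASIAN[1] > 0,
                              status = c("healthy", "asymptomatic",
                                         "symptomatic")[rows$STATUS[1] + 1])
    want <- steady_state_sua(apply_covariates(ua_params(), cov),
                             renal_context(cov$egfr))
    expect_equal(rows$DV, rep(want, nrow(rows)), tolerance = 1e-5)
  }
})

test_that("row counts follow the design bookkeeping", {
  des <- small_combo_design(n = 10)
  dat <- generate_virtual_study(des, seed = 2)
  n_serum <- length(des$serum_times)
  n_urine <- nrow(des$urine_intervals)
  truth <- attr(dat, "truth")
  arm_names <- vapply(des$arms, `[[`, character(1), "name")
  for (id in unique(dat$ID)) {
    d <- dat[dat$ID == id, ]
    arm <- des$arms[[match(truth$arm[truth$ID == id], arm_names)]]
    n_doses <- sum(vapply(arm$regimens, function(r) r$n_doses, numeric(1)))
    expect_equal(sum(d$EVID == 0 & d$CMT == 1), n_serum)
    expect_equal(sum(d$EVID == 0 & d$CMT == 2), n_urine)
    expect_equal(sum(d$EVID == 1), n_doses)
  }
})

test_that("pre-dose serum replicates show the additive serum error", {
  des <- study_design(n_subjects = 400,
                      egfr_range = c(60, 60, 60),
                      weight_range = c(80, 80, 80), frac_asian = 0,
                      status_mix = c(healthy = 0, asymptomatic = 1,
                                     symptomatic = 0),
                      arms = list(list(name = "p", fraction = 1,
                                       regimens = list())),
                      serum_times = c(0, 24), urine_intervals = cbind(0, 24),
                      duration = 24)
  re0 <- random_effects_spec(cv_kin = 1e-8, cv_feua = 1e-8,
                             cv_ec50_ver = 1e-8, corr_kin_feua = 0)
  dat <- generate_virtual_study(des, re = re0, seed = 9)
  serum0 <- dat$DV[dat$EVID == 0 & dat$CMT == 1 & dat$TIME == 0]
  expect_equal(sd(serum0), 0.4107, tolerance = 0.12)
  expect_equal(mean(serum0),
               steady_state_sua(typical_asym60(), renal_context(60)),
               tolerance = 0.01)
})

test_that("generation is reproducible byte-for-byte under a fixed seed", {
  des <- small_combo_design(n = 6)
  d1 <- generate_virtual_study(des, seed = 77)
  d2 <- generate_virtual_study(des, seed = 77)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_ua_dataset(d1, f1)
  write_ua_dataset(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  d3 <- generate_virtual_study(des, seed = 78)
  expect_false(identical(d1$DV, d3$DV))
})

test_that("per-stratum median baseline sUA matches the closed form
          within 2% at n = 2000", {
  des <- study_design(n_subjects = 2000,
                      egfr_range = c(60, 60, 60),
                      weight_range = c(80, 80, 80), frac_asian = 0,
                      status_mix = c(healthy = 0.5, asymptomatic = 0,
                                     symptomatic = 0.5),
                      arms = list(list(name = "p", fraction = 1,
                                       regimens = list())),
                      serum_times = 0, urine_intervals = cbind(0, 24),
                      duration = 24)
  res0 <- residual_spec(a_serum = 0, a_urine = 0, b_urine = 0)
  dat <- generate_virtual_study(des, res = res0, seed = 13)
  serum <- dat[dat$EVID == 0 & dat$CMT == 1, ]
  for (st in c(0L, 2L)) {
    rows <- serum[serum$STATUS == st, ]
    cov <- subject_covariates(egfr = 60,
                              status = if (st == 0) "healthy"
                                       else "symptomatic")
    want <- steady_state_sua(apply_covariates(ua_params(), cov),
                             renal_context(60))
    expect_equal(median(rows$DV), want, tolerance = 0.02)
  }
})

test_that("design templates validate and carry the documented dose levels", {
  for (nm in c("sad_mad", "combo_phase2a", "renal_impairment")) {
    des <- design_from_template(nm)
    expect_s3_class(des, "ua_design")
  }
  combo <- design_from_template("combo_phase2a")
  ver_doses <- sort(unique(unlist(lapply(combo$arms, function(a)
    vapply(a$regimens, function(r)
      if (grepl("^verinurad", r$drug)) r$dose else NA_real_, numeric(1))))))
  expect_equal(ver_doses[!is.na(ver_doses)], c(2.5, 5, 10, 15, 20))
  feb_doses <- sort(unique(unlist(lapply(combo$arms, function(a)
    vapply(a$regimens, function(r)
      if (r$drug == "febuxostat") r$dose else NA_real_, numeric(1))))))
  expect_equal(feb_doses[!is.na(feb_doses)], c(40, 80))
  expect_error(design_from_template("nope"), "unknown template")
})
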