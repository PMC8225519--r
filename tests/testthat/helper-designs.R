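# Shared fixtures: small study designs and typical parameter sets built in
# code at test time.

typical_asym60 <- function() {
  apply_covariates(ua_params(),
                   subject_covariates(egfr = 60, status = "asymptomatic"),
                   covariate_coefficients())
}

# Two-arm design (verinurad mono + verinurad/febuxostat combination) with
# rich serum sampling and interval urine collections over three days.
small_combo_design <- function(n = 20) {
  arms <- list(
    list(name = "v6", fraction = 0.5,
         regimens = list(dose_regimen("verinurad_ER8", 6, n_doses = 3))),
    list(name = "v12f80", fraction = 0.5,
         regimens = list(dose_regimen("verinurad_ER8", 12, n_doses = 3),
                         dose_regimen("febuxostat", 80, n_doses = 3))))
  study_design(n_subjects = n,
               egfr_range = c(55, 90, 130), weight_range = c(60, 84, 120),
               frac_asian = 0.2,
               status_mix = c(healthy = 0.5, asymptomatic = 0.2,
                              symptomatic = 0.3),
               arms = arms,
               serum_times = c(0, 2, 6, 12, 24, 30, 48, 54, 71),
               urine_intervals = cbind(c(0, 6, 12, 18, 24, 30, 36, 42),
                                       c(6, 12, 18, 24, 30, 36, 42, 48)),
               duration = 72)
}

# The parameter-recovery design: verinurad doses spanning 2.5-20 mg with and
# without febuxostat, rich serum sampling, four urine intervals per day over
# two days.
recovery_design <- function(n = 200) {
  mk <- function(nm, frac, regs)
    list(name = nm, fraction = frac, regimens = regs)
  arms <- list(
    mk("v2.5", 0.25, list(dose_regimen("verinurad_ER8", 2.5, n_doses = 3))),
    mk("v10", 0.25, list(dose_regimen("verinurad_ER8", 10, n_doses = 3))),
    mk("v20", 0.25, list(dose_regimen("verinurad_ER8", 20, n_doses = 3))),
    mk("v10f80", 0.25,
       list(dose_regimen("verinurad_ER8", 10, n_doses = 3),
            dose_regimen("febuxostat", 80, n_doses = 3))))
  study_design(n_subjects = n,
               egfr_range = c(55, 90, 130), weight_range = c(60, 84, 120),
               frac_asian = 0.2,
               status_mix = c(healthy = 0.5, asymptomatic = 0.2,
                              symptomatic = 0.3),
               arms = arms,
               serum_times = c(0, 2, 6, 12, 24, 26, 30, 36, 48, 54, 71),
               urine_intervals = cbind(c(0, 6, 12, 18, 24, 30, 36, 42),
                                       c(6, 12, 18, 24, 30, 36, 42, 48)),
               duration = 72)
}

# Single-subject serum-only dataset with only a production-rate random
# effect: the 1-eta toy used for the quadrature oracle.
one_eta_dataset <- function(seed = 11, n_obs = 6) {
  des <- study_design(n_subjects = 1,
                      egfr_range = c(90, 90, 90),
                      weight_range = c(80, 80, 80), frac_asian = 0,
                      status_mix = c(healthy = 1, asymptomatic = 0,
                                     symptomatic = 0),
                      arms = list(list(name = "plc", fraction = 1,
                                       regimens = list())),
                      serum_times = seq(0, 48, length.out = n_obs),
                      urine_intervals = cbind(0, 24), duration = 48)
  dat <- generate_virtual_study(des, seed = seed)
  dat[dat$CMT == 1 | dat$EVID == 1, , drop = FALSE]
}
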