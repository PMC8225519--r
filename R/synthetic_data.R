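# Virtual-study generator: covariate distributions echoing the observed
# demographics, study designs patterned on the clinical program, true
# parameters from the population layer, and NONMEM-style output rows with a
# truth sidecar for recovery testing.

#' Study design for a virtual trial
#'
#' @param n_subjects Number of subjects.
#' @param egfr_range `c(min, median, max)` of eGFR, mL/min/1.73 m^2.
#' @param weight_range `c(min, median, max)` of body weight, kg.
#' @param frac_asian Fraction of Asian subjects.
#' @param status_mix Named fractions over `healthy`, `asymptomatic`,
#'   `symptomatic`; must sum to 1.
#' @param arms List of arms; each arm is a list with elements `name`,
#'   `fraction` (of subjects) and `regimens` (list of [dose_regimen()],
#'   possibly empty for a placebo arm).
#' @param serum_times Serum sampling times, h.
#' @param urine_intervals Two-column matrix of urine collection intervals
#'   `(start, end)`, h; intervals must not overlap.
#' @param duration Study duration, h.
#' @return Object of class `ua_design`.
#' @export
study_design <- function(n_subjects,
                         egfr_range = c(12.3, 97, 138.3),
                         weight_range = c(52.6, 84, 147.6),
                         frac_asian = 0.36,
                         status_mix = c(healthy = 0.35,
                                        asymptomatic = 0.22,
                                        symptomatic = 0.43),
                         arms,
                         serum_times,
                         urine_intervals,
                         duration = max(serum_times, urine_intervals)) {
  stopifnot(n_subjects >= 1)
  for (r in list(egfr_range, weight_range)) {
    if (length(r) != 3 || r[1] > r[2] || r[2] > r[3])
      stop("covariate range must be c(min, median, max) with ",
           "min <= median <= max")
  }
  if (abs(sum(status_mix) - 1) > 1e-8)
    stop("'status_mix' must sum to 1")
  if (frac_asian < 0 || frac_asian > 1) stop("invalid 'frac_asian'")
  fr <- vapply(arms, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("arm fractions must sum to 1")
  ui <- matrix(urine_intervals, ncol = 2)
  if (any(ui[, 2] <= ui[, 1]))
    stop("urine intervals must have end > start")
  o <- order(ui[, 1])
  if (any(ui[o, 1][-1] < ui[o, 2][-nrow(ui)]))
    stop("urine intervals must not overlap")
  if (any(serum_times > duration) || any(ui > duration))
    stop("sampling times must lie within the study duration")
  structure(list(n_subjects = n_subjects, egfr_range = egfr_range,
                 weight_range = weight_range, frac_asian = frac_asian,
                 status_mix = status_mix, arms = arms,
                 serum_times = sort(serum_times), urine_intervals = ui[o, ,
                                                                      drop = FALSE],
                 duration = duration),
            class = "ua_design")
}

# Truncated lognormal matched to a (min, median, max) triple: meanlog at
# the log median; sdlog from the narrower half-range so that truncation
# (by resampling) barely moves the median.
rlnorm_range <- function(n, range3) {
  lo <- range3[1]; md <- range3[2]; hi <- range3[3]
  if (lo == hi) return(rep(md, n))
  sdlog <- min(log(hi / md), log(md / lo)) / 2.5
  if (sdlog <= 0) return(rep(md, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2 * n, meanlog = log(md), sdlog = sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Sample subject covariates from a study design
#'
#' eGFR and body weight are drawn from truncated lognormal distributions
#' matched to the design's median and range; hyperuricemia status and race
#' follow the stated fractions.
#'
#' @param design A [study_design()].
#' @return List of [subject_covariates()] of length `n_subjects`.
#' @export
sample_covariates <- function(design) {
  n <- design$n_subjects
  egfr <- rlnorm_range(n, design$egfr_range)
  wt <- rlnorm_range(n, design$weight_range)
  status <- sample(names(design$status_mix), n, replace = TRUE,
                   prob = design$status_mix)
  asian <- runif(n) < design$frac_asian
  lapply(seq_len(n), function(i)
    subject_covariates(egfr = egfr[i], weight = wt[i], asian = asian[i],
                       status = status[i]))
}

# Deterministic arm assignment honouring the fractions
assign_arms <- function(design) {
  n <- design$n_subjects
  fr <- vapply(design$arms, `[[`, numeric(1), "fraction")
  counts <- diff(c(0, round(cumsum(fr) * n)))
  rep(seq_along(design$arms), counts)[seq_len(n)]
}

#' Generate a virtual study dataset
#'
#' Per subject: samples covariates, assigns an arm, draws correlated
#' lognormal random effects (EC50 effects only for drugs dosed in the
#' subject's arm), builds exposures, simulates the uric acid model and
#' emits dose rows plus noisy serum and interval-urine observations. The
#' true individual parameters and random effects are recorded in a truth
#' sidecar (`attr(x, "truth")`) that the estimation machinery never reads.
#'
#' @param design A [study_design()].
#' @param pop,re,coef,res Population model components.
#' @param pk_catalog PK catalogue.
#' @param seed RNG seed (required for reproducibility).
#' @return A `ua_dataset` data.frame (see [read_ua_dataset()] for the
#'   column dialect) with attribute `truth`.
#' @export
generate_virtual_study <- function(design, pop = ua_params(),
                                   re = random_effects_spec(),
                                   coef = covariate_coefficients(),
                                   res = residual_spec(),
                                   pk_catalog = default_pk_catalog(),
                                   seed = 1L) {
  set.seed(seed)
  covs <- sample_covariates(design)
  arm_idx <- assign_arms(design)
  rows <- list()
  truth <- list()
  n_dropped <- 0L
  for (i in seq_len(design$n_subjects)) {
    cov_i <- covs[[i]]
    arm <- design$arms[[arm_idx[i]]]
    drugs <- regimen_drugs(arm$regimens)
    eta <- sample_etas(1, re,
                       drugs = if (length(drugs)) drugs else "verinurad")[1, ]
    if (!length(drugs)) eta <- eta[c("kin", "feua")]
    p_i <- individual_params(pop, cov_i, eta, coef)
    renal <- renal_context(cov_i$egfr)
    exposures <- build_exposures(arm$regimens, cov_i, pk_catalog)
    ui <- design$urine_intervals
    sim_times <- sort(unique(c(0, design$serum_times, ui[, 1], ui[, 2])))
    sim <- tryCatch(simulate_ua(p_i, renal, exposures, sim_times),
                    error = function(e) NULL)
    if (is.null(sim)) {
      warning("subject ", i, " dropped (simulation failure)")
      n_dropped <- n_dropped + 1L
      next
    }
    st <- attr(sim, "state")
    serum_f <- st$a1[match(design$serum_times, sim_times)] / p_i$v1 / 10
    urine_f <- st$a2[match(ui[, 2], sim_times)] -
      st$a2[match(ui[, 1], sim_times)]
    serum_y <- observe(serum_f, "serum", res)
    urine_y <- observe(urine_f, "urine", res)
    status_code <- match(cov_i$status,
                         c("healthy", "asymptomatic", "symptomatic")) - 1L
    base <- data.frame(ID = i, EGFR = cov_i$egfr, WEIGHT = cov_i$weight,
                       ASIAN = as.integer(cov_i$asian),
                       STATUS = status_code, ARM = arm$name)
    dose_rows <- do.call(rbind, lapply(arm$regimens, function(r) {
      if (r$dose <= 0) return(NULL)
      tt <- r$start + (seq_len(r$n_doses) - 1) * r$interval
      data.frame(TIME = tt, EVID = 1L, CMT = 1L, AMT = r$dose,
                 DRUG = r$drug, DV = NA_real_, MDV = 1L,
                 TSTART = NA_real_)
    }))
    obs_rows <- rbind(
      data.frame(TIME = design$serum_times, EVID = 0L, CMT = 1L,
                 AMT = NA_real_, DRUG = "", DV = serum_y, MDV = 0L,
                 TSTART = NA_real_),
      data.frame(TIME = ui[, 2], EVID = 0L, CMT = 2L, AMT = NA_real_,
                 DRUG = "", DV = urine_y, MDV = 0L, TSTART = ui[, 1]))
    subj <- rbind(dose_rows, obs_rows)
    subj <- subj[order(subj$TIME, -subj$EVID, subj$CMT), , drop = FALSE]
    rows[[length(rows) + 1L]] <- cbind(base, subj, row.names = NULL)
    truth[[length(truth) + 1L]] <- data.frame(
      ID = i, arm = arm$name,
      t(setNames(as.numeric(eta), paste0("eta_", names(eta)))),
      kin = p_i$kin, feua = p_i$feua, ec50_ver = p_i$ec50_ver,
      ec50_feb = p_i$ec50_feb, ec50_oxy = p_i$ec50_oxy)
  }
  out <- do.call(rbind, rows)
  cols <- c("ID", "TIME", "EVID", "CMT", "AMT", "DRUG", "DV", "MDV",
            "TSTART", "EGFR", "WEIGHT", "ASIAN", "STATUS", "ARM")
  out <- out[, cols]
  rownames(out) <- NULL
  truth_df <- do.call(rbind, lapply(truth, function(x) {
    miss <- setdiff(c("eta_kin", "eta_feua", "eta_ec50_ver",
                      "eta_ec50_feb", "eta_ec50_oxy"), names(x))
    for (m in miss) x[[m]] <- NA_real_
    x
  }))
  attr(out, "truth") <- truth_df
  attr(out, "seed") <- seed
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("ua_dataset", "data.frame")
  out
}

#' Built-in study-design templates
#'
#' Structural approximations (reduced sampling density) of designs from
#' the verinurad clinical program; the actual per-study sampling schedules
#' are not public, so these templates mirror arm structure and dose levels
#' only.
#'
#' * `sad_mad`: healthy volunteers, single + multiple once-daily verinurad
#'   dosing at 2.5-15 mg (MR4).
#' * `combo_phase2a`: symptomatic hyperuricemic patients, verinurad
#'   2.5-20 mg (MR4) combined with 40 or 80 mg febuxostat.
#' * `renal_impairment`: single 15 mg dose across a wide eGFR range.
#'
#' @param name Template name.
#' @param n_subjects Optional override of the template's subject count.
#' @return A [study_design()].
#' @export
design_from_template <- function(name = c("sad_mad", "combo_phase2a",
                                          "renal_impairment"),
                                 n_subjects = NULL) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown template '", name[1], "'; available: sad_mad, ",
         "combo_phase2a, renal_impairment"))
  serum_days <- function(days, within = c(0, 1, 2, 4, 8, 12, 16))
    sort(unique(as.numeric(outer(within, (days - 1) * 24, `+`))))
  urine_days <- function(days) {
    starts <- as.numeric(outer(c(0, 6, 12, 18), (days - 1) * 24, `+`))
    cbind(starts, starts + 6)
  }
  if (name == "sad_mad") {
    doses <- c(2.5, 5, 10, 15)
    arms <- lapply(doses, function(d) list(
      name = paste0("ver", d), fraction = 1 / length(doses),
      regimens = list(dose_regimen("verinurad_MR4", d, n_doses = 7))))
    design <- study_design(
      n_subjects = if (is.null(n_subjects)) 48 else n_subjects,
      egfr_range = c(78, 113.4, 138.3), weight_range = c(54.9, 70.4, 101.7),
      frac_asian = 1,
      status_mix = c(healthy = 1, asymptomatic = 0, symptomatic = 0),
      arms = arms, serum_times = serum_days(c(1, 7)),
      urine_intervals = urine_days(c(1, 7)), duration = 7 * 24)
  } else if (name == "combo_phase2a") {
    ver_doses <- c(2.5, 5, 10, 15, 20)
    feb_doses <- c(40, 80)
    combos <- expand.grid(ver = ver_doses, feb = feb_doses)
    arms <- lapply(seq_len(nrow(combos)), function(i) list(
      name = paste0("ver", combos$ver[i], "_feb", combos$feb[i]),
      fraction = 1 / nrow(combos),
      regimens = list(
        dose_regimen("verinurad_MR4", combos$ver[i], n_doses = 7),
        dose_regimen("febuxostat", combos$feb[i], n_doses = 7))))
    design <- study_design(
      n_subjects = if (is.null(n_subjects)) 64 else n_subjects,
      egfr_range = c(57.4, 89.7, 121.1), weight_range = c(63.8, 98.65, 138.7),
      frac_asian = 0.22,
      status_mix = c(healthy = 0, asymptomatic = 0, symptomatic = 1),
      arms = arms, serum_times = serum_days(c(1, 7)),
      urine_intervals = urine_days(c(1, 7)), duration = 7 * 24)
  } else {
    design <- study_design(
      n_subjects = if (is.null(n_subjects)) 31 else n_subjects,
      egfr_range = c(12.3, 74, 106.1), weight_range = c(59, 82.6, 122),
      frac_asian = 0,
      status_mix = c(healthy = 1, asymptomatic = 0, symptomatic = 0),
      arms = list(list(name = "ver15", fraction = 1,
                       regimens = list(dose_regimen("verinurad_MR4", 15)))),
      serum_times = serum_days(1, within = c(0, 1, 2, 4, 8, 12, 24, 48)),
      urine_intervals = urine_days(1), duration = 72)
  }
  design
}
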