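# Synthetic two-arm trial generator. Emulates a wound-sampling trial in
# infected diabetic foot ulcers: staggered recruitment with a fixed
# administrative stop, a 0/4/12/26/39/52/104-week visit schedule, lognormal
# accelerated-failure-time survival, a latent linear mixed model for EQ-5D-3L
# utility (mapped to the nearest-tariff 3L profile), proportional-odds
# hospitalisation categories and logistic antibiotic prescription per
# inter-visit period, Poisson healthcare-contact counts per 4-week recall
# window, and MAR nonresponse of the self-reported streams on top of
# administrative censoring. The generative families deliberately match the
# analysis models so that model fitting is well-specified.

#' Configuration for the synthetic trial generator
#'
#' Defaults are calibrated to the published baseline table of the motivating
#' trial (arm-specific age, sex, ulcer-size distributions), its attrition
#' table (per-visit nonresponse), and arm-level survival anchors; see the
#' methods vignette for the calibration.
#'
#' @param n_per_arm Named counts `c(swab = , tissue = )` (a single number is
#'   used for both arms).
#' @param recruitment_window_weeks Recruitment spread, calendar weeks.
#' @param admin_stop_week Calendar week of the administrative end of
#'   follow-up (trial termination).
#' @param visit_weeks Scheduled visit weeks, strictly increasing from 0.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param baseline,survival,utility,hospitalisation,antibiotics,contacts,missingness
#'   Named coefficient lists for each generative sub-model; any element
#'   supplied replaces the calibrated default.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = c(swab = 75, tissue = 74),
                         recruitment_window_weeks = 155,
                         admin_stop_week = 207,
                         visit_weeks = c(0, 4, 12, 26, 39, 52, 104),
                         seed = 1L,
                         baseline = list(), survival = list(), utility = list(),
                         hospitalisation = list(), antibiotics = list(),
                         contacts = list(), missingness = list()) {
  if (length(n_per_arm) == 1L) n_per_arm <- c(swab = n_per_arm, tissue = n_per_arm)
  n_per_arm <- n_per_arm[c("swab", "tissue")]
  if (any(is.na(n_per_arm)) || any(n_per_arm < 2)) {
    stop("n_per_arm must give at least 2 patients per arm")
  }
  if (visit_weeks[1] != 0 || any(diff(visit_weeks) <= 0)) {
    stop("visit_weeks must be strictly increasing and start at 0")
  }
  def <- list(
    baseline = list(
      age_mean = c(swab = 65.7, tissue = 59.7),
      age_sd = c(swab = 11.39, tissue = 12.98),
      age_range = c(18, 100),
      p_male = c(swab = 0.867, tissue = 0.784),
      area_meanlog = c(swab = log(2.2), tissue = log(1.1)),
      area_sdlog = c(swab = 1.41, tissue = 1.35),
      duration_meanlog = c(swab = log(1.0), tissue = log(2.0)),
      duration_sdlog = c(swab = 1.33, tissue = 1.54),
      n_ulcers_lambda = 0.33
    ),
    survival = list(intercept = 5.22, arm = 0.43, age = -0.02, sex_male = 0,
                    n_ulcers = 0, ulcer_area = 0, ulcer_duration = 0,
                    sigma = 0.98),
    utility = list(
      intercept = 0.511,
      week = c(`0` = 0, `4` = 0.040, `12` = 0.097, `26` = 0.018,
               `39` = -0.107, `52` = -0.042, `104` = -0.369),
      arm_week = c(`0` = 0.056, `4` = 0.086, `12` = -0.063, `26` = 0.054,
                   `39` = 0.070, `52` = -0.069, `104` = 0.228),
      age = 0, sex_male = 0, n_ulcers = 0, ulcer_area = 0, ulcer_duration = 0,
      sd_patient = 0.25, sd_resid = 0.25
    ),
    hospitalisation = list(
      thresholds = qlogis(c(0.70, 0.90, 0.97)),  # cumulative: none, +other, +minor/revasc
      arm = 0.20, age = 0.01, sex_male = 0, n_ulcers = 0, ulcer_area = 0,
      ulcer_duration = 0
    ),
    antibiotics = list(
      intercept = qlogis(0.45), arm = 0.602, age = 0, sex_male = 0,
      n_ulcers = 0, ulcer_area = 0, ulcer_duration = 0,
      drugs = data.frame(
        drug = c("flucloxacillin", "co-amoxiclav", "doxycycline",
                 "clindamycin", "flucloxacillin", "ertapenem", "metronidazole"),
        form = c("500 mg capsule", "500 mg/125 mg tablet", "100 mg capsule",
                 "300 mg capsule", "500 mg vial", "1 g powder vial", "400 mg"),
        units_per_day = c(4, 3, 1, 4, 4, 1, 3),
        duration_days = c(7, 7, 7, 7, 14, 14, 7),
        prob = c(0.33, 0.25, 0.10, 0.10, 0.10, 0.07, 0.05)
      )
    ),
    contacts = list(
      rates = c(gp = 0.6, practice_nurse = 0.8, district_nurse = 1.2,
                foot_clinic = 1.0, outpatient = 0.4, ae = 0.08),
      arm_log_rate = 0.22
    ),
    missingness = list(
      visit_rate = c(`0` = 0.054, `4` = 0.190, `12` = 0.338, `26` = 0.438,
                     `39` = 0.579, `52` = 0.548, `104` = 0.875),
      age = 0.015, prev_utility = -0.30
    )
  )
  cfg <- list(n_per_arm = n_per_arm,
              recruitment_window_weeks = recruitment_window_weeks,
              admin_stop_week = admin_stop_week,
              visit_weeks = visit_weeks, seed = as.integer(seed))
  user <- list(baseline = baseline, survival = survival, utility = utility,
               hospitalisation = hospitalisation, antibiotics = antibiotics,
               contacts = contacts, missingness = missingness)
  for (part in names(def)) {
    cfg[[part]] <- utils::modifyList(def[[part]], user[[part]])
  }
  pr <- c(cfg$baseline$p_male, plogis(cfg$antibiotics$intercept),
          cfg$missingness$visit_rate)
  if (any(pr < 0 | pr > 1)) stop("probability parameters must lie in [0,1]")
  structure(cfg, class = "trial_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Generate baseline covariates for a synthetic trial
#'
#' @param config A [trial_config()].
#' @return Data frame with one row per patient: `patient_id`, `arm`, `age`,
#'   `sex`, `n_ulcers`, `ulcer_area`, `ulcer_duration`, `recruitment_week`.
#' @export
generate_baseline <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  b <- config$baseline
  out <- lapply(c("swab", "tissue"), function(arm) {
    n <- config$n_per_arm[[arm]]
    data.frame(
      arm = arm,
      age = rtrunc_norm(n, b$age_mean[[arm]], b$age_sd[[arm]],
                        b$age_range[1], b$age_range[2]),
      sex = ifelse(rbinom(n, 1, b$p_male[[arm]]) == 1, "male", "female"),
      n_ulcers = 1L + rpois(n, b$n_ulcers_lambda),
      ulcer_area = rlnorm(n, b$area_meanlog[[arm]], b$area_sdlog[[arm]]),
      ulcer_duration = rlnorm(n, b$duration_meanlog[[arm]], b$duration_sdlog[[arm]]),
      recruitment_week = floor(runif(n, 0, config$recruitment_window_weeks + 1))
    )
  })
  out <- do.call(rbind, out)
  out <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

# Linear predictor on the common covariate set. Age is centred at the pooled
# mean so arm-specific age imbalance feeds through the coefficients.
synth_lp <- function(patients, coefs, age_centre) {
  coefs$intercept %||% 0 +
    coefs$arm * (patients$arm == "tissue") +
    coefs$age * (patients$age - age_centre) +
    coefs$sex_male * (patients$sex == "male") +
    coefs$n_ulcers * patients$n_ulcers +
    coefs$ulcer_area * patients$ulcer_area +
    coefs$ulcer_duration * patients$ulcer_duration
}

#' Simulate outcome streams for generated patients
#'
#' Draws a death week from the lognormal accelerated-failure-time model,
#' per-visit EQ-5D-3L profiles from a latent linear mixed model (patient
#' random intercept; latent value mapped to the profile whose tariff score is
#' nearest, ties to the lexicographically smallest profile), per-period
#' hospitalisation categories from a proportional-odds model, antibiotic
#' prescriptions from a logistic model, and 4-week-recall contact counts from
#' Poisson rates. No stream contains observations after death.
#'
#' @param patients Baseline table from [generate_baseline()].
#' @param config The same [trial_config()].
#' @return A list of class `cua_data`: `patients` (with `death_week`,
#'   `followup_end`, `time`, `status` survival columns), `eq5d`,
#'   `admissions`, `antibiotics`, `contacts`, and attributes carrying the
#'   visit schedule.
#' @export
simulate_outcomes <- function(patients, config = trial_config()) {
  set.seed(config$seed + 1L)
  n <- nrow(patients)
  vw <- config$visit_weeks
  age_c <- mean(patients$age)
  tariff <- eq5d_tariff_uk()

  # --- survival: lognormal AFT, death week continuous ---
  sv <- config$survival
  lp <- synth_lp(patients, sv, age_c)
  patients$death_week <- exp(lp + sv$sigma * rnorm(n))
  patients$followup_end <- pmin(max(vw),
                                config$admin_stop_week - patients$recruitment_week)
  patients$time <- pmin(patients$death_week, patients$followup_end)
  patients$status <- as.integer(patients$death_week <= patients$followup_end)

  # --- EQ-5D-3L per visit (alive only) ---
  ut <- config$utility
  b_i <- rnorm(n, 0, ut$sd_patient)
  eq <- expand.grid(patient_id = patients$patient_id, week = vw,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eq <- eq[order(eq$patient_id, eq$week), ]
  ix <- match(eq$patient_id, patients$patient_id)
  alive <- eq$week < patients$death_week[ix]
  eq <- eq[alive, ]
  ix <- ix[alive]
  latent <- ut$intercept +
    ut$week[as.character(eq$week)] +
    ut$arm_week[as.character(eq$week)] * (patients$arm[ix] == "tissue") +
    synth_lp(patients[ix, ], utils::modifyList(ut, list(intercept = 0, arm = 0)), age_c) +
    b_i[ix] + rnorm(nrow(eq), 0, ut$sd_resid)
  prof <- nearest_profile_utility(latent, tariff)$profiles
  eq5d <- cbind(eq, as.data.frame(prof))
  eq5d$miss <- ""
  rownames(eq5d) <- NULL

  # --- per-period hospitalisation (proportional odds) and antibiotics ---
  per <- data.frame(start = vw[-length(vw)], end = vw[-1])
  hp <- config$hospitalisation
  ab <- config$antibiotics
  eta_h <- synth_lp(patients, utils::modifyList(hp, list(intercept = 0)), age_c)
  eta_a <- synth_lp(patients, ab, age_c)
  adm_rows <- list(); ab_rows <- list()
  avg_los <- vapply(unit_costs()$admissions, `[[`, numeric(1), "avg_los_days")
  hosp_levels <- c("none", "other", "minor_amp_revasc", "major_amp")
  other_cats <- c("osteotomy_ipj", "surgical_debridement", "arthroplasty",
                  "osteomyelitis", "cellulitis", "other")
  for (j in seq_len(nrow(per))) {
    at_risk <- which(patients$death_week > per$start[j])
    for (i in at_risk) {
      cum <- plogis(hp$thresholds - eta_h[i])
      pr <- diff(c(0, cum, 1))
      cat_j <- sample(hosp_levels, 1L, prob = pr)
      if (cat_j != "none") {
        adm_cat <- switch(cat_j,
          other = sample(other_cats, 1L),
          minor_amp_revasc = sample(c("minor_amputation", "revascularisation"), 1L),
          major_amp = "major_amputation")
        start <- runif(1, per$start[j], min(per$end[j], patients$death_week[i]))
        los <- max(1L, rpois(1L, avg_los[[adm_cat]]))
        adm_rows[[length(adm_rows) + 1L]] <- data.frame(
          patient_id = patients$patient_id[i], category = adm_cat,
          start_week = floor(start), end_week = floor(start) + ceiling(los / 7),
          los_days = los)
      }
      if (rbinom(1L, 1L, plogis(eta_a[i])) == 1L) {
        k <- sample(nrow(ab$drugs), 1L, prob = ab$drugs$prob)
        ab_rows[[length(ab_rows) + 1L]] <- data.frame(
          patient_id = patients$patient_id[i],
          week = floor(runif(1, per$start[j], min(per$end[j], patients$death_week[i]))),
          drug = ab$drugs$drug[k], form = ab$drugs$form[k],
          units_per_day = ab$drugs$units_per_day[k],
          duration_days = ab$drugs$duration_days[k])
      }
    }
  }
  empty_adm <- data.frame(patient_id = character(), category = character(),
                          start_week = numeric(), end_week = numeric(),
                          los_days = numeric())
  empty_ab <- data.frame(patient_id = character(), week = numeric(),
                         drug = character(), form = character(),
                         units_per_day = numeric(), duration_days = numeric())
  admissions <- if (length(adm_rows)) do.call(rbind, adm_rows) else empty_adm
  antibiotics <- if (length(ab_rows)) do.call(rbind, ab_rows) else empty_ab

  # --- contact counts per 4-week recall window at visits 4+ ---
  ct <- config$contacts
  cc <- expand.grid(patient_id = patients$patient_id, week = vw[-1],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cc <- cc[order(cc$patient_id, cc$week), ]
  ix <- match(cc$patient_id, patients$patient_id)
  cc <- cc[cc$week < patients$death_week[ix], ]
  ix <- match(cc$patient_id, patients$patient_id)
  mult <- exp(ct$arm_log_rate * (patients$arm[ix] == "tissue"))
  for (type in names(ct$rates)) {
    cc[[type]] <- rpois(nrow(cc), ct$rates[[type]] * mult)
  }
  cc$miss <- ""
  rownames(cc) <- NULL

  structure(list(patients = patients, eq5d = eq5d, admissions = admissions,
                 antibiotics = antibiotics, contacts = cc),
            class = "cua_data", visit_weeks = vw, config = config)
}

#' Apply administrative censoring and MAR nonresponse
#'
#' Visits whose calendar week (`recruitment_week` + visit week) falls after
#' the administrative stop are blanked (`miss = "admin"`); remaining
#' self-reported visits (EQ-5D and contact counts, which share a
#' questionnaire) are blanked with a per-visit MAR probability depending on
#' age and the previous observed utility (`miss = "mar"`).
#' Researcher-collected streams (survival, admissions, antibiotics) are never
#' made missing.
#'
#' @param data A `cua_data` list from [simulate_outcomes()].
#' @param config The same [trial_config()].
#' @return The `cua_data` list with missing self-reported values set to `NA`
#'   and `miss` flags filled in.
#' @export
apply_missingness <- function(data, config = trial_config()) {
  set.seed(config$seed + 2L)
  pts <- data$patients
  ms <- config$missingness
  eq <- data$eq5d
  ix <- match(eq$patient_id, pts$patient_id)
  calendar <- pts$recruitment_week[ix] + eq$week
  admin <- calendar > config$admin_stop_week

  # previous utility enters the MAR hazard; rows are sorted patient-then-week
  u_all <- score_eq5d(eq[, EQ5D_DIMENSIONS])
  prev_u <- c(0.55, u_all[-length(u_all)])
  first_of_patient <- c(TRUE, eq$patient_id[-1] != eq$patient_id[-nrow(eq)])
  prev_u[first_of_patient] <- 0.55
  eta <- qlogis(ms$visit_rate[as.character(eq$week)]) +
    ms$age * (pts$age[ix] - mean(pts$age)) +
    ms$prev_utility * (prev_u - 0.55)
  mar <- !admin & runif(nrow(eq)) < plogis(eta)
  eq$miss[admin] <- "admin"
  eq$miss[mar] <- "mar"
  eq[eq$miss != "", EQ5D_DIMENSIONS] <- NA

  cc <- data$contacts
  key_eq <- paste(eq$patient_id, eq$week)
  flag <- setNames(eq$miss, key_eq)
  ccf <- flag[paste(cc$patient_id, cc$week)]
  ccf[is.na(ccf)] <- ""
  cc$miss <- ccf
  cc[cc$miss != "", names(config$contacts$rates)] <- NA

  data$eq5d <- eq
  data$contacts <- cc
  data
}

#' Simulate a complete synthetic trial dataset
#'
#' Convenience wrapper: [generate_baseline()], [simulate_outcomes()] and
#' (optionally) [apply_missingness()] under one seed.
#'
#' @param config A [trial_config()].
#' @param missingness Apply the missingness mechanism (default `TRUE`).
#' @return A `cua_data` list.
#' @export
simulate_trial <- function(config = trial_config(), missingness = TRUE) {
  data <- simulate_outcomes(generate_baseline(config), config)
  if (missingness) data <- apply_missingness(data, config)
  data
}

#' Write / read a trial dataset as CSV tables
#'
#' Writes `patients.csv`, `eq5d.csv`, `admissions.csv`, `antibiotics.csv` and
#' `contacts.csv` (RFC-4180, UTF-8, `NA` for missing) to a directory, and
#' reads them back into a `cua_data` list.
#'
#' @param data A `cua_data` list.
#' @param dir Directory path.
#' @param visit_weeks Visit schedule to attach on read (default recovered
#'   from the EQ-5D table).
#' @return `write_trial_csv` returns `dir` invisibly; `read_trial_csv`
#'   returns a `cua_data` list.
#' @export
write_trial_csv <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "eq5d", "admissions", "antibiotics", "contacts")) {
    write.csv(data[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(dir, visit_weeks = NULL) {
  out <- lapply(c("patients", "eq5d", "admissions", "antibiotics", "contacts"),
                function(nm) read.csv(file.path(dir, paste0(nm, ".csv")),
                                      stringsAsFactors = FALSE))
  names(out) <- c("patients", "eq5d", "admissions", "antibiotics", "contacts")
  for (nm in c("eq5d", "contacts")) out[[nm]]$miss[is.na(out[[nm]]$miss)] <- ""
  if (is.null(visit_weeks)) visit_weeks <- sort(unique(out$eq5d$week))
  structure(out, class = "cua_data", visit_weeks = visit_weeks)
}
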