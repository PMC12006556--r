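# Shared fixtures, built once per test run.

# small complete trial (no missingness) for fit/CGP tests
small_trial <- local({
  dat <- NULL
  function() {
    if (is.null(dat)) {
      dat <<- simulate_trial(trial_config(n_per_arm = c(swab = 40, tissue = 40),
                                          seed = 101L),
                             missingness = FALSE)
    }
    dat
  }
})

# small trial with the default missingness mechanism
small_trial_missing <- local({
  dat <- NULL
  function() {
    if (is.null(dat)) {
      dat <<- simulate_trial(trial_config(n_per_arm = c(swab = 40, tissue = 40),
                                          seed = 202L))
    }
    dat
  }
})

# hand-built miniature dataset: n patients, two visits (0, 4), fully
# observed; a fifth of patients die at week 50 (after the last visit) so the
# survival model always has events
toy_data <- function(n = 40, seed = 7, p_major = 0, p_ab = 0.5) {
  set.seed(seed)
  death_week <- ifelse(runif(n) < 0.2, 50, 1000)
  patients <- data.frame(
    patient_id = sprintf("T%02d", 1:n),
    arm = rep(c("swab", "tissue"), length.out = n),
    age = rnorm(n, 60, 10), sex = sample(c("male", "female"), n, TRUE),
    n_ulcers = 1 + rpois(n, 0.3), ulcer_area = rlnorm(n, 0.5, 1),
    ulcer_duration = rlnorm(n, 0, 1), recruitment_week = 0,
    death_week = death_week, followup_end = 104,
    time = pmin(death_week, 104), status = as.integer(death_week <= 104))
  prof <- eq5d_profiles()
  eq5d <- do.call(rbind, lapply(c(0, 4), function(w) {
    idx <- sample(nrow(prof), n, TRUE)
    cbind(data.frame(patient_id = patients$patient_id, week = w),
          as.data.frame(prof[idx, , drop = FALSE]), miss = "")
  }))
  admissions <- data.frame(
    patient_id = patients$patient_id[rbinom(n, 1, p_major) == 1],
    category = "major_amputation", start_week = 1, end_week = 4)
  admissions$los_days <- rep(19, nrow(admissions))
  ab_ids <- patients$patient_id[rbinom(n, 1, p_ab) == 1]
  antibiotics <- data.frame(
    patient_id = ab_ids,
    week = rep(2, length(ab_ids)), drug = rep("flucloxacillin", length(ab_ids)),
    form = rep("500 mg capsule", length(ab_ids)),
    units_per_day = rep(4, length(ab_ids)),
    duration_days = rep(7, length(ab_ids)))
  contacts <- data.frame(patient_id = patients$patient_id, week = 4,
                         gp = rpois(n, 1), practice_nurse = rpois(n, 1),
                         district_nurse = rpois(n, 1), foot_clinic = rpois(n, 1),
                         outpatient = rpois(n, 0.5), ae = rpois(n, 0.1),
                         miss = "")
  structure(list(patients = patients, eq5d = eq5d, admissions = admissions,
                 antibiotics = antibiotics, contacts = contacts),
            class = "cua_data", visit_weeks = c(0, 4))
}

# assemble a cua_fits list from individually fitted models
as_cua_fits <- function(survival, utility, hospitalisation, antibiotic,
                        othercost, cv) {
  structure(list(survival = survival, utility = utility,
                 hospitalisation = hospitalisation, antibiotic = antibiotic,
                 othercost = othercost, covariates = cv),
            class = "cua_fits")
}
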