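# direct construction of a cua_data-shaped survival dataset
surv_data <- function(time, status, arm = NULL) {
  n <- length(time)
  patients <- data.frame(
    patient_id = sprintf("S%03d", 1:n),
    arm = arm %||% rep(c("swab", "tissue"), length.out = n),
    age = 60, sex = "male", n_ulcers = 1, ulcer_area = 1, ulcer_duration = 1,
    recruitment_week = 0, death_week = ifelse(status == 1, time, Inf),
    followup_end = max(time), time = time, status = status)
  structure(list(patients = patients), class = "cua_data")
}

test_that("uncensored intercept-only AFT recovers log-time mean and SD", {
  set.seed(42)
  n <- 400
  t_obs <- exp(rnorm(n, 4, 0.7))
  fit <- fit_survival(surv_data(t_obs, rep(1L, n)), rhs = "1")
  # closed form: ML estimates are the mean and population SD of log times
  expect_equal(unname(coef(fit)["(Intercept)"]), mean(log(t_obs)), tolerance = 1e-6)
  expect_equal(fit$sigma, sqrt(mean((log(t_obs) - mean(log(t_obs)))^2)),
               tolerance = 1e-5)
})

test_that("survival fitting validates its preconditions", {
  expect_error(fit_survival(surv_data(c(10, 20), c(0L, 0L))), "no deaths")
  expect_error(fit_survival(surv_data(c(-1, 20), c(1L, 1L))), "non-positive")
})

test_that("AIC selects the lognormal family on lognormal data", {
  hits <- vapply(1:30, function(r) {
    set.seed(300 + r)
    n <- 500
    t_obs <- exp(rnorm(n, 4, 0.9))
    cens <- runif(n, 0, 400)
    d <- surv_data(pmin(t_obs, cens), as.integer(t_obs <= cens))
    suppressMessages(as.character(select_survival_family(d))) == "lognormal"
  }, logical(1))
  expect_gte(mean(hits), 26 / 30)
})

test_that("cross-check: AFT coefficients agree with an independent fitter", {
  skip_if_not_installed("flexsurv")
  dat <- small_trial()
  fit <- fit_survival(dat)
  cv <- covariate_frame(dat)
  d <- cbind(cv, time = dat$patients$time, status = dat$patients$status)
  ref <- flexsurv::flexsurvreg(
    survival::Surv(time, status) ~ arm + age_c + sex + n_ulcers +
      ulcer_area + ulcer_duration, data = d, dist = "lnorm")
  expect_equal(unname(coef(fit)["armtissue"]),
               unname(ref$res["armtissue", "est"]), tolerance = 1e-4)
  expect_equal(fit$sigma, unname(ref$res["sdlog", "est"]), tolerance = 1e-4)
})

test_that("mixed model with balanced complete data matches ordinary least squares", {
  set.seed(8)
  n <- 60
  weeks <- c(0, 4, 12)
  cvp <- data.frame(patient_id = sprintf("L%02d", 1:n),
                    arm = rep(c("swab", "tissue"), n / 2),
                    age = rnorm(n, 60, 8),
                    sex = sample(c("male", "female"), n, TRUE),
                    n_ulcers = 1 + rpois(n, 0.3),
                    ulcer_area = runif(n, 1, 4),
                    ulcer_duration = runif(n, 0, 6))
  long <- expand.grid(patient_id = cvp$patient_id, week = weeks,
                      stringsAsFactors = FALSE)
  ix <- match(long$patient_id, cvp$patient_id)
  # no patient random effect in the generating process
  long$utility <- 0.5 + 0.05 * (cvp$arm[ix] == "tissue") +
    0.01 * long$week + rnorm(nrow(long), 0, 0.1)
  long$miss <- ""
  cv <- covariate_frame(list(patients = cvp))
  fit <- fit_utility_lmm(list(), utilities = long, covariates = cv)
  d <- merge(long, cv, by = "patient_id")
  d$week_f <- factor(d$week)
  ols <- lm(utility ~ arm * week_f + age_c + sex + n_ulcers + ulcer_area +
              ulcer_duration, data = d)
  keep <- names(coef(fit))[!is.na(coef(ols)[names(coef(fit))])]
  expect_equal(coef(fit)[keep], coef(ols)[keep], tolerance = 1e-6)
})

test_that("a single observation per patient still yields a usable fit", {
  set.seed(9)
  n <- 50
  cvp <- data.frame(patient_id = sprintf("B%02d", 1:n),
                    arm = rep(c("swab", "tissue"), n / 2),
                    age = rnorm(n, 60, 8),
                    sex = sample(c("male", "female"), n, TRUE),
                    n_ulcers = 1, ulcer_area = runif(n, 1, 4),
                    ulcer_duration = runif(n, 0, 6))
  long <- data.frame(patient_id = cvp$patient_id, week = 0,
                     utility = rnorm(n, 0.5, 0.2), miss = "")
  cv <- covariate_frame(list(patients = cvp))
  fit <- fit_utility_lmm(list(), utilities = long, covariates = cv)
  expect_true(all(is.finite(coef(fit))))
  expect_true(is.finite(fit$sd_resid) || fit$sd_resid >= 0)
})

test_that("all observations missing raises an error", {
  long <- data.frame(patient_id = "X1", week = 0, utility = NA_real_,
                     miss = "mar")
  cv <- covariate_frame(list(patients = data.frame(
    patient_id = "X1", arm = "swab", age = 60, sex = "male", n_ulcers = 1,
    ulcer_area = 1, ulcer_duration = 1)))
  expect_error(fit_utility_lmm(list(), utilities = long, covariates = cv),
               "all observations missing")
})

test_that("intercept-only ordinal fit saturates to observed frequencies", {
  dat <- small_trial()
  fit <- fit_hospitalisation_ordinal(dat, rhs = "1")
  per <- period_table(dat)
  freq <- prop.table(table(per$hosp_cat))
  cum <- plogis(fit$coefficients)
  p_hat <- unname(diff(c(0, cum, 1)))
  expect_equal(p_hat, as.numeric(freq[freq > 0]), tolerance = 1e-4)
})

test_that("ordinal predicted probabilities sum to one for every patient", {
  dat <- small_trial()
  fits <- fit_models(dat)
  f <- fits$hospitalisation
  X <- model.matrix(as.formula(paste("~", f$rhs)), fits$covariates)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  eta <- drop(X %*% coef(f)[seq_len(f$n_beta)])
  zeta <- coef(f)[-seq_len(f$n_beta)]
  cum <- plogis(outer(eta, zeta, function(e, z) z - e))
  p <- cbind(cum, 1) - cbind(0, cum)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_true(all(p >= -1e-12))
  expect_true(all(diff(zeta) > 0))
})

test_that("unobserved ordinal categories merge upward with a warning", {
  dat <- small_trial()
  dat$admissions <- dat$admissions[dat$admissions$category != "major_amputation", ]
  expect_warning(fit_hospitalisation_ordinal(dat), "merged upward")
})

test_that("logistic fit equals the hand-computed log odds ratio on a 2x2 table", {
  # 2x2 table: swab 30/100 prescribed, tissue 45/100
  n <- 200
  cvp <- data.frame(patient_id = sprintf("Q%03d", 1:n),
                    arm = rep(c("swab", "tissue"), each = 100),
                    age = 60, sex = "male", n_ulcers = 1, ulcer_area = 1,
                    ulcer_duration = 1)
  per <- data.frame(patient_id = cvp$patient_id, start = 0, end = 4,
                    hosp_cat = "none",
                    antibiotic = c(rep(1L, 30), rep(0L, 70),
                                   rep(1L, 45), rep(0L, 55)))
  cv <- covariate_frame(list(patients = cvp))
  fit <- fit_antibiotic_logit(list(), periods = per, covariates = cv,
                              rhs = "arm")
  log_or <- log((45 / 55) / (30 / 70))
  expect_equal(unname(coef(fit)["armtissue"]), log_or, tolerance = 1e-6)
})

test_that("balanced null data give a near-zero arm coefficient", {
  set.seed(21)
  dat <- simulate_trial(trial_config(n_per_arm = 400, seed = 61L,
                                     antibiotics = list(arm = 0)),
                        missingness = FALSE)
  fit <- fit_antibiotic_logit(dat)
  se <- sqrt(vcov(fit)["armtissue", "armtissue"])
  expect_lt(abs(coef(fit)["armtissue"]), 3 * se)
})

test_that("perfect separation is reported with the offending covariate", {
  n <- 40
  cvp <- data.frame(patient_id = sprintf("R%02d", 1:n),
                    arm = rep(c("swab", "tissue"), each = n / 2),
                    age = 60, sex = "male", n_ulcers = 1, ulcer_area = 1,
                    ulcer_duration = 1)
  per <- data.frame(patient_id = cvp$patient_id, start = 0, end = 4,
                    hosp_cat = "none",
                    antibiotic = as.integer(cvp$arm == "tissue"))
  cv <- covariate_frame(list(patients = cvp))
  expect_error(fit_antibiotic_logit(list(), periods = per, covariates = cv,
                                    rhs = "arm"),
               "separation.*arm")
})

test_that("information criteria reproduce a hand calculation on a tiny fixture", {
  n <- 5
  cvp <- data.frame(patient_id = sprintf("A%d", 1:n),
                    arm = c("swab", "swab", "tissue", "tissue", "tissue"),
                    age = 60, sex = "male", n_ulcers = 1, ulcer_area = 1,
                    ulcer_duration = 1)
  per <- data.frame(patient_id = cvp$patient_id, start = 0, end = 4,
                    hosp_cat = "none", antibiotic = c(0L, 1L, 0L, 1L, 1L))
  cv <- covariate_frame(list(patients = cvp))
  fit <- fit_antibiotic_logit(list(), periods = per, covariates = cv, rhs = "1")
  p_hat <- mean(per$antibiotic)
  ll <- sum(per$antibiotic * log(p_hat) + (1 - per$antibiotic) * log(1 - p_hat))
  expect_equal(fit$logLik, ll, tolerance = 1e-8)
  expect_equal(fit$AIC, -2 * ll + 2 * 1, tolerance = 1e-8)
  expect_equal(fit$BIC, -2 * ll + 1 * log(n), tolerance = 1e-8)
})

test_that("all five fits share one covariate design", {
  dat <- small_trial()
  fits <- fit_models(dat)
  expect_s3_class(fits, "cua_fits")
  centres <- vapply(fits[c("survival", "utility", "hospitalisation",
                           "antibiotic", "othercost")],
                    `[[`, numeric(1), "age_centre")
  expect_true(all(centres == centres[1]))
  # reconstructing each patient-level design from the stored formulas gives
  # byte-identical matrices
  X_s <- model.matrix(as.formula(paste("~", fits$survival$rhs)), fits$covariates)
  X_a <- model.matrix(as.formula(paste("~", fits$antibiotic$rhs)), fits$covariates)
  X_h <- model.matrix(as.formula(paste("~", fits$hospitalisation$rhs)), fits$covariates)
  expect_identical(X_s, X_a)
  expect_identical(X_s, X_h)
  # variance-covariance matrices are symmetric PSD with the declared layout
  for (f in fits[c("survival", "utility", "hospitalisation", "antibiotic",
                   "othercost")]) {
    expect_true(all(abs(f$vcov - t(f$vcov)) < 1e-10))
    expect_gte(min(eigen(f$vcov, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
    expect_equal(rownames(f$vcov), names(coef(f)))
  }
})

test_that("fits serialise to JSON and read back consistently", {
  dat <- small_trial()
  fits <- fit_models(dat)
  path <- tempfile(fileext = ".json")
  serialise_fits(fits, path)
  back <- jsonlite::read_json(path)
  expect_equal(names(back),
               c("survival", "utility", "hospitalisation", "antibiotic",
                 "othercost"))
  expect_equal(back$survival$coefficients$armtissue,
               unname(coef(fits$survival)["armtissue"]))
  expect_equal(length(back$utility$re_estimates), nrow(dat$patients))
  unlink(path)
})
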