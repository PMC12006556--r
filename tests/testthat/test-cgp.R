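test_that("the predicted survival curve has lognormal anchor points", {
  dat <- small_trial()
  fit <- fit_survival(dat)
  patient <- dat$patients[3, ]
  nd <- data.frame(arm = factor("tissue", levels = c("swab", "tissue")),
                   age_c = patient$age - fit$age_centre,
                   sex = factor(patient$sex, levels = c("female", "male")),
                   n_ulcers = patient$n_ulcers, ulcer_area = patient$ulcer_area,
                   ulcer_duration = patient$ulcer_duration)
  beta <- coef(fit)[setdiff(names(coef(fit)), "Log(scale)")]
  lp <- drop(model.matrix(as.formula(paste("~", fit$rhs)), nd) %*% beta)
  curve <- predict_survival_curve(fit, patient, "tissue",
                                  c(0, exp(lp), 10 * exp(lp)))
  expect_equal(curve$surv[1], 1)                    # S(0) = 1
  expect_equal(curve$surv[2], 0.5, tolerance = 1e-10)  # median at exp(x beta)
  expect_true(all(diff(curve$surv) <= 1e-12))       # non-increasing
  expect_true(all(curve$surv >= 0 & curve$surv <= 1))
  expect_error(predict_survival_curve(fit, patient, "tissue", c(-1, 5)),
               "non-negative")
})

test_that("a degenerate scale collapses the curve to a step at the median", {
  dat <- small_trial()
  fit <- fit_survival(dat)
  fit$sigma <- 0
  patient <- dat$patients[1, ]
  curve <- predict_survival_curve(fit, patient, "swab", seq(0, 300, by = 1))
  expect_true(all(curve$surv %in% c(0, 1)))
  expect_equal(curve$surv[1], 1)
  expect_equal(curve$surv[length(curve$surv)], 0)
})

test_that("the fitted density integrates to one minus the survival curve", {
  dat <- small_trial()
  fit <- fit_survival(dat)
  patient <- dat$patients[5, ]
  curve <- predict_survival_curve(fit, patient, "swab", c(26, 52, 104))
  nd <- data.frame(arm = factor("swab", levels = c("swab", "tissue")),
                   age_c = patient$age - fit$age_centre,
                   sex = factor(patient$sex, levels = c("female", "male")),
                   n_ulcers = patient$n_ulcers, ulcer_area = patient$ulcer_area,
                   ulcer_duration = patient$ulcer_duration)
  beta <- coef(fit)[setdiff(names(coef(fit)), "Log(scale)")]
  lp <- drop(model.matrix(as.formula(paste("~", fit$rhs)), nd) %*% beta)
  for (i in seq_len(nrow(curve))) {
    cdf <- integrate(dlnorm, 0, curve$time[i], meanlog = lp,
                     sdlog = fit$sigma, rel.tol = 1e-10)$value
    expect_equal(1 - curve$surv[i], cdf, tolerance = 1e-6)
  }
})

test_that("expected QALYs reproduce closed-form fixtures", {
  full <- data.frame(time = c(0, 104), surv = 1)
  u1 <- data.frame(week = c(0, 52, 104), utility = 1)
  expect_equal(expected_qaly(full, u1, 52), 1, tolerance = 1e-10)
  u05 <- data.frame(week = c(0, 26, 104), utility = 0.5)
  expect_equal(expected_qaly(full, u05, 26), 0.25, tolerance = 1e-10)
  dead <- data.frame(time = c(0, 104), surv = c(1, 0))
  none <- data.frame(time = c(0, 104), surv = 0)
  expect_equal(expected_qaly(none, u1, 52), 0, tolerance = 1e-10)
  expect_error(expected_qaly(full, data.frame(week = c(0, 26), utility = 1), 52),
               "beyond the last visit week")
})

test_that("the QALY trapezoid matches dense-grid quadrature", {
  dat <- small_trial()
  fit <- fit_survival(dat)
  patient <- dat$patients[7, ]
  # piecewise utility over three visits, non-trivial survival
  u <- data.frame(week = c(0, 26, 52), utility = c(0.8, 0.5, 0.65))
  curve <- predict_survival_curve(fit, patient, "swab", seq(0, 52, by = 0.1))
  got <- expected_qaly(curve, u, 52, grid_step = 0.1)
  dense <- predict_survival_curve(fit, patient, "swab", seq(0, 52, by = 0.001))
  uu <- approx(u$week, u$utility, xout = dense$time)$y
  oracle <- sum(diff(dense$time) *
                  (head(dense$surv * uu, -1) + tail(dense$surv * uu, -1)) / 2) / 52
  expect_equal(got, oracle, tolerance = 1e-4)
  # discounting multiplies the post-week-52 portion by 1/1.035
  curve104 <- predict_survival_curve(fit, patient, "swab", seq(0, 104, by = 0.1))
  u104 <- data.frame(week = c(0, 52, 104), utility = 0.6)
  q_undisc <- expected_qaly(curve104, u104, 104)
  q_disc <- expected_qaly(curve104, u104, 104, discount = TRUE)
  q_yr1 <- expected_qaly(curve104, u104, 52)
  expect_equal(q_disc, q_yr1 + (q_undisc - q_yr1) / 1.035, tolerance = 1e-10)
})

test_that("single-period cost arithmetic and the intercept-only collapse hold", {
  dat <- toy_data(n = 50, seed = 3, p_major = 0.2, p_ab = 0.4)
  cv <- covariate_frame(dat)
  fits <- suppressWarnings(as_cua_fits(
    fit_survival(dat, rhs = "1"),
    fit_utility_lmm(dat, covariates = cv, rhs = "1"),
    fit_hospitalisation_ordinal(dat, covariates = cv, rhs = "1"),
    fit_antibiotic_logit(dat, covariates = cv, rhs = "1"),
    fit_othercost_lmm(dat, covariates = cv, rhs = "1"), cv))
  opts <- cgp_options(survival_weighting = FALSE, sampling = FALSE,
                      category_costs = c(other = 0, minor_amp_revasc = 0,
                                        major_amp = 12878),
                      course_cost = 28 * 0.16)
  res <- cgp_average(fits, dat, 4, opts = opts)
  per <- period_table(dat)
  p_major <- mean(per$hosp_cat == "major_amp")
  p_ab <- mean(per$antibiotic)
  # hand arithmetic: P(category) x category cost, P(prescription) x course
  expect_equal(unname(res$arms["swab", "hospitalisation"]), p_major * 12878,
               tolerance = 1e-6)
  expect_equal(unname(res$arms["swab", "antibiotics"]), p_ab * 28 * 0.16,
               tolerance = 1e-6)
  # intercept-only collapse: expected other cost equals the observed mean
  oc <- othercost_table(dat)
  expect_equal(unname(res$arms["swab", "other"]), mean(oc$window_cost),
               tolerance = 1e-6)
  # the per-patient entry point gives the same single-period arithmetic
  one <- expected_event_costs(fits, dat$patients[1, ], "swab", 4, opts = opts)
  expect_equal(one$hospitalisation, p_major * 12878, tolerance = 1e-6)
  expect_equal(one$total, one$antibiotics + one$hospitalisation + one$other)
  # arms are indistinguishable under intercept-only fits
  expect_equal(res$incremental[["total"]], 0, tolerance = 1e-9)
})

test_that("probability-zero events contribute zero expected cost", {
  dat <- toy_data(n = 40, seed = 5, p_major = 0.2, p_ab = 0)
  cv <- covariate_frame(dat)
  fits <- suppressWarnings(as_cua_fits(
    fit_survival(dat, rhs = "1"),
    fit_utility_lmm(dat, covariates = cv, rhs = "1"),
    fit_hospitalisation_ordinal(dat, covariates = cv, rhs = "1"),
    fit_antibiotic_logit(dat, covariates = cv, rhs = "1"),
    fit_othercost_lmm(dat, covariates = cv, rhs = "1"), cv))
  # zero category costs and a zero prescription probability zero the
  # event-cost components
  opts <- cgp_options(survival_weighting = FALSE, sampling = FALSE,
                      category_costs = c(other = 0, minor_amp_revasc = 0,
                                        major_amp = 0), course_cost = 10)
  res <- cgp_average(fits, dat, 4, opts = opts)
  expect_equal(unname(res$arms["swab", "hospitalisation"]), 0)
  expect_lt(unname(res$arms["swab", "antibiotics"]), 1e-6)
})

test_that("a three-patient logistic fixture matches hand-computed predictions", {
  dat <- toy_data(n = 30, seed = 13, p_major = 0.3, p_ab = 0.5)
  cv3 <- covariate_frame(dat)[1:3, ]
  fits <- suppressWarnings(fit_models(dat))
  f <- fits$antibiotic
  X <- model.matrix(as.formula(paste("~", f$rhs)), transform(cv3, arm = factor(
    "tissue", levels = c("swab", "tissue"))))
  by_hand <- mean(plogis(drop(X %*% coef(f))))
  small <- dat
  small$patients <- dat$patients[1:3, ]
  fits3 <- fits
  fits3$covariates <- cv3
  opts <- cgp_options(survival_weighting = FALSE, sampling = FALSE,
                      category_costs = c(other = 0, minor_amp_revasc = 0,
                                        major_amp = 0), course_cost = 100)
  res <- cgp_average(fits3, small, 4, opts = opts)
  expect_equal(unname(res$arms["tissue", "antibiotics"]), by_hand * 100,
               tolerance = 1e-9)
})

test_that("CGP equals the analytic marginal prediction for linear components", {
  dat <- small_trial()
  fits <- fit_models(dat)
  opts <- cgp_options(survival_weighting = FALSE, sampling = FALSE)
  res <- cgp_average(fits, dat, 52, opts = opts)
  # other-cost component is linear: the population average equals the
  # prediction at the covariate means (random effects average to zero on a
  # balanced frame only up to shrinkage; include their mean explicitly)
  f <- fits$othercost
  cv_mean <- fits$covariates[1, ]
  for (v in c("age_c", "n_ulcers", "ulcer_area", "ulcer_duration")) {
    cv_mean[[v]] <- mean(fits$covariates[[v]])
  }
  for (a in c("swab", "tissue")) {
    nd <- cv_mean[rep(1, length(f$xlevels$week_f)), ]
    nd$arm <- factor(a, levels = c("swab", "tissue"))
    nd$week_f <- factor(f$xlevels$week_f, levels = f$xlevels$week_f)
    X <- model.matrix(as.formula(paste("~", f$rhs)), nd)
    # sex is a factor: replace its column by the sample proportion
    X[, "sexmale"] <- mean(fits$covariates$sex == "male")
    pred <- drop(X[, names(coef(f)), drop = FALSE] %*% coef(f)) +
      mean(f$re_estimates)
    weeks <- as.numeric(f$xlevels$week_f)
    keep <- weeks <= 52
    prev <- c(0, weeks[keep][-sum(keep)])
    marginal <- sum(pred[keep] * (weeks[keep] - prev) / 4)
    expect_equal(unname(res$arms[a, "other"]), marginal, tolerance = 1e-8)
  }
})

test_that("relabelling arms flips the sign of incremental results", {
  dat <- small_trial()
  opts <- cgp_options(survival_weighting = TRUE, sampling = FALSE)
  res1 <- cgp_average(fit_models(dat), dat, 52, opts = opts)
  flip <- dat
  flip$patients$arm <- ifelse(dat$patients$arm == "swab", "tissue", "swab")
  res2 <- cgp_average(fit_models(flip), flip, 52, opts = opts)
  expect_equal(unname(res2$incremental[["qaly"]]),
               -unname(res1$incremental[["qaly"]]), tolerance = 1e-4)
  expect_equal(unname(res2$incremental[["total"]]),
               -unname(res1$incremental[["total"]]), tolerance = 1e-2)
})

test_that("QALYs respect their structural bounds and costs grow with horizon", {
  dat <- small_trial()
  fits <- fit_models(dat)
  res <- lapply(c(26, 52, 104), function(h) cgp_average(fits, dat, h))
  # bound predicted utilities over both counterfactual arms: the QALY area
  # can never exceed horizon/52 times the largest predicted utility
  u_rng <- range(unlist(lapply(c("swab", "tissue"), function(a) {
    dz <- trialcua:::cgp_design_arm(fits, fits$covariates, a, 104)
    matrix(drop(dz$util$X %*% coef(fits$utility)), nrow = dz$n,
           byrow = TRUE) + dz$b_u
  })))
  for (i in seq_along(res)) {
    h <- c(26, 52, 104)[i]
    expect_true(all(res[[i]]$patient$qaly <= h / 52 * max(u_rng, 0) + 1e-9))
    expect_true(all(res[[i]]$patient$qaly >= h / 52 * min(u_rng, 0) - 1e-9))
  }
  for (comp in c("antibiotics", "hospitalisation", "other", "total")) {
    vals <- vapply(res, function(r) unname(r$arms["tissue", comp]), numeric(1))
    expect_true(all(diff(vals) >= -1e-9))
  }
  expect_error(cgp_average(fits, dat, 30), "aligned")
  expect_error(cgp_average(fits, dat, 208), "beyond")
})
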