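# The five regressions of the economic analysis, all on the same explanatory
# set (arm, mean-adjusted age, sex, number of ulcers, ulcer area, ulcer
# duration): lognormal AFT survival, linear mixed models with patient random
# intercepts for EQ-5D utility and other NHS cost, proportional-odds
# hospitalisation category per inter-visit period, and plain logistic
# antibiotic prescription per period (random-effects logits, as in the
# motivating analysis, do not converge at trial-scale n and are deliberately
# not used). Each fit exposes coefficients and a full variance-covariance
# matrix for corrected-group-prognosis prediction and probabilistic
# sensitivity analysis.

COVARIATE_RHS <- "arm + age_c + sex + n_ulcers + ulcer_area + ulcer_duration"

#' Patient-level covariate frame for the common regression design
#'
#' @param data A `cua_data` list.
#' @param age_centre Centring constant for age; defaults to the sample mean
#'   (stored as an attribute so predictions reuse it).
#' @return Data frame with `patient_id`, `arm`, `age_c`, `sex`, `n_ulcers`,
#'   `ulcer_area`, `ulcer_duration` and attribute `age_centre`.
#' @export
covariate_frame <- function(data, age_centre = NULL) {
  p <- data$patients
  if (is.null(age_centre)) age_centre <- mean(p$age)
  out <- data.frame(
    patient_id = p$patient_id,
    arm = factor(p$arm, levels = c("swab", "tissue")),
    age_c = p$age - age_centre,
    sex = factor(p$sex, levels = c("female", "male")),
    n_ulcers = p$n_ulcers,
    ulcer_area = p$ulcer_area,
    ulcer_duration = p$ulcer_duration
  )
  attr(out, "age_centre") <- age_centre
  out
}

#' Derived outcome tables
#'
#' `utility_table` scores the EQ-5D-3L table to long utilities (missing
#' profiles score `NA`); `period_table` reduces the continuously recorded
#' admission and antibiotic streams to one row per patient per inter-visit
#' period at risk (worst hospitalisation category in the period, any
#' antibiotic prescription); `othercost_table` costs each 4-week contact
#' recall window (healthcare-professional contacts and non-admitted visits).
#'
#' @param data A `cua_data` list.
#' @param costs Unit-cost configuration from [unit_costs()].
#' @return A data frame (see Details).
#' @export
utility_table <- function(data) {
  eq <- data$eq5d
  data.frame(patient_id = eq$patient_id, week = eq$week,
             utility = score_eq5d(eq[, EQ5D_DIMENSIONS]),
             miss = eq$miss %||% "")
}

HOSP_LEVELS <- c("none", "other", "minor_amp_revasc", "major_amp")

map_hosp_category <- function(category) {
  out <- ifelse(category == "major_amputation", "major_amp",
         ifelse(category %in% c("minor_amputation", "revascularisation"),
                "minor_amp_revasc", "other"))
  out
}

#' @rdname utility_table
#' @export
period_table <- function(data) {
  vw <- attr(data, "visit_weeks") %||% sort(unique(data$eq5d$week))
  per <- data.frame(start = vw[-length(vw)], end = vw[-1])
  p <- data$patients
  grid <- merge(data.frame(patient_id = p$patient_id, time = p$time),
                per, by = NULL)
  grid <- grid[grid$start < grid$time, , drop = FALSE]
  adm <- data$admissions
  ab <- data$antibiotics
  grid$hosp_cat <- "none"
  grid$antibiotic <- 0L
  gkey <- paste(grid$patient_id, match(grid$start, per$start))
  if (nrow(adm)) {
    lev <- match(map_hosp_category(adm$category), HOSP_LEVELS)
    akey <- paste(adm$patient_id, findInterval(adm$start_week, per$start))
    worst <- tapply(lev, akey, max)
    hit <- match(gkey, names(worst))
    grid$hosp_cat <- ifelse(is.na(hit), "none", HOSP_LEVELS[worst[hit]])
  }
  if (nrow(ab)) {
    key <- paste(ab$patient_id, findInterval(ab$week, per$start))
    grid$antibiotic <- as.integer(gkey %in% key)
  }
  grid$hosp_cat <- factor(grid$hosp_cat, levels = HOSP_LEVELS, ordered = TRUE)
  grid[order(grid$patient_id, grid$start), c("patient_id", "start", "end",
                                             "hosp_cat", "antibiotic")]
}

#' @rdname utility_table
#' @export
othercost_table <- function(data, costs = unit_costs()) {
  cc <- data$contacts
  types <- intersect(names(costs$contacts), names(cc))
  win <- apply(cc[types], 1L, cost_contacts_window, costs = costs)
  data.frame(patient_id = cc$patient_id, week = cc$week, window_cost = win,
             miss = cc$miss %||% "")
}

new_cua_fit <- function(family, model, coefficients, vcov, age_centre,
                        n, extra = list()) {
  ll <- tryCatch(as.numeric(logLik(model)), error = function(e) NA_real_)
  k <- length(coefficients)
  structure(c(list(family = family, model = model, coefficients = coefficients,
                   vcov = vcov, age_centre = age_centre, n = n,
                   logLik = ll, AIC = -2 * ll + 2 * k,
                   BIC = -2 * ll + k * log(n)), extra),
            class = "cua_fit")
}

#' @export
#' @method print cua_fit
print.cua_fit <- function(x, ...) {
  cat("Model fit (", x$family, "), n = ", x$n, "\n", sep = "")
  print(round(x$coefficients, 4))
  cat("AIC", round(x$AIC, 1), " BIC", round(x$BIC, 1), "\n")
  invisible(x)
}

#' @export
coef.cua_fit <- function(object, ...) object$coefficients

#' @export
vcov.cua_fit <- function(object, ...) object$vcov

check_vcov <- function(V, tol = 1e-8) {
  if (any(abs(V - t(V)) > 1e-8)) stop("variance-covariance matrix not symmetric")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop("variance-covariance matrix not positive semi-definite; ",
         "consider a nearest-PSD repair")
  }
  V
}

#' Fit the lognormal accelerated-failure-time survival model
#'
#' Maximum-likelihood AFT fit with right censoring on the common covariate
#' set; the variance-covariance matrix includes the log-scale parameter so
#' that PSA draws keep the scale positive.
#'
#' @param data A `cua_data` list.
#' @param dist Parametric family passed to [survival::survreg()].
#' @param rhs Right-hand side of the regression formula (the common
#'   covariate set by default; `"1"` gives an intercept-only fit).
#' @param covariates Optional covariate frame from [covariate_frame()].
#' @return A `cua_fit` with the AFT scale in `$sigma`.
#' @export
fit_survival <- function(data, dist = "lognormal", covariates = NULL,
                         rhs = COVARIATE_RHS) {
  cv <- covariates %||% covariate_frame(data)
  d <- cbind(cv, time = data$patients$time, status = data$patients$status)
  if (any(d$time <= 0)) stop("non-positive survival times")
  if (sum(d$status) == 0) stop("no deaths observed")
  fml <- as.formula(paste("survival::Surv(time, status) ~", rhs))
  fit <- survival::survreg(fml, data = d, dist = dist,
                           control = survival::survreg.control(
                             maxiter = 500, rel.tolerance = 1e-10))
  theta <- c(fit$coefficients,
             if (nrow(fit$var) > length(fit$coefficients)) c(`Log(scale)` = log(fit$scale)))
  V <- fit$var
  dimnames(V) <- list(names(theta), names(theta))
  new_cua_fit(paste0(dist, "_aft"), fit, theta, check_vcov(V),
              attr(cv, "age_centre"), nrow(d),
              list(sigma = fit$scale, dist = dist, rhs = rhs))
}

#' Select the best-fitting parametric survival family by AIC
#'
#' Fits exponential, Weibull, lognormal and log-logistic AFT models and
#' returns the AIC-minimising family; a BIC disagreement is reported as a
#' message.
#'
#' @param data A `cua_data` list.
#' @return The selected family name, with the AIC/BIC table as attribute
#'   `"fits"`.
#' @export
select_survival_family <- function(data) {
  fams <- c("exponential", "weibull", "lognormal", "loglogistic")
  fits <- lapply(fams, function(f) fit_survival(data, dist = f))
  tab <- data.frame(family = fams,
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
                    BIC = vapply(fits, `[[`, numeric(1), "BIC"))
  best_aic <- fams[which.min(tab$AIC)]
  best_bic <- fams[which.min(tab$BIC)]
  if (best_aic != best_bic) {
    message("AIC selects ", best_aic, " but BIC selects ", best_bic,
            "; returning the AIC choice")
  }
  structure(best_aic, fits = tab)
}

fit_lmm <- function(long, value_col, cv, family_label, rhs = COVARIATE_RHS) {
  long <- long[long$miss == "" & !is.na(long[[value_col]]), , drop = FALSE]
  if (nrow(long) == 0L) stop("all observations missing")
  d <- merge(long, cv, by = "patient_id")
  d$week_f <- factor(d$week)
  d$y <- d[[value_col]]
  # a single observed week degenerates the categorical time structure
  fixed_rhs <- if (rhs == COVARIATE_RHS && nlevels(d$week_f) > 1) {
    paste("arm * week_f +", sub("arm \\+ ", "", rhs))
  } else rhs
  fml <- as.formula(paste("y ~", fixed_rhs, "+ (1 | patient_id)"))
  fit <- suppressMessages(lme4::lmer(fml, data = d, REML = TRUE,
                                     control = lme4::lmerControl(
                                       check.conv.singular = "ignore",
                                       check.nobs.vs.nlev = "ignore",
                                       check.nobs.vs.nRE = "ignore",
                                       check.nobs.vs.rankZ = "ignore")))
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  dimnames(V) <- list(names(beta), names(beta))
  re <- lme4::ranef(fit)$patient_id
  re_vec <- setNames(re[, 1], rownames(re))
  # patients with no observed rows carry a zero (prior-mean) random effect
  re_all <- setNames(rep(0, nrow(cv)), cv$patient_id)
  re_all[names(re_vec)] <- re_vec
  vc <- as.data.frame(lme4::VarCorr(fit))
  new_cua_fit(family_label, fit, beta, check_vcov(V), attr(cv, "age_centre"),
              nrow(d),
              list(re_estimates = re_all,
                   sd_patient = vc$sdcor[vc$grp == "patient_id"],
                   sd_resid = vc$sdcor[vc$grp == "Residual"],
                   weeks = sort(unique(d$week)), rhs = fixed_rhs,
                   xlevels = list(week_f = levels(d$week_f))))
}

#' Fit the utility and other-cost linear mixed models
#'
#' Restricted-ML linear mixed models with a patient random intercept;
#' visit week enters as a categorical effect interacting with arm so that
#' per-week arm contrasts exist. Empirical-Bayes random-effect predictions
#' are returned for corrected-group-prognosis prediction.
#'
#' @param data A `cua_data` list.
#' @param utilities,windows Optional replacement outcome tables (used by the
#'   multiple-imputation pipeline); default derived from `data` with missing
#'   rows dropped (available-case analysis).
#' @param covariates Optional covariate frame from [covariate_frame()].
#' @param costs Unit-cost configuration (other-cost model only).
#' @param rhs Right-hand side of the fixed-effects formula.
#' @return A `cua_fit` with `$re_estimates`, `$sd_patient`, `$sd_resid`.
#' @export
fit_utility_lmm <- function(data, utilities = NULL, covariates = NULL,
                            rhs = COVARIATE_RHS) {
  cv <- covariates %||% covariate_frame(data)
  fit_lmm(utilities %||% utility_table(data), "utility", cv, "utility_lmm", rhs)
}

#' @rdname fit_utility_lmm
#' @export
fit_othercost_lmm <- function(data, windows = NULL, covariates = NULL,
                              costs = unit_costs(), rhs = COVARIATE_RHS) {
  cv <- covariates %||% covariate_frame(data)
  long <- windows %||% othercost_table(data, costs)
  fit_lmm(long, "window_cost", cv, "othercost_lmm", rhs)
}

#' Fit the proportional-odds hospitalisation model
#'
#' Ordinal logistic regression of the per-period hospitalisation category
#' (none < other < minor amputation or revascularisation < major amputation)
#' on the common covariate set. Categories unobserved in the data are merged
#' upward into the next more severe observed category with a warning.
#'
#' @param data A `cua_data` list.
#' @param periods Optional replacement period table from [period_table()].
#' @param rhs Right-hand side of the regression formula.
#' @param covariates Optional covariate frame from [covariate_frame()].
#' @return A `cua_fit`; coefficients hold the covariate effects followed by
#'   the (strictly increasing) thresholds.
#' @export
fit_hospitalisation_ordinal <- function(data, periods = NULL,
                                        covariates = NULL,
                                        rhs = COVARIATE_RHS) {
  cv <- covariates %||% covariate_frame(data)
  per <- periods %||% period_table(data)
  d <- merge(per, cv, by = "patient_id")
  y <- d$hosp_cat
  present <- levels(y)[table(y) > 0]
  if (length(present) < length(levels(y))) {
    absent <- setdiff(levels(y), present)
    warning("hospitalisation categor",
            if (length(absent) > 1) "ies " else "y ",
            paste(absent, collapse = ", "),
            " unobserved; merged upward into the next more severe category")
    map <- vapply(levels(y), function(l) {
      sev <- match(l, levels(y))
      cand <- present[match(present, levels(y)) >= sev]
      if (length(cand)) cand[1] else present[length(present)]
    }, character(1))
    y <- factor(map[as.character(y)], levels = present, ordered = TRUE)
  }
  if (nlevels(y) < 2) stop("fewer than two hospitalisation categories observed")
  d$y <- y
  if (nlevels(y) == 2) {
    # two observed categories: the proportional-odds model reduces exactly to
    # a logistic regression; re-express it on the threshold parameterisation
    d$event <- as.integer(d$y == levels(y)[2])
    fit <- glm(as.formula(paste("event ~", rhs)), data = d,
               family = binomial(),
               control = list(maxit = 500, epsilon = 1e-10))
    b <- coef(fit)
    beta <- b[setdiff(names(b), "(Intercept)")]
    zeta <- setNames(-b[["(Intercept)"]], paste(levels(y), collapse = "|"))
    theta <- c(beta, zeta)
    k <- length(b)
    A <- matrix(0, k, k)               # theta = A b (reorder, negate intercept)
    if (k > 1) for (i in 2:k) A[i - 1, i] <- 1
    A[k, 1] <- -1
    V <- A %*% vcov(fit) %*% t(A)
    dimnames(V) <- list(names(theta), names(theta))
    return(new_cua_fit("ordinal_logit", fit, theta, check_vcov(V),
                       attr(cv, "age_centre"), nrow(d),
                       list(levels = levels(y), n_beta = length(beta),
                            rhs = rhs)))
  }
  fml <- as.formula(paste("y ~", rhs))
  fit <- MASS::polr(fml, data = d, Hess = TRUE, method = "logistic",
                    control = list(maxit = 500, reltol = 1e-10))
  theta <- c(fit$coefficients, fit$zeta)
  if (any(diff(fit$zeta) <= 0)) stop("ordinal thresholds not increasing")
  V <- vcov(fit)[names(theta), names(theta), drop = FALSE]
  new_cua_fit("ordinal_logit", fit, theta, check_vcov(V),
              attr(cv, "age_centre"), nrow(d),
              list(levels = levels(y), n_beta = length(fit$coefficients),
                   rhs = rhs))
}

#' Fit the antibiotic-prescription logistic model
#'
#' Plain (fixed-effects) logistic regression of any-antibiotic-prescription
#' per inter-visit period on the common covariate set. `exp(coef)` of the arm
#' term is the arm odds ratio reported in cost summaries.
#'
#' @inheritParams fit_hospitalisation_ordinal
#' @return A `cua_fit`.
#' @export
fit_antibiotic_logit <- function(data, periods = NULL, covariates = NULL,
                                 rhs = COVARIATE_RHS) {
  cv <- covariates %||% covariate_frame(data)
  per <- periods %||% period_table(data)
  d <- merge(per, cv, by = "patient_id")
  fml <- as.formula(paste("antibiotic ~", rhs))
  fit <- suppressWarnings(glm(fml, data = d, family = binomial(),
                              control = list(maxit = 500, epsilon = 1e-10)))
  eta <- abs(predict(fit, type = "link"))
  if (max(abs(coef(fit)[-1]), 0, na.rm = TRUE) > 15 && all(eta > 7 | fit$fitted.values %in% c(0, 1))) {
    sep <- names(which.max(abs(coef(fit)[-1])))
    stop("perfect separation detected; separating covariate: ", sep)
  }
  beta <- coef(fit)
  new_cua_fit("logit", fit, beta, check_vcov(as.matrix(vcov(fit))),
              attr(cv, "age_centre"), nrow(d), list(rhs = rhs))
}

#' Fit all five regressions on one dataset
#'
#' Fits survival, utility, hospitalisation, antibiotic and other-cost models
#' on byte-identical patient-level covariate designs (asserted), as required
#' for corrected-group-prognosis standardisation and PSA.
#'
#' @param data A `cua_data` list.
#' @param utilities,windows Optional replacement outcome tables (MI pipeline).
#' @param costs Unit-cost configuration from [unit_costs()].
#' @param survival_dist AFT family (default lognormal).
#' @return A list of class `cua_fits` with elements `survival`, `utility`,
#'   `hospitalisation`, `antibiotic`, `othercost`, plus the covariate frame.
#' @export
fit_models <- function(data, utilities = NULL, windows = NULL,
                       costs = unit_costs(), survival_dist = "lognormal") {
  cv <- covariate_frame(data)
  per <- period_table(data)
  fits <- list(
    survival = fit_survival(data, dist = survival_dist, covariates = cv),
    utility = fit_utility_lmm(data, utilities = utilities, covariates = cv),
    hospitalisation = fit_hospitalisation_ordinal(data, periods = per,
                                                  covariates = cv),
    antibiotic = fit_antibiotic_logit(data, periods = per, covariates = cv),
    othercost = fit_othercost_lmm(data, windows = windows, covariates = cv,
                                  costs = costs)
  )
  X <- model.matrix(as.formula(paste("~", COVARIATE_RHS)), data = cv)
  for (f in fits) stopifnot(identical(f$age_centre, attr(cv, "age_centre")))
  structure(c(fits, list(covariates = cv, design = X)), class = "cua_fits")
}

#' Serialise fitted models to JSON
#'
#' Writes coefficients, variance-covariance matrices, dispersion parameters
#' and random-effect predictions for all five fits, enough to reproduce
#' corrected-group-prognosis and PSA results without the original data.
#'
#' @param fits A `cua_fits` list from [fit_models()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialise_fits <- function(fits, path) {
  keep <- c("survival", "utility", "hospitalisation", "antibiotic", "othercost")
  out <- lapply(fits[keep], function(f) {
    list(family = f$family, coefficients = as.list(f$coefficients),
         vcov = unname(f$vcov), sigma = f$sigma,
         sd_patient = f$sd_patient, sd_resid = f$sd_resid,
         re_estimates = as.list(f$re_estimates), levels = f$levels,
         logLik = f$logLik, AIC = f$AIC, BIC = f$BIC, n = f$n)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
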