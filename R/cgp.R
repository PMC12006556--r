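# Corrected group prognosis: every patient is predicted under BOTH arms with
# their own covariates (and empirical-Bayes random intercept), the fitted
# survival curve weights conditional utility (QALY by area under S(t)*u(t))
# and period costs (no cost accrual after death), and predictions are
# averaged over the full population. Incremental results are always
# tissue minus swab.

#' Options for corrected-group-prognosis standardisation
#'
#' @param discount Apply 3.5% discounting to amounts accruing after week 52
#'   (the second year of follow-up).
#' @param rate Annual discount rate (default 0.035).
#' @param grid_step Trapezoid grid step in weeks for the QALY area under
#'   S(t)u(t) (default 0.1; utilities are linearly interpolated between visit
#'   weeks).
#' @param survival_weighting Weight period cost contributions by the
#'   predicted probability of being alive at period start (default `TRUE`).
#' @param category_costs Named expected costs per hospitalisation category
#'   (`other`, `minor_amp_revasc`, `major_amp`); `NULL` estimates them from
#'   the observed admissions via [estimate_event_costs()].
#' @param course_cost Expected cost of one antibiotic course; `NULL`
#'   estimates it from the observed prescriptions.
#' @param sampling Include per-occasion wound-sampling costs in the other
#'   component (default `TRUE`).
#' @param followup_sampling_occasions Expected follow-up sampling occasions
#'   per patient beyond the baseline occasion (default 1).
#' @return A list of class `cgp_options`.
#' @export
cgp_options <- function(discount = FALSE, rate = 0.035, grid_step = 0.1,
                        survival_weighting = TRUE, category_costs = NULL,
                        course_cost = NULL, sampling = TRUE,
                        followup_sampling_occasions = 1) {
  if (rate < 0) stop("discount rate must be non-negative")
  structure(list(discount = discount, rate = rate, grid_step = grid_step,
                 survival_weighting = survival_weighting,
                 category_costs = category_costs, course_cost = course_cost,
                 sampling = sampling,
                 followup_sampling_occasions = followup_sampling_occasions),
            class = "cgp_options")
}

#' Estimate expected event costs from the observed streams
#'
#' Mean observed cost of an admission in each ordinal hospitalisation
#' category and of one antibiotic course, falling back to unit-cost-table
#' constants for categories without observed events (episode cost at average
#' length of stay, plus post-amputation rehabilitation for amputations; the
#' minor-amputation-or-revascularisation category falls back to the midpoint
#' of its two constituent episode costs).
#'
#' @param data A `cua_data` list.
#' @param costs Unit-cost configuration from [unit_costs()].
#' @return List with `category_costs` (named numeric) and `course_cost`.
#' @export
estimate_event_costs <- function(data, costs = unit_costs()) {
  fallback <- c(
    other = costs$admissions$other$cost_per_episode,
    minor_amp_revasc = mean(c(
      costs$admissions$minor_amputation$cost_per_episode + costs$post_amputation_cost,
      costs$admissions$revascularisation$cost_per_episode)),
    major_amp = costs$admissions$major_amputation$cost_per_episode +
      costs$post_amputation_cost
  )
  cat_costs <- fallback
  adm <- resolve_overlapping_admissions(data$admissions, costs)
  if (nrow(adm)) {
    amt <- cost_admission(adm$category, adm$los_days, costs)
    lev <- map_hosp_category(adm$category)
    for (l in unique(lev)) cat_costs[[l]] <- mean(amt[lev == l])
  }
  ab <- data$antibiotics
  course <- if (nrow(ab)) {
    mean(cost_antibiotic_course(ab$drug, ab$form, ab$units_per_day,
                                ab$duration_days, costs))
  } else 50
  list(category_costs = cat_costs, course_cost = course)
}

# parameter vectors at the estimates, in the layout cgp_eval consumes
fit_params <- function(fits) {
  list(survival = fits$survival$coefficients,
       utility = fits$utility$coefficients,
       hospitalisation = fits$hospitalisation$coefficients,
       antibiotic = fits$antibiotic$coefficients,
       othercost = fits$othercost$coefficients)
}

# design matrices for one counterfactual arm, aligned to coefficient names
cgp_design_arm <- function(fits, cv, arm, horizon) {
  nd <- cv
  nd$arm <- factor(arm, levels = levels(cv$arm))
  mm <- function(rhs) model.matrix(as.formula(paste("~", rhs)), nd)
  X_s <- mm(fits$survival$rhs)
  X_h <- mm(fits$hospitalisation$rhs)
  X_h <- X_h[, setdiff(colnames(X_h), "(Intercept)"), drop = FALSE]
  X_a <- mm(fits$antibiotic$rhs)

  lmm_design <- function(fit) {
    weeks <- as.numeric(fit$xlevels$week_f)
    ndu <- nd[rep(seq_len(nrow(nd)), each = length(weeks)), , drop = FALSE]
    ndu$week_f <- factor(rep(weeks, nrow(nd)), levels = fit$xlevels$week_f)
    X <- model.matrix(as.formula(paste("~", fit$rhs)), ndu)
    list(X = X[, names(fit$coefficients), drop = FALSE], weeks = weeks)
  }
  list(X_s = X_s[, setdiff(names(fits$survival$coefficients), "Log(scale)"),
                 drop = FALSE],
       X_h = X_h[, names(fits$hospitalisation$coefficients)[
         seq_len(fits$hospitalisation$n_beta)], drop = FALSE],
       X_a = X_a[, names(fits$antibiotic$coefficients), drop = FALSE],
       util = lmm_design(fits$utility),
       oc = lmm_design(fits$othercost),
       b_u = fits$utility$re_estimates[as.character(cv$patient_id)],
       b_oc = fits$othercost$re_estimates[as.character(cv$patient_id)],
       arm = arm, n = nrow(cv), patient_id = cv$patient_id)
}

lognormal_surv <- function(t, lp, sigma) {
  # S(t) = 1 - Phi((log t - lp)/sigma); t = 0 gives S = 1; sigma -> 0 gives a
  # step at exp(lp)
  if (sigma <= 0) {
    outer(lp, t, function(l, tt) as.numeric(log(pmax(tt, 0)) < l))
  } else {
    S <- 1 - pnorm(outer(-lp, log(pmax(t, 0)), "+") / sigma)
    S
  }
}

# linear-interpolation operator from visit weeks onto a fine grid
interp_matrix <- function(weeks, grid) {
  W <- matrix(0, length(grid), length(weeks))
  for (j in seq_along(weeks)) {
    e <- rep(0, length(weeks)); e[j] <- 1
    W[, j] <- approx(weeks, e, xout = grid, rule = 2)$y
  }
  W
}

# core evaluator: expected outcomes per patient for one arm, given parameter
# vectors (defaults to the ML estimates; PSA passes draws)
cgp_eval <- function(fits, design, horizon, costs, opts, params = NULL,
                     event_costs) {
  params <- params %||% fit_params(fits)
  n <- design$n
  th_s <- params$survival
  sigma <- if ("Log(scale)" %in% names(th_s)) exp(th_s[["Log(scale)"]]) else fits$survival$sigma
  lp <- drop(design$X_s %*% th_s[colnames(design$X_s)])

  # --- QALY: area under S(t) * u(t) on a fine grid, utilities interpolated ---
  u_weeks <- design$util$weeks
  if (horizon > max(u_weeks)) {
    stop("horizon beyond the last visit week with utility data; ",
         "utilities are not extrapolated")
  }
  grid <- seq(0, horizon, by = opts$grid_step)
  U <- matrix(drop(design$util$X %*% params$utility), nrow = n, byrow = TRUE)
  U <- U + design$b_u
  W <- interp_matrix(u_weeks, grid)
  Ug <- U %*% t(W)
  S <- lognormal_surv(grid, lp, sigma)
  h <- diff(grid)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  # discount whole segments, so the week-52 year boundary splits exactly
  disc <- if (opts$discount) ifelse(mid > 52, 1 / (1 + opts$rate), 1) else rep(1, length(mid))
  integrand <- S * Ug
  qaly <- (integrand[, -ncol(integrand), drop = FALSE] +
             integrand[, -1, drop = FALSE]) %*% (h * disc / 2) / 52
  qaly <- drop(qaly)

  # --- per-period event costs, weighted by survival at period start ---
  vw <- design$oc$weeks                      # contact visit weeks (4, 12, ...)
  all_weeks <- sort(unique(c(0, u_weeks, vw)))
  if (!horizon %in% all_weeks) stop("horizon not aligned to period boundaries")
  starts <- all_weeks[all_weeks < horizon]
  ends <- all_weeks[-1][all_weeks[-1] <= horizon]
  S_start <- if (opts$survival_weighting) lognormal_surv(starts, lp, sigma) else matrix(1, n, length(starts))
  d_start <- if (opts$discount) {
    ifelse(starts >= 52, 1 / (1 + opts$rate), 1)
  } else rep(1, length(starts))

  # hospitalisation: proportional-odds category probabilities (per period)
  nb <- fits$hospitalisation$n_beta
  th_h <- params$hospitalisation
  eta_h <- if (nb > 0) drop(design$X_h %*% th_h[seq_len(nb)]) else rep(0, n)
  zeta <- if (nb > 0) th_h[-seq_len(nb)] else th_h
  cum <- plogis(outer(eta_h, zeta, function(e, z) z - e))
  p_cat <- cbind(cum, 1) - cbind(0, cum)
  colnames(p_cat) <- fits$hospitalisation$levels
  cc <- event_costs$category_costs
  exp_hosp_period <- drop(p_cat[, setdiff(colnames(p_cat), "none"), drop = FALSE] %*%
                            cc[setdiff(colnames(p_cat), "none")])

  # antibiotics: logistic probability times expected course cost (per period)
  p_ab <- drop(plogis(design$X_a %*% params$antibiotic))
  exp_ab_period <- p_ab * event_costs$course_cost

  hosp <- drop(S_start %*% d_start) * 0  # init
  anti <- hosp
  for (j in seq_along(starts)) {
    w <- S_start[, j] * d_start[j]
    hosp <- hosp + w * exp_hosp_period
    anti <- anti + w * exp_ab_period
  }

  # other NHS cost: predicted 4-week recall window at each contact visit,
  # extrapolated to the interval since the previous visit
  OC <- matrix(drop(design$oc$X %*% params$othercost), nrow = n, byrow = TRUE)
  OC <- OC + design$b_oc
  oc_weeks <- vw[vw <= horizon]
  prev <- c(0, oc_weeks[-length(oc_weeks)])
  other <- rep(0, n)
  if (length(oc_weeks)) {
    S_prev <- if (opts$survival_weighting) lognormal_surv(prev, lp, sigma) else matrix(1, n, length(prev))
    d_prev <- if (opts$discount) ifelse(prev >= 52, 1 / (1 + opts$rate), 1) else rep(1, length(prev))
    fac <- (oc_weeks - prev) / 4
    for (j in seq_along(oc_weeks)) {
      other <- other + S_prev[, j] * d_prev[j] *
        OC[, match(oc_weeks[j], design$oc$weeks)] * fac[j]
    }
  }
  if (opts$sampling) {
    other <- other + costs$sampling[[design$arm]] *
      (1 + opts$followup_sampling_occasions)
  }

  data.frame(patient_id = design$patient_id, arm = design$arm,
             horizon = horizon, qaly = qaly, antibiotics = anti,
             hospitalisation = hosp, other = other,
             total = anti + hosp + other)
}

#' Predicted lognormal survival curve for one patient under an arm
#'
#' @param fit A survival `cua_fit` from [fit_survival()].
#' @param patient One-row data frame with `age`, `sex`, `n_ulcers`,
#'   `ulcer_area`, `ulcer_duration` (raw scales).
#' @param arm Counterfactual arm, `"swab"` or `"tissue"`.
#' @param grid Non-negative time grid in weeks.
#' @return Data frame `time`, `surv` with `S(0) = 1` and S non-increasing.
#' @export
predict_survival_curve <- function(fit, patient, arm, grid) {
  if (any(grid < 0)) stop("survival grid must be non-negative")
  nd <- data.frame(
    arm = factor(arm, levels = c("swab", "tissue")),
    age_c = patient$age - fit$age_centre,
    sex = factor(patient$sex, levels = c("female", "male")),
    n_ulcers = patient$n_ulcers, ulcer_area = patient$ulcer_area,
    ulcer_duration = patient$ulcer_duration
  )
  X <- model.matrix(as.formula(paste("~", fit$rhs)), nd)
  beta <- fit$coefficients[setdiff(names(fit$coefficients), "Log(scale)")]
  lp <- drop(X[, names(beta), drop = FALSE] %*% beta)
  data.frame(time = grid, surv = drop(lognormal_surv(grid, lp, fit$sigma)))
}

#' Expected QALY from a survival curve and conditional utilities
#'
#' Trapezoidal area under S(t)u(t) over `[0, horizon]` with utilities
#' linearly interpolated between visit weeks, divided by 52 weeks/year.
#' With `discount = TRUE` the portion accruing after week 52 is discounted at
#' `rate`.
#'
#' @param curve Data frame `time`, `surv` (from [predict_survival_curve()]);
#'   survival is linearly interpolated onto the integration grid.
#' @param utilities Data frame `week`, `utility` at the visit weeks.
#' @param horizon Horizon in weeks; must not exceed the last utility week.
#' @param discount,rate Second-year discounting switch and annual rate.
#' @param grid_step Integration step in weeks.
#' @return Expected QALYs (years).
#' @export
expected_qaly <- function(curve, utilities, horizon, discount = FALSE,
                          rate = 0.035, grid_step = 0.1) {
  if (horizon > max(utilities$week)) {
    stop("horizon beyond the last visit week with utility data")
  }
  grid <- seq(0, horizon, by = grid_step)
  Sg <- approx(curve$time, curve$surv, xout = grid, rule = 2)$y
  ug <- approx(utilities$week, utilities$utility, xout = grid, rule = 2)$y
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  disc <- if (discount) ifelse(mid > 52, 1 / (1 + rate), 1) else rep(1, length(mid))
  f <- Sg * ug
  sum(diff(grid) * disc * (f[-length(f)] + f[-1]) / 2) / 52
}

#' Expected event costs for one patient under an arm
#'
#' Per inter-visit period: ordinal-model category probabilities times
#' expected category costs (hospitalisation), logistic prescription
#' probability times expected course cost (antibiotics), and the predicted
#' 4-week-recall other cost extrapolated to the period; contributions
#' weighted by predicted survival at period start and summed to the horizon.
#'
#' @param fits A `cua_fits` list from [fit_models()].
#' @param patient One-row patients data frame (raw covariates plus
#'   `patient_id`).
#' @param arm Counterfactual arm.
#' @param horizon Horizon in weeks (a visit week).
#' @param costs Unit-cost configuration.
#' @param opts A [cgp_options()] list.
#' @return One-row data frame of cost components and QALY.
#' @export
expected_event_costs <- function(fits, patient, arm, horizon,
                                 costs = unit_costs(), opts = cgp_options()) {
  cv <- covariate_frame(list(patients = patient),
                        age_centre = fits$survival$age_centre)
  ec <- list(category_costs = opts$category_costs,
             course_cost = opts$course_cost)
  if (is.null(ec$category_costs) || is.null(ec$course_cost)) {
    stop("expected_event_costs needs category_costs and course_cost in opts ",
         "(see estimate_event_costs)")
  }
  design <- cgp_design_arm(fits, cv, arm, horizon)
  cgp_eval(fits, design, horizon, costs, opts, event_costs = ec)
}

#' Corrected-group-prognosis population averages
#'
#' Predicts every patient under both counterfactual arms with their own
#' covariates and empirical-Bayes random effects, and averages over the full
#' population. The incremental row is tissue minus swab.
#'
#' @param fits A `cua_fits` list from [fit_models()].
#' @param data The `cua_data` list the fits came from (used for the
#'   population and for estimating event costs).
#' @param horizon Horizon in weeks (must be a visit week).
#' @param costs Unit-cost configuration.
#' @param opts A [cgp_options()] list.
#' @param params Optional replacement parameter vectors (PSA draws).
#' @return A list of class `cgp_result`: `arms` (two-row data frame of mean
#'   QALY and cost components), `incremental` (named vector `qaly`,
#'   `antibiotics`, `hospitalisation`, `other`, `total`), `patient`
#'   (per-patient-per-arm predictions).
#' @export
cgp_average <- function(fits, data, horizon, costs = unit_costs(),
                        opts = cgp_options(), params = NULL) {
  cv <- fits$covariates
  est <- if (is.null(opts$category_costs) || is.null(opts$course_cost)) {
    estimate_event_costs(data, costs)
  }
  ec <- list(category_costs = opts$category_costs %||% est$category_costs,
             course_cost = opts$course_cost %||% est$course_cost)
  per <- do.call(rbind, lapply(c("swab", "tissue"), function(a) {
    cgp_eval(fits, cgp_design_arm(fits, cv, a, horizon), horizon, costs,
             opts, params, ec)
  }))
  num <- c("qaly", "antibiotics", "hospitalisation", "other", "total")
  arms <- aggregate(per[num], by = list(arm = per$arm), FUN = mean)
  rownames(arms) <- arms$arm
  inc <- unlist(arms["tissue", num]) - unlist(arms["swab", num])
  structure(list(arms = arms, incremental = inc, patient = per,
                 horizon = horizon), class = "cgp_result")
}

#' @export
#' @method print cgp_result
print.cgp_result <- function(x, ...) {
  cat("Corrected group prognosis at week", x$horizon, "\n")
  print(cbind(arm = x$arms$arm, round(x$arms[-1], 3)), row.names = FALSE)
  cat("Incremental (tissue - swab): dQALY =", round(x$incremental["qaly"], 4),
      ", dCost =", round(x$incremental["total"], 2), "\n")
  invisible(x)
}
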