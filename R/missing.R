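# Missing-data handling for the self-reported streams (EQ-5D utilities and
# other-cost recall windows): available-case analysis, and multiple
# imputation by fully conditional specification on the utility / window-cost
# scale with Bayesian linear draws and Rubin pooling. Researcher-collected
# streams (survival, admissions, antibiotics) are complete by design and are
# never imputed. Visits after death are structurally undefined, not missing.

#' Multiple-imputation configuration
#'
#' @param n_imputations Number of completed datasets m (default 100).
#' @param burnin Chained-equation sweeps before each chain's dataset is saved
#'   (default 10).
#' @param seed Integer seed; imputation is deterministic given the seed.
#' @return A list of class `mi_config`.
#' @export
mi_config <- function(n_imputations = 100, burnin = 10, seed = 1L) {
  if (n_imputations < 2) stop("n_imputations must be at least 2")
  structure(list(n_imputations = as.integer(n_imputations),
                 burnin = as.integer(burnin), seed = as.integer(seed)),
            class = "mi_config")
}

#' Available-case filter for self-reported outcomes
#'
#' Drops EQ-5D and contact-window rows flagged or observed as missing;
#' survival, admission and antibiotic streams are always retained complete.
#'
#' @param data A `cua_data` list.
#' @return The filtered `cua_data` list.
#' @export
aca_filter <- function(data) {
  u <- utility_table(data)
  keep_eq <- u$miss == "" & !is.na(u$utility)
  cc <- data$contacts
  keep_cc <- cc$miss == "" & stats::complete.cases(
    cc[setdiff(names(cc), c("patient_id", "week", "miss"))])
  if (!any(keep_eq)) stop("no available cases")
  data$eq5d <- data$eq5d[keep_eq, , drop = FALSE]
  data$contacts <- cc[keep_cc, , drop = FALSE]
  data
}

# wide outcome matrix for FCS: one row per patient, u_<week> and oc_<week>
# columns; eligibility = alive at the visit (later cells are structurally
# undefined, never imputed)
mi_wide <- function(data, costs = unit_costs()) {
  u <- utility_table(data)
  oc <- othercost_table(data, costs)
  p <- data$patients
  uw <- sort(unique(u$week)); ow <- sort(unique(oc$week))
  n <- nrow(p)
  cols <- c(paste0("u_", uw), paste0("oc_", ow))
  Y <- matrix(NA_real_, n, length(cols), dimnames = list(p$patient_id, cols))
  elig <- matrix(FALSE, n, length(cols), dimnames = dimnames(Y))
  death <- p$death_week %||% rep(Inf, n)
  death[is.na(death)] <- Inf
  for (j in seq_along(uw)) {
    elig[, j] <- uw[j] < death
    rows <- u$week == uw[j]
    Y[match(u$patient_id[rows], p$patient_id), j] <- u$utility[rows]
  }
  for (j in seq_along(ow)) {
    k <- length(uw) + j
    elig[, k] <- ow[j] < death
    rows <- oc$week == ow[j]
    Y[match(oc$patient_id[rows], p$patient_id), k] <- oc$window_cost[rows]
  }
  X0 <- cbind(1,
              arm = as.numeric(p$arm == "tissue"),
              age = p$age - mean(p$age),
              sex = as.numeric(p$sex == "male"),
              n_ulcers = p$n_ulcers, ulcer_area = p$ulcer_area,
              ulcer_duration = p$ulcer_duration)
  list(Y = Y, elig = elig, X0 = X0, u_weeks = uw, oc_weeks = ow,
       patient_id = p$patient_id)
}

# one Bayesian linear imputation draw (the chained-equation "norm" step)
draw_impute <- function(y, X, mis, ridge = 1e-5) {
  obs <- !mis
  Xo <- X[obs, , drop = FALSE]; yo <- y[obs]
  keep <- which(apply(Xo, 2, function(v) stats::sd(v) > 0 | all(v == 1)))
  if (nrow(Xo) < length(keep) + 2) keep <- 1L
  Xo <- Xo[, keep, drop = FALSE]
  XtX <- crossprod(Xo) + diag(ridge, ncol(Xo))
  bhat <- solve(XtX, crossprod(Xo, yo))
  res <- yo - Xo %*% bhat
  nu <- max(nrow(Xo) - ncol(Xo), 1)
  s2 <- sum(res^2) / rchisq(1, nu)
  bstar <- drop(bhat) +
    drop(t(chol(s2 * chol2inv(chol(XtX)))) %*% rnorm(ncol(Xo)))
  Xm <- X[mis, keep, drop = FALSE]
  drop(Xm %*% bstar) + rnorm(sum(mis), 0, sqrt(s2))
}

#' Multiple imputation by fully conditional specification
#'
#' Imputes missing EQ-5D utilities and other-cost recall windows (MAR
#' assumed) by chained Bayesian linear regressions in a fixed sweep order
#' (utility columns by week, then cost columns by week), each conditioning on
#' baseline covariates and the current values of outcomes at the same and
#' earlier weeks. Each of the m imputations is an independent chain with
#' `burnin` sweeps; observed values are never altered.
#'
#' @param data A `cua_data` list.
#' @param config An [mi_config()].
#' @param costs Unit-cost configuration from [unit_costs()].
#' @return A list of class `cua_mi` with m elements, each holding completed
#'   `utilities` and `windows` tables ready for [fit_models()].
#' @export
mi_fcs <- function(data, config = mi_config(), costs = unit_costs()) {
  w <- mi_wide(data, costs)
  mis <- is.na(w$Y) & w$elig
  all_missing <- colSums(!is.na(w$Y)) == 0 & colSums(w$elig) > 0
  if (any(all_missing)) {
    stop("variable(s) 100% missing: ",
         paste(colnames(w$Y)[all_missing], collapse = ", "))
  }
  u_cols <- seq_along(w$u_weeks)
  oc_cols <- length(w$u_weeks) + seq_along(w$oc_weeks)
  out <- vector("list", config$n_imputations)
  for (m in seq_len(config$n_imputations)) {
    set.seed(config$seed + 7L * m)
    Y <- w$Y
    # initial fill: draw from the observed margin of each column
    for (j in which(colSums(mis) > 0)) {
      pool <- Y[!is.na(w$Y[, j]), j]
      Y[mis[, j], j] <- sample(pool, sum(mis[, j]), replace = TRUE)
    }
    if (any(mis)) {
      for (sweep in seq_len(config$burnin)) {
        for (j in c(u_cols, oc_cols)) {
          if (!any(mis[, j])) next
          rows <- w$elig[, j]
          # predictors: baseline covariates + outcomes at the same or
          # earlier weeks (defined for every row eligible for column j)
          wk <- c(w$u_weeks, w$oc_weeks)[j]
          pred <- setdiff(which(c(w$u_weeks, w$oc_weeks) <= wk), j)
          X <- cbind(w$X0[rows, , drop = FALSE], Y[rows, pred, drop = FALSE])
          Y[rows, j][mis[rows, j]] <-
            draw_impute(Y[rows, j], X, mis[rows, j])
        }
      }
    }
    long_u <- data.frame(
      patient_id = rep(w$patient_id, length(w$u_weeks)),
      week = rep(w$u_weeks, each = nrow(Y)),
      utility = as.vector(Y[, u_cols]), miss = "")
    long_u <- long_u[as.vector(w$elig[, u_cols, drop = FALSE]), ]
    long_u <- long_u[order(long_u$patient_id, long_u$week), ]
    rownames(long_u) <- NULL
    long_oc <- data.frame(
      patient_id = rep(w$patient_id, length(w$oc_weeks)),
      week = rep(w$oc_weeks, each = nrow(Y)),
      window_cost = as.vector(Y[, oc_cols]), miss = "")
    long_oc <- long_oc[as.vector(w$elig[, oc_cols, drop = FALSE]), ]
    long_oc <- long_oc[order(long_oc$patient_id, long_oc$week), ]
    rownames(long_oc) <- NULL
    out[[m]] <- list(utilities = long_u, windows = long_oc)
  }
  structure(out, class = "cua_mi", config = config)
}

#' Rubin's rules for pooling multiple-imputation estimates
#'
#' @param estimates Per-imputation point estimates (length m >= 2).
#' @param variances Per-imputation (within-imputation) variances; default 0
#'   treats the per-imputation estimates as exact and pools their mean and
#'   between-imputation spread only.
#' @param conf_level Confidence level for the interval.
#' @return List with `estimate`, `within`, `between`, `total` (variance),
#'   `df` (Barnard-Rubin style large-sample MI degrees of freedom), `ci`.
#' @export
pool_rubin <- function(estimates, variances = rep(0, length(estimates)),
                       conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("pooling needs at least 2 imputations")
  stopifnot(length(variances) == m)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tv <- W + (1 + 1 / m) * B
  r <- (1 + 1 / m) * B / max(W, .Machine$double.eps)
  df <- (m - 1) * (1 + 1 / r)^2
  half <- if (Tv > 0) qt(1 - (1 - conf_level) / 2, df) * sqrt(Tv) else 0
  list(estimate = qbar, within = W, between = B, total = Tv, df = df,
       ci = c(qbar - half, qbar + half))
}
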