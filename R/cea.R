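# Decision layer: second-year discounting, ICER with dominance
# classification, incremental net monetary / health benefit, probabilistic
# sensitivity analysis by multivariate-normal parameter draws, CEAC and
# cost-effectiveness-plane outputs. Sign convention throughout:
# incremental = tissue - swab.

#' Discount amounts accruing in the second year
#'
#' Amounts (costs or utilities) accruing in weeks 0-52 are undiscounted;
#' amounts accruing after week 52 are divided by (1 + rate), the one-factor
#' second-year adjustment appropriate to a two-year horizon.
#'
#' @param amount Amount (pounds or QALYs).
#' @param week Week at which the amount accrues (>= 0).
#' @param rate Annual discount rate (default 0.035).
#' @return The discounted amount.
#' @examples
#' discount(100, 26)    # 100
#' discount(103.5, 80)  # 100
#' @export
discount <- function(amount, week, rate = 0.035) {
  if (rate < 0) stop("discount rate must be non-negative")
  if (any(week < 0)) stop("week must be non-negative")
  ifelse(week > 52, amount / (1 + rate), amount)
}

#' ICER with dominance classification
#'
#' The ratio dC/dQ is reported only in the trade-off quadrants; an
#' intervention that costs more and yields fewer QALYs is dominated, one that
#' costs less and yields more dominates. With dQ = 0 the ratio is undefined
#' and the label follows the sign of dC.
#'
#' @param d_cost Incremental cost (tissue - swab), pounds.
#' @param d_qaly Incremental QALYs (tissue - swab).
#' @return List with `value` (the ratio, or `NA` under dominance/undefined)
#'   and `label` (`"dominated"`, `"dominant"`, `"cost-effective ratio"` or
#'   `"undefined"`).
#' @export
icer <- function(d_cost, d_qaly) {
  if (d_qaly == 0) {
    label <- if (d_cost > 0) "dominated" else if (d_cost < 0) "dominant" else "undefined"
    return(list(value = NA_real_, label = label))
  }
  if (d_cost > 0 && d_qaly < 0) return(list(value = NA_real_, label = "dominated"))
  if (d_cost < 0 && d_qaly > 0) return(list(value = NA_real_, label = "dominant"))
  list(value = d_cost / d_qaly, label = "cost-effective ratio")
}

#' Incremental net monetary and net health benefit
#'
#' `inmb = lambda * dQ - dC` (pounds); `inhb = dQ - dC / lambda` (QALYs);
#' the identity `inhb = inmb / lambda` holds exactly. An intervention with
#' positive mean incremental benefit should be adopted at that threshold.
#'
#' @param d_qaly Incremental QALYs (tissue - swab).
#' @param d_cost Incremental cost (tissue - swab), pounds.
#' @param lambda Willingness-to-pay threshold, pounds per QALY (> 0).
#' @return Net benefit (vectorised over `lambda`).
#' @export
inmb <- function(d_qaly, d_cost, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  lambda * d_qaly - d_cost
}

#' @rdname inmb
#' @export
inhb <- function(d_qaly, d_cost, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  d_qaly - d_cost / lambda
}

draw_model_params <- function(fit) {
  theta <- fit$coefficients
  V <- fit$vcov
  if (all(V == 0)) return(theta)
  draw <- drop(MASS::mvrnorm(1, theta, V))
  if (fit$family == "ordinal_logit" && fit$n_beta < length(theta)) {
    # redraw the rare non-monotone threshold draws
    for (try in 1:100) {
      zeta <- draw[-seq_len(fit$n_beta)]
      if (fit$n_beta == 0) zeta <- draw
      if (all(diff(zeta) > 0)) break
      draw <- drop(MASS::mvrnorm(1, theta, V))
    }
  }
  names(draw) <- names(theta)
  draw
}

#' Probabilistic sensitivity analysis
#'
#' Each model's full parameter vector is drawn from a multivariate normal at
#' its estimates and variance-covariance matrix (within-model correlation
#' preserved; across-model draws independent; the AFT scale is drawn on the
#' log scale and so stays positive), and the corrected-group-prognosis
#' pipeline is re-run per draw. With a list of per-imputation fits, draws are
#' allocated round-robin across imputations so parameter and imputation
#' uncertainty propagate together.
#'
#' @param fits A `cua_fits` list, or a list of them (one per imputation).
#' @param data The `cua_data` list the fits came from.
#' @param horizon Horizon in weeks (a visit week).
#' @param n_draws Number of draws (default 1000).
#' @param seed Integer seed.
#' @param costs Unit-cost configuration.
#' @param opts A [cgp_options()] list.
#' @return A data frame of class `cua_psa` with one row per draw:
#'   `draw`, per-arm `qaly_*` and `cost_*`, `d_qaly`, `d_cost`.
#' @export
psa_run <- function(fits, data, horizon, n_draws = 1000, seed = 1L,
                    costs = unit_costs(), opts = cgp_options()) {
  fit_list <- if (inherits(fits, "cua_fits")) list(fits) else fits
  for (f in fit_list) check_vcov(f$survival$vcov)
  set.seed(seed)
  est <- if (is.null(opts$category_costs) || is.null(opts$course_cost)) {
    estimate_event_costs(data, costs)
  }
  ec <- list(category_costs = opts$category_costs %||% est$category_costs,
             course_cost = opts$course_cost %||% est$course_cost)
  designs <- lapply(fit_list, function(f) {
    list(swab = cgp_design_arm(f, f$covariates, "swab", horizon),
         tissue = cgp_design_arm(f, f$covariates, "tissue", horizon))
  })
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    k <- ((d - 1) %% length(fit_list)) + 1L
    f <- fit_list[[k]]
    params <- list(survival = draw_model_params(f$survival),
                   utility = draw_model_params(f$utility),
                   hospitalisation = draw_model_params(f$hospitalisation),
                   antibiotic = draw_model_params(f$antibiotic),
                   othercost = draw_model_params(f$othercost))
    res <- lapply(designs[[k]], function(dz)
      cgp_eval(f, dz, horizon, costs, opts, params, ec))
    rows[[d]] <- data.frame(
      draw = d,
      qaly_swab = mean(res$swab$qaly), qaly_tissue = mean(res$tissue$qaly),
      cost_swab = mean(res$swab$total), cost_tissue = mean(res$tissue$total))
  }
  out <- do.call(rbind, rows)
  out$d_qaly <- out$qaly_tissue - out$qaly_swab
  out$d_cost <- out$cost_tissue - out$cost_swab
  if (any(!is.finite(as.matrix(out)))) stop("non-finite PSA draw encountered")
  class(out) <- c("cua_psa", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with strictly positive incremental net monetary
#' benefit for tissue versus swab at each willingness-to-pay value.
#'
#' @param draws A `cua_psa` data frame from [psa_run()].
#' @param lambda_grid Thresholds in pounds per QALY (default 0-50,000 by
#'   1,000; the value 0 is evaluated as the limit "fraction of draws with
#'   dC < 0").
#' @return Data frame `lambda`, `probability`.
#' @export
ceac <- function(draws, lambda_grid = seq(0, 50000, by = 1000)) {
  if (nrow(draws) == 0) stop("no PSA draws")
  prob <- vapply(lambda_grid, function(l) {
    if (l == 0) mean(draws$d_cost < 0)
    else mean(inmb(draws$d_qaly, draws$d_cost, l) > 0)
  }, numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}

#' Cost-effectiveness plane points
#'
#' @param draws A `cua_psa` data frame from [psa_run()].
#' @return Data frame `d_qaly`, `d_cost`, one point per draw.
#' @export
ce_plane <- function(draws) {
  if (nrow(draws) == 0) stop("no PSA draws")
  data.frame(d_qaly = draws$d_qaly, d_cost = draws$d_cost)
}
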