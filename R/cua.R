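# The central analysis object: one call runs regression fitting, corrected
# group prognosis, the chosen missing-data treatment and (optionally) PSA at
# one horizon, and returns a classed result with the decision statistics.

#' Within-trial cost-utility analysis of a two-arm trial
#'
#' Fits the five regressions (lognormal AFT survival, utility and other-cost
#' linear mixed models, proportional-odds hospitalisation, logistic
#' antibiotic prescription) on the common covariate set, standardises them by
#' corrected group prognosis to expected per-arm costs and QALYs at the
#' horizon, and derives ICER, INMB and INHB. Self-reported missingness is
#' handled by available-case analysis (`missing = "ACA"`) or fully
#' conditional specification multiple imputation (`missing = "MI"`);
#' uncertainty by probabilistic sensitivity analysis (`method = "PSA"`).
#'
#' @param data A `cua_data` list (five tables; see [simulate_trial()] and
#'   [read_trial_csv()]).
#' @param horizon Horizon in weeks; must be a scheduled visit week.
#' @param missing `"ACA"` or `"MI"`.
#' @param method `"deterministic"` or `"PSA"`.
#' @param lambda Willingness-to-pay thresholds, pounds per QALY.
#' @param discount Apply 3.5% second-year discounting.
#' @param n_draws PSA draws (default 1000).
#' @param mi An [mi_config()] (MI only).
#' @param costs Unit-cost configuration from [unit_costs()].
#' @param opts A [cgp_options()]; `discount` overrides its discount flag.
#' @param seed Integer seed for PSA.
#' @return An object of class `cua`: per-arm expected costs (components) and
#'   QALYs, incremental statistics, ICER label, net benefits at each lambda,
#'   the fitted models, and PSA draws plus CEAC when `method = "PSA"`.
#' @export
cua <- function(data, horizon = 52, missing = c("ACA", "MI"),
                method = c("deterministic", "PSA"),
                lambda = c(20000, 30000), discount = FALSE, n_draws = 1000,
                mi = mi_config(n_imputations = 20), costs = unit_costs(),
                opts = cgp_options(), seed = 1L) {
  missing <- match.arg(missing)
  method <- match.arg(method)
  opts$discount <- discount
  vw <- attr(data, "visit_weeks") %||% sort(unique(data$eq5d$week))
  if (!horizon %in% vw) stop("horizon must be one of the visit weeks: ",
                             paste(vw, collapse = ", "))

  fit_sets <- if (missing == "ACA") {
    list(fit_models(data, costs = costs))
  } else {
    imp <- mi_fcs(data, config = mi, costs = costs)
    lapply(imp, function(d) fit_models(data, utilities = d$utilities,
                                       windows = d$windows, costs = costs))
  }

  cgps <- lapply(fit_sets, cgp_average, data = data, horizon = horizon,
                 costs = costs, opts = opts)
  num <- c("qaly", "antibiotics", "hospitalisation", "other", "total")
  arms <- cgps[[1]]$arms
  arms[num] <- Reduce(`+`, lapply(cgps, function(g) g$arms[num])) / length(cgps)
  inc <- colMeans(do.call(rbind, lapply(cgps, `[[`, "incremental")))

  draws <- ceac_tab <- NULL
  if (method == "PSA") {
    draws <- psa_run(if (length(fit_sets) == 1) fit_sets[[1]] else fit_sets,
                     data, horizon, n_draws = n_draws, seed = seed,
                     costs = costs, opts = opts)
    # PSA means replace the deterministic point estimates
    arms[arms$arm == "swab", c("qaly", "total")] <-
      c(mean(draws$qaly_swab), mean(draws$cost_swab))
    arms[arms$arm == "tissue", c("qaly", "total")] <-
      c(mean(draws$qaly_tissue), mean(draws$cost_tissue))
    inc["qaly"] <- mean(draws$d_qaly)
    inc["total"] <- mean(draws$d_cost)
    ceac_tab <- ceac(draws)
  }

  res <- structure(list(
    horizon = horizon, missing = missing, method = method,
    discount = discount, lambda = lambda,
    arms = arms, incremental = inc,
    icer = icer(inc[["total"]], inc[["qaly"]]),
    inmb = setNames(inmb(inc[["qaly"]], inc[["total"]], lambda),
                    paste0("lambda_", lambda)),
    inhb = setNames(inhb(inc[["qaly"]], inc[["total"]], lambda),
                    paste0("lambda_", lambda)),
    fits = fit_sets[[1]], n_imputations = length(fit_sets),
    draws = draws, ceac = ceac_tab,
    call = match.call()), class = "cua")
  res
}

#' @export
#' @method print cua
print.cua <- function(x, ...) {
  cat("Within-trial cost-utility analysis (", x$missing, ", ", x$method,
      ") at week ", x$horizon, "\n", sep = "")
  tab <- x$arms
  tab[-1] <- round(tab[-1], 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Incremental (tissue - swab): dQALY = %.4f, dCost = £%.2f\n",
              x$incremental[["qaly"]], x$incremental[["total"]]))
  for (i in seq_along(x$lambda)) {
    cat(sprintf("  lambda £%s: INMB = £%.0f, INHB = %.3f QALYs\n",
                format(x$lambda[i], big.mark = ","), x$inmb[i], x$inhb[i]))
  }
  cat("ICER:", if (is.na(x$icer$value)) x$icer$label else
    sprintf("£%.0f per QALY", x$icer$value), "\n")
  invisible(x)
}

#' @export
#' @method summary cua
summary.cua <- function(object, ...) {
  out <- list(result = object,
              table = cua_report_row(object),
              coefficients = lapply(
                object$fits[c("survival", "utility", "hospitalisation",
                              "antibiotic", "othercost")], coef))
  class(out) <- "summary.cua"
  out
}

#' @export
#' @method print summary.cua
print.summary.cua <- function(x, ...) {
  print(x$result)
  cat("\nArm coefficient (exp) per model:\n")
  for (nm in names(x$coefficients)) {
    b <- x$coefficients[[nm]]["armtissue"]
    if (!is.na(b)) {
      cat(sprintf("  %-16s %8.4f  (ratio %.3f)\n", nm, b, exp(b)))
    }
  }
  invisible(x)
}

#' @export
coef.cua <- function(object, ...) object$incremental

#' Cost-effectiveness plane plot
#'
#' Scatter of PSA draws (tissue minus swab) on the cost-effectiveness plane,
#' with the willingness-to-pay line(s).
#'
#' @param x A `cua` object fitted with `method = "PSA"`.
#' @param lambda Threshold line(s) to draw.
#' @param ... Passed to [plot()].
#' @export
plot.cua <- function(x, lambda = x$lambda, ...) {
  if (is.null(x$draws)) stop("no PSA draws; fit with method = 'PSA'")
  pl <- ce_plane(x$draws)
  plot(pl$d_qaly, pl$d_cost, pch = 16, cex = 0.4,
       col = "#00000055", xlab = "Incremental QALYs (tissue - swab)",
       ylab = "Incremental cost (£)", ...)
  abline(h = 0, v = 0, col = "grey")
  for (l in lambda) abline(0, l, lty = 2, col = "steelblue")
  points(mean(pl$d_qaly), mean(pl$d_cost), pch = 3, col = "red", cex = 1.5)
  invisible(x)
}

# one row of a Table-7-style report
cua_report_row <- function(x) {
  data.frame(
    week = x$horizon, analysis = x$missing, method = x$method,
    qaly_tissue = x$arms["tissue", "qaly"], qaly_swab = x$arms["swab", "qaly"],
    d_qaly = x$incremental[["qaly"]],
    cost_tissue = x$arms["tissue", "total"], cost_swab = x$arms["swab", "total"],
    d_cost = x$incremental[["total"]],
    inhb_20k = inhb(x$incremental[["qaly"]], x$incremental[["total"]], 20000),
    inmb_20k = inmb(x$incremental[["qaly"]], x$incremental[["total"]], 20000),
    inhb_30k = inhb(x$incremental[["qaly"]], x$incremental[["total"]], 30000),
    inmb_30k = inmb(x$incremental[["qaly"]], x$incremental[["total"]], 30000),
    icer = if (is.na(x$icer$value)) x$icer$label else
      format(round(x$icer$value)), row.names = NULL)
}
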