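# Costing of resource-use event streams: hospital admissions priced as HRG
# episode cost plus excess bed-days, antibiotic courses priced from a BNF-style
# unit price list, and 4-week-recall healthcare contacts extrapolated to the
# period they represent.

#' Load the unit-cost configuration
#'
#' Reads the bundled 2021/22 NHS/PSS unit-cost tables (sampling, healthcare
#' contacts, admission episodes with average length of stay and excess-bed-day
#' costs, antibiotic unit prices) or a user-supplied YAML file with the same
#' structure.
#'
#' @param file Optional path to a YAML configuration overriding the bundled
#'   tables.
#' @return A list with components `sampling`, `contacts`, `admissions`,
#'   `post_amputation_cost`, `antibiotics` (data frame), `price_year`,
#'   `default_duration_days`, `default_units_per_day`.
#' @export
unit_costs <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "unit_costs.yaml", package = "trialcua")
  }
  cfg <- yaml::read_yaml(file)
  cfg$antibiotics <- do.call(rbind, lapply(cfg$antibiotics, as.data.frame))
  stopifnot(all(cfg$antibiotics$unit_cost > 0),
            all(unlist(cfg$contacts) >= 0),
            all(unlist(cfg$sampling) >= 0))
  for (a in cfg$admissions) {
    stopifnot(a$cost_per_episode >= 0, a$avg_los_days >= 0, a$excess_bed_day >= 0)
  }
  cfg
}

#' Cost one hospital admission
#'
#' Episode cost for the admission's category plus the excess-bed-day cost for
#' each observed day beyond the category's costed average length of stay
#' (never negative). Amputation admissions additionally incur a one-off
#' post-amputation rehabilitation cost.
#'
#' @param category Admission category (a name of `costs$admissions`).
#' @param observed_los_days Observed length of stay in days.
#' @param costs Unit-cost configuration from [unit_costs()].
#' @param post_amputation Add the rehabilitation cost to amputation
#'   admissions (default `TRUE`).
#' @return Cost in pounds.
#' @examples
#' cost_admission("major_amputation", 19)  # 11723 + 529
#' cost_admission("major_amputation", 21)  # 11723 + 2*313 + 529
#' @export
cost_admission <- function(category, observed_los_days, costs = unit_costs(),
                           post_amputation = TRUE) {
  if (length(category) > 1L) {
    return(mapply(cost_admission, category, observed_los_days,
                  MoreArgs = list(costs = costs, post_amputation = post_amputation),
                  USE.NAMES = FALSE))
  }
  tab <- costs$admissions[[category]]
  if (is.null(tab)) {
    stop("unknown admission category '", category, "'; known: ",
         paste(names(costs$admissions), collapse = ", "))
  }
  if (observed_los_days < 0) stop("observed_los_days must be non-negative")
  amount <- tab$cost_per_episode +
    max(0, observed_los_days - tab$avg_los_days) * tab$excess_bed_day
  if (post_amputation && grepl("amputation", category)) {
    amount <- amount + costs$post_amputation_cost
  }
  amount
}

#' Resolve admissions recorded for the same dates
#'
#' Where several admission events share an identical (start, end) week pair
#' only the most expensive is retained; equal-cost ties break by category name
#' order. Non-overlapping events pass through untouched, and the result does
#' not depend on input ordering.
#'
#' @param events Data frame with columns `patient_id`, `category`,
#'   `start_week`, `end_week`, `los_days`.
#' @param costs Unit-cost configuration from [unit_costs()].
#' @return The events data frame with same-dated duplicates removed.
#' @export
resolve_overlapping_admissions <- function(events, costs = unit_costs()) {
  if (nrow(events) == 0L) return(events)
  if (any(events$end_week < events$start_week)) {
    stop("admission end_week before start_week")
  }
  amount <- cost_admission(events$category, events$los_days, costs)
  key <- paste(events$patient_id, events$start_week, events$end_week, sep = "\r")
  # order: by key, then decreasing cost, then category name for ties
  ord <- order(key, -amount, as.character(events$category))
  keep <- !duplicated(key[ord])
  out <- events[ord[keep], , drop = FALSE]
  out[order(out$patient_id, out$start_week, out$end_week), , drop = FALSE]
}

#' Cost an antibiotic course
#'
#' Unit price times units per day times duration. Missing duration or
#' frequency fall back to the configured defaults (the prescribing-guideline
#' convention for incompletely recorded prescriptions).
#'
#' @param drug,form Drug name and pharmaceutical form, matched against the
#'   price list.
#' @param units_per_day Dose units per day; `NA` uses
#'   `costs$default_units_per_day`.
#' @param duration_days Course length in days; `NA` uses
#'   `costs$default_duration_days`.
#' @param costs Unit-cost configuration from [unit_costs()].
#' @return Cost in pounds.
#' @examples
#' cost_antibiotic_course("co-amoxiclav", "500 mg/125 mg tablet", 3, 7)  # 8.19
#' @export
cost_antibiotic_course <- function(drug, form, units_per_day = NA,
                                   duration_days = NA, costs = unit_costs()) {
  if (length(drug) > 1L) {
    return(mapply(cost_antibiotic_course, drug, form, units_per_day,
                  duration_days, MoreArgs = list(costs = costs),
                  USE.NAMES = FALSE))
  }
  hit <- costs$antibiotics$drug == drug & costs$antibiotics$form == form
  if (sum(hit) != 1L) {
    stop("unknown antibiotic '", drug, " ", form, "' (or ambiguous entry)")
  }
  if (is.na(units_per_day)) units_per_day <- costs$default_units_per_day
  if (is.na(duration_days)) duration_days <- costs$default_duration_days
  if (units_per_day < 0 || duration_days < 0) stop("negative dose or duration")
  units_per_day * duration_days * costs$antibiotics$unit_cost[hit]
}

#' Cost a 4-week healthcare-contact recall window
#'
#' @param counts Named vector or one-row data frame of contact counts; names
#'   must match `costs$contacts` (gp, practice_nurse, district_nurse,
#'   foot_clinic, outpatient, ae).
#' @param costs Unit-cost configuration from [unit_costs()].
#' @return Window cost in pounds.
#' @examples
#' cost_contacts_window(c(gp = 1, district_nurse = 2))  # 38 + 108
#' @export
cost_contacts_window <- function(counts, costs = unit_costs()) {
  counts <- unlist(counts)
  if (any(is.na(counts))) return(NA_real_)
  if (any(counts < 0)) stop("negative contact counts")
  unknown <- setdiff(names(counts), names(costs$contacts))
  if (length(unknown)) stop("unknown contact type(s): ", paste(unknown, collapse = ", "))
  sum(counts * unlist(costs$contacts)[names(counts)])
}

#' Extrapolate a recall-window cost to the period it represents
#'
#' Contact questionnaires ask about the previous 4 weeks; each observation is
#' taken as representative of the whole interval since the last scheduled
#' visit and scaled accordingly.
#'
#' @param window_cost Cost of the 4-week recall window, pounds.
#' @param weeks_since_last_visit Length of the interval the window represents.
#' @return Extrapolated cost in pounds.
#' @export
extrapolate_window <- function(window_cost, weeks_since_last_visit) {
  if (any(weeks_since_last_visit <= 0)) stop("weeks_since_last_visit must be positive")
  window_cost * weeks_since_last_visit / 4
}

# Observed (data-level) per-patient cost summaries used by descriptive output
# and the intercept-only collapse checks: admissions and antibiotics costed
# per event, contacts costed per window and extrapolated over the visit grid.
cost_events <- function(data, costs = unit_costs(), horizon = 52) {
  adm <- resolve_overlapping_admissions(data$admissions, costs)
  adm <- adm[adm$start_week < horizon, , drop = FALSE]
  adm_amt <- if (nrow(adm)) cost_admission(adm$category, adm$los_days, costs) else numeric(0)
  ab <- data$antibiotics[data$antibiotics$week < horizon, , drop = FALSE]
  ab_amt <- if (nrow(ab)) {
    cost_antibiotic_course(ab$drug, ab$form, ab$units_per_day, ab$duration_days, costs)
  } else numeric(0)
  visits <- sort(unique(data$contacts$week))
  prev <- setNames(c(0, visits[-length(visits)]), visits)
  cc <- data$contacts[data$contacts$week <= horizon, , drop = FALSE]
  types <- intersect(names(costs$contacts), names(cc))
  win <- apply(cc[types], 1L, cost_contacts_window, costs = costs)
  oc_amt <- extrapolate_window(win, cc$week - prev[as.character(cc$week)])
  rbind(
    data.frame(patient_id = adm$patient_id, week = adm$start_week,
               category = "admission", amount = adm_amt),
    data.frame(patient_id = ab$patient_id, week = ab$week,
               category = "antibiotic", amount = ab_amt),
    data.frame(patient_id = cc$patient_id, week = cc$week,
               category = "contact", amount = oc_amt)
  )
}
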