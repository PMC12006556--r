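# EQ-5D-3L scoring with the UK general-population time-trade-off tariff.
#
# A profile is five integer levels in {1,2,3} for mobility, self-care, usual
# activities, pain/discomfort and anxiety/depression. The tariff subtracts a
# constant for any problem, per-dimension level decrements, and a single N3
# decrement if any dimension is at level 3; states worse than death (utility
# below 0) are permitted.

EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' UK time-trade-off tariff for EQ-5D-3L
#'
#' Returns the standard UK general-population time-trade-off valuation
#' coefficients as a named list: `constant` (decrement applied once if any
#' dimension is above level 1), a 2-row matrix `decrements` of level-2 and
#' level-3 decrements per dimension, and `n3` (decrement applied once if any
#' dimension is at level 3). The bundled coefficients are also shipped as a
#' plain-text table in `inst/extdata/eq5d_uk_tto.csv`; a user-supplied file
#' with the same layout can be loaded via `file`.
#'
#' @param file Optional path to a CSV with columns `term`, `level`,
#'   `decrement` overriding the bundled tariff.
#' @return A list with elements `constant`, `decrements` (2 x 5 matrix, rows
#'   `"2"` and `"3"`), `n3` and `floor` (the all-threes score).
#' @examples
#' tar <- eq5d_tariff_uk()
#' score_eq5d(c(1, 1, 1, 1, 1), tar)  # 1
#' score_eq5d(c(3, 3, 3, 3, 3), tar)  # -0.594
#' @export
eq5d_tariff_uk <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "eq5d_uk_tto.csv", package = "trialcua")
  }
  tab <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "level", "decrement") %in% names(tab)))
  dec <- matrix(NA_real_, 2, 5, dimnames = list(c("2", "3"), EQ5D_DIMENSIONS))
  for (d in EQ5D_DIMENSIONS) {
    for (l in c("2", "3")) {
      v <- tab$decrement[tab$term == d & tab$level == l]
      if (length(v) != 1L) stop("tariff file lacks a unique row for ", d, " level ", l)
      dec[l, d] <- v
    }
  }
  tariff <- list(
    constant = tab$decrement[tab$term == "constant"][1],
    decrements = dec,
    n3 = tab$decrement[tab$term == "n3"][1]
  )
  if (any(unlist(tariff) < 0)) stop("tariff decrements must be non-negative")
  tariff$floor <- 1 - tariff$constant - sum(dec["3", ]) - tariff$n3
  tariff
}

#' Score EQ-5D-3L profiles to utilities
#'
#' Maps each five-dimension profile to a utility on the scale where 1 is full
#' health and 0 is death. Profiles with any missing dimension score `NA`
#' (no partial scoring).
#'
#' @param profiles A length-5 vector (one profile) or a matrix/data frame with
#'   five columns in the order mobility, self-care, usual activities,
#'   pain/discomfort, anxiety/depression; levels in `{1, 2, 3}`.
#' @param tariff A tariff list as returned by [eq5d_tariff_uk()] (the default).
#' @return Numeric vector of utilities, one per profile row.
#' @export
score_eq5d <- function(profiles, tariff = eq5d_tariff_uk()) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != 5L) stop("profiles must have five dimensions")
  storage.mode(profiles) <- "double"
  obs <- stats::complete.cases(profiles)
  bad <- obs & !apply(profiles, 1L, function(p) all(p %in% 1:3))
  if (any(bad)) {
    stop("invalid EQ-5D-3L level(s) outside {1,2,3} in row(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  }
  out <- rep(NA_real_, nrow(profiles))
  if (any(obs)) {
    p <- profiles[obs, , drop = FALSE]
    dec2 <- tariff$decrements["2", ]
    dec3 <- tariff$decrements["3", ]
    per_dim <- sweep(p == 2, 2L, dec2, "*") + sweep(p == 3, 2L, dec3, "*")
    u <- 1 - rowSums(per_dim) -
      tariff$constant * (rowSums(p > 1) > 0) -
      tariff$n3 * (rowSums(p == 3) > 0)
    out[obs] <- u
  }
  out
}

#' Enumerate all 243 EQ-5D-3L profiles
#'
#' @return A 243 x 5 integer matrix, one profile per row, in lexicographic
#'   order (11111 first, 33333 last).
#' @export
eq5d_profiles <- function() {
  g <- expand.grid(rev(replicate(5, 1:3, simplify = FALSE)))[, 5:1]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, EQ5D_DIMENSIONS)
  m[order(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5]), ]
}

# Nearest-tariff-value mapping from a latent utility to a 3L profile; ties go
# to the lexicographically smallest profile. Used by the trial generator so
# that scoring the generated profile round-trips to (approximately) the
# latent value.
nearest_profile_utility <- function(latent, tariff = eq5d_tariff_uk()) {
  prof <- eq5d_profiles()
  sc <- score_eq5d(prof, tariff)
  idx <- vapply(latent, function(u) which.min(abs(sc - u)), integer(1))
  list(profiles = prof[idx, , drop = FALSE], utility = sc[idx])
}
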