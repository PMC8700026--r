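#' Synthetic patient-level cost and EQ-5D-5L microdata
#'
#' The treatment-cost and utility rows of the parameter table came from
#' primary data collection at one provincial hospital (1631 cost
#' records, 218 quality-of-life surveys) that is not deposited. These
#' generators emulate that collection so the aggregation pipeline --
#' patient-level records in, (mean, SE) rows out -- can be exercised
#' and validated end to end. They are explicitly synthetic stand-ins.
#'
#' @name dmscreen-microdata
NULL

#' Generate synthetic annual treatment cost records
#'
#' Costs are gamma distributed (right-skewed, nonnegative) with the
#' requested mean and coefficient of variation.
#'
#' @param n Number of patients.
#' @param mean_cost Target mean annual cost (USD).
#' @param cv Coefficient of variation (sd / mean); 0 gives constant
#'   records.
#' @param state_label `"diagnosed"` or `"complication"`.
#' @param component `"medical"` or `"nonmedical"`.
#' @param seed Integer seed; `NULL` continues the RNG stream.
#' @return Data frame: `patient_id`, `state_label`,
#'   `perspective_component`, `annual_cost`.
#' @export
synth_cost_records <- function(n, mean_cost, cv, state_label = "diagnosed",
                               component = "medical", seed = NULL) {
  stopifnot(n >= 1, mean_cost > 0, cv >= 0)
  state_label <- match.arg(state_label, c("diagnosed", "complication"))
  component <- match.arg(component, c("medical", "nonmedical"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cost <- if (cv == 0) rep(mean_cost, n)
          else stats::rgamma(n, shape = 1 / cv^2, scale = mean_cost * cv^2)
  data.frame(patient_id = seq_len(n), state_label = state_label,
             perspective_component = component, annual_cost = cost)
}

#' Mean and standard error of a microdata column
#'
#' The estimator that turns patient-level records into a
#' (mean, SE-of-the-mean) parameter row: arithmetic mean and
#' `sd / sqrt(n)`.
#'
#' @param x Numeric vector, or a data frame with an `annual_cost` or
#'   `utility` column.
#' @return Named vector `c(mean, se)`.
#' @export
estimate_mean_se <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("annual_cost", "utility"), names(x))[1]
    if (is.na(col)) stop("no annual_cost or utility column found")
    x <- x[[col]]
  }
  n <- length(x)
  if (n < 2) stop("need at least 2 records to estimate an SE")
  c(mean = mean(x), se = stats::sd(x) / sqrt(n))
}

#' Additive-decrement EQ-5D-5L value-set stub
#'
#' A configurable stand-in for a national tariff: utility is
#' 1 minus the sum of per-dimension decrements, where the decrement of
#' a response at level L (1..5) is `(L - 1) / 4` times that dimension's
#' maximum decrement. An all-ones profile maps to exactly 1. Fidelity
#' to any published value set is not claimed.
#'
#' @param max_decrements Numeric length 5: maximum decrement per
#'   dimension (mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression) at level 5.
#' @return Function mapping a 5-column level matrix to utilities.
#' @export
eq5d_value_set_stub <- function(max_decrements =
                                  c(0.20, 0.15, 0.15, 0.20, 0.15)) {
  stopifnot(length(max_decrements) == 5, all(max_decrements >= 0))
  function(levels) {
    levels <- matrix(as.integer(levels), ncol = 5)
    if (any(levels < 1 | levels > 5)) stop("levels must be in 1..5")
    1 - as.vector((levels - 1L) %*% (max_decrements / 4))
  }
}

#' Generate synthetic EQ-5D-5L survey records
#'
#' Response levels are drawn per dimension from a severity-tilted
#' distribution: level L gets weight proportional to
#' `severity^(L - 1)` for `severity` in (0, 1], so severity 0 forces an
#' all-ones (full health) profile and increasing severity shifts mass
#' to worse levels; mean utility is strictly decreasing in severity.
#'
#' @param n Number of respondents.
#' @param state_label Health-state label attached to the records.
#' @param severity Scalar in \[0, 1\].
#' @param value_set Function from [eq5d_value_set_stub()].
#' @param seed Integer seed.
#' @return Data frame: `patient_id`, `state_label`, `mo`, `sc`, `ua`,
#'   `pd`, `ad` (levels 1..5), `utility`.
#' @export
synth_eq5d <- function(n, state_label = "diagnosed", severity = 0.3,
                       value_set = eq5d_value_set_stub(), seed = NULL) {
  stopifnot(n >= 1, severity >= 0, severity <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lv <- if (severity == 0) {
    matrix(1L, n, 5)
  } else {
    w <- severity^(0:4)
    matrix(sample.int(5L, n * 5, replace = TRUE, prob = w / sum(w)), n, 5)
  }
  u <- value_set(lv)
  data.frame(patient_id = seq_len(n), state_label = state_label,
             mo = lv[, 1], sc = lv[, 2], ua = lv[, 3], pd = lv[, 4],
             ad = lv[, 5], utility = u)
}
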