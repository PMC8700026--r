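#' Screening cascades at the two primary-care tiers
#'
#' Two delivery settings are modelled. At the commune health station
#' (CHS) the cascade is risk questionnaire -> fasting capillary glucose
#' -> referral to the district level -> confirmatory fasting plasma
#' glucose; only the referral leg is subject to the adherence
#' proportion. At the district health center (DHC) it is questionnaire
#' -> FPG -> immediate second FPG, all in one visit. Repeated tests are
#' treated as conditionally independent given true disease status, and
#' healthy subjects who run the full false-positive cascade return to
#' normal glucose tolerance (they incur cost but no treatment).
#'
#' @name dmscreen-screening
NULL

SETTINGS  <- c("CHS", "DHC")
INTERVALS <- c("one-off", "annual", "3-yearly")

#' Define a screening strategy
#'
#' @param setting `"CHS"` or `"DHC"`.
#' @param interval `"one-off"` (cycle 0 only), `"annual"` (every
#'   cycle), or `"3-yearly"` (cycles 0, 3, 6, ...).
#' @param start_age Age at which the cohort enters the model; the
#'   reference grid uses 30, 35, 40, 45 but any age is accepted.
#' @return Object of class `screening_strategy`.
#' @examples
#' screening_strategy("CHS", "annual", 40)
#' @export
screening_strategy <- function(setting, interval = "annual",
                               start_age = 40) {
  setting <- match.arg(setting, SETTINGS)
  interval <- match.arg(interval, INTERVALS)
  stopifnot(start_age >= 18, start_age < 100)
  structure(list(setting = setting, interval = interval,
                 start_age = start_age,
                 id = paste(setting, interval, start_age, sep = "_")),
            class = "screening_strategy")
}

#' Cycles in which screening is offered
#'
#' @param interval Screening interval keyword.
#' @param n_cycles Number of model cycles (screening can occur in
#'   cycles `0 .. n_cycles - 1`).
#' @return Integer vector of screening cycle indices (0-based).
#' @export
screening_cycles <- function(interval, n_cycles) {
  interval <- match.arg(interval, INTERVALS)
  switch(interval,
         `one-off` = 0L,
         annual = seq.int(0L, n_cycles - 1L),
         `3-yearly` = seq.int(0L, n_cycles - 1L, by = 3L))
}

#' Probability a truly diseased participant is detected in one round
#'
#' CHS chains questionnaire, capillary test, referral adherence and one
#' confirmatory plasma test; DHC chains questionnaire and two plasma
#' tests. Tests are conditionally independent given disease.
#'
#' @param strategy `screening_strategy`.
#' @param pset `parameter_set`.
#' @return Probability in \[0, 1\].
#' @export
detection_probability <- function(strategy, pset) {
  sn <- pset$sens
  if (strategy$setting == "CHS")
    unname(sn["findrisc"] * sn["fcg"] * pset$adherence_referral * sn["fpg"])
  else
    unname(sn["findrisc"] * sn["fpg"]^2)
}

# per-branch reach probabilities through the cascade for one true state
cascade_branches <- function(strategy, true_state, pset) {
  p_pos <- if (true_state == "diseased") pset$sens else 1 - pset$spec
  if (strategy$setting == "CHS") {
    p1 <- unname(p_pos["findrisc"])            # reaches FCG
    p2 <- p1 * unname(p_pos["fcg"])            # positive FCG
    p3 <- p2 * pset$adherence_referral         # attends DHC referral
    p4 <- p3 * unname(p_pos["fpg"])            # final positive
    list(reach_fcg = p1, reach_referral = p2, reach_fpg = p3,
         final_positive = p4)
  } else {
    p1 <- unname(p_pos["findrisc"])            # reaches first FPG
    p2 <- p1 * unname(p_pos["fpg"])            # reaches second FPG
    p3 <- p2 * unname(p_pos["fpg"])            # final positive
    list(reach_fpg1 = p1, reach_fpg2 = p2, final_positive = p3)
  }
}

#' Expected per-participant cost of one screening round
#'
#' Sums branch probability times branch cost over the cascade. Under
#' the societal perspective the setting's direct non-medical visit cost
#' is added once for the initial visit, and at CHS once more for the
#' referral trip to the district level (taken only by adherent
#' FCG-positives). The provider perspective counts test costs only.
#'
#' @param strategy `screening_strategy`.
#' @param true_state `"healthy"` or `"diseased"`.
#' @param perspective `"societal"` or `"provider"`.
#' @param pset `parameter_set`.
#' @return Expected cost in USD.
#' @export
expected_screening_cost <- function(strategy,
                                    true_state = c("healthy", "diseased"),
                                    perspective = c("societal", "provider"),
                                    pset) {
  true_state <- match.arg(true_state)
  perspective <- match.arg(perspective)
  b <- cascade_branches(strategy, true_state, pset)
  ct <- pset$cost_test
  societal <- perspective == "societal"
  if (strategy$setting == "CHS") {
    cost <- ct["findrisc"] +
      b$reach_fcg * ct["fcg"] +
      b$reach_fpg * ct["fpg"]
    if (societal)
      cost <- cost + pset$cost_visit["chs"] +
        b$reach_fpg * pset$cost_visit["dhc"]
  } else {
    cost <- ct["findrisc"] +
      b$reach_fpg1 * ct["fpg"] +
      b$reach_fpg2 * ct["fpg"]
    if (societal) cost <- cost + pset$cost_visit["dhc"]
  }
  unname(cost)
}

#' Full cascade outcome summary for one screening round
#'
#' @inheritParams detection_probability
#' @return Object of class `cascade_result`: detection probability for
#'   diseased participants, the probability a healthy participant runs
#'   the complete false-positive cascade (they are returned to normal
#'   glucose tolerance, untreated), and expected round costs by true
#'   state and perspective.
#' @export
misclassification_outcomes <- function(strategy, pset) {
  cost <- matrix(NA_real_, 2, 2,
                 dimnames = list(c("healthy", "diseased"),
                                 c("societal", "provider")))
  for (st in rownames(cost))
    for (pp in colnames(cost))
      cost[st, pp] <- expected_screening_cost(strategy, st, pp, pset)
  structure(list(
    strategy = strategy,
    p_detect_given_diseased = detection_probability(strategy, pset),
    p_full_false_cascade_given_healthy =
      cascade_branches(strategy, "healthy", pset)$final_positive,
    expected_cost = cost
  ), class = "cascade_result")
}
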