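#' Five-state lifetime Markov cohort engine
#'
#' States: normal glucose tolerance (NGT), undiagnosed T2DM (UNDX),
#' diagnosed T2DM (DX), T2DM with complication (COMP), and absorbing
#' DEAD. One-year cycles run from the cohort's starting age to the
#' closing age. Background mortality comes from a life table; the
#' diabetic states carry relative risks applied on the rate scale, with
#' the undiagnosed and complication states further scaled by their
#' predicted excess HbA1c over the diagnosed level. Screening moves
#' undiagnosed survivors into the diagnosed state in screening cycles.
#'
#' @name dmscreen-markov
NULL

STATES <- c("NGT", "UNDX", "DX", "COMP", "DEAD")

#' Apply a relative risk to an annual probability on the rate scale
#'
#' The probability is converted to a constant hazard, the hazard scaled
#' by `rr`, and converted back: `p' = 1 - (1 - p)^rr`. This is the
#' standard transformation for applying hazard ratios to annual
#' probabilities and reproduces the parameter table's derived
#' undiagnosed-to-complication entry; direct multiplication `rr * p`
#' does not.
#'
#' @param p Annual probability in \[0, 1).
#' @param rr Relative risk (hazard ratio), `> 0`.
#' @return Adjusted annual probability.
#' @examples
#' round(adjust_probability(0.0140, 1.40^1.5), 4) # 0.0231
#' @export
adjust_probability <- function(p, rr) {
  stopifnot(all(rr > 0))
  if (any(p < 0 | p >= 1))
    stop("p must lie in [0, 1): the rate transform is undefined at 1")
  1 - (1 - p)^rr
}

#' Relative-risk multiplier for an HbA1c difference
#'
#' A per-1-percentage-point risk ratio compounds geometrically over the
#' HbA1c gap: `rr_per_pct^(hba1c - ref_hba1c)`.
#'
#' @param rr_per_pct Risk ratio per 1% HbA1c increase.
#' @param hba1c HbA1c level of the state (%).
#' @param ref_hba1c Reference HbA1c level (%).
#' @return Multiplier (1 when the levels coincide).
#' @export
hba1c_multiplier <- function(rr_per_pct, hba1c, ref_hba1c) {
  stopifnot(rr_per_pct > 0)
  rr_per_pct^(hba1c - ref_hba1c)
}

#' Annual death probability by health state
#'
#' NGT dies at the background rate `qx`. Diagnosed T2DM carries the
#' overall T2DM mortality risk ratio; the undiagnosed and complication
#' states compound it with the per-1%-HbA1c mortality multiplier
#' raised to their HbA1c excess over the diagnosed level (the anchor of
#' the overall ratio). All ratios act on the rate scale.
#'
#' @param qx Background annual death probability.
#' @param state One of `"NGT"`, `"UNDX"`, `"DX"`, `"COMP"`.
#' @param pset `parameter_set`.
#' @return Annual death probability.
#' @export
state_mortality <- function(qx, state, pset) {
  state <- match.arg(state, STATES[1:4])
  if (qx >= 1) return(1)
  if (state == "NGT") return(qx)
  rr <- unname(pset$rr["death_t2dm"])
  if (state != "DX") {
    lev <- if (state == "UNDX") pset$hba1c["undx"] else pset$hba1c["comp"]
    rr <- rr * hba1c_multiplier(unname(pset$rr["death_per_hba1c"]),
                                unname(lev), unname(pset$hba1c["dx"]))
  }
  adjust_probability(qx, rr)
}

#' One row of the cycle transition matrix
#'
#' Death competes first at the state-specific probability; the
#' surviving mass is allocated to disease transitions and the residual
#' remains in state. In a screening cycle, screening detection and
#' clinical detection of undiagnosed T2DM combine as independent
#' events. If competing exit probabilities among survivors exceed 1
#' they are rescaled proportionally with a warning.
#'
#' @param state Origin state.
#' @param age Integer age at the start of the cycle.
#' @param screened Logical: is screening offered this cycle?
#' @param p_detect Per-round screening detection probability for a
#'   truly diseased participant (ignored unless `screened`).
#' @param pset `parameter_set`.
#' @param life_table `life_table` covering `age`.
#' @return Named probability vector over the five states, summing to 1.
#' @export
build_transition_row <- function(state, age, screened = FALSE,
                                 p_detect = 0, pset, life_table) {
  state <- match.arg(state, STATES)
  row <- stats::setNames(numeric(5), STATES)
  if (state == "DEAD") { row["DEAD"] <- 1; return(row) }
  i <- match(age, life_table$age)
  if (is.na(i)) stop("life table does not cover age ", age)
  qd <- state_mortality(life_table$qx[i], state, pset)
  surv <- 1 - qd
  tp <- pset$tp
  exits <- switch(state,
    NGT  = c(UNDX = unname(tp["ngt_undx"]), DX = unname(tp["ngt_dx"])),
    UNDX = {
      p_dx <- if (screened)
        1 - (1 - unname(tp["undx_dx"])) * (1 - p_detect)
      else unname(tp["undx_dx"])
      c(DX = p_dx, COMP = unname(tp["undx_comp"]))
    },
    DX   = c(COMP = unname(tp["dx_comp"])),
    COMP = c()
  )
  tot <- sum(exits)
  if (tot > 1) {
    warning("competing exits from ", state, " exceed 1 (", tot,
            "); rescaling proportionally")
    exits <- exits / tot
    tot <- 1
  }
  row["DEAD"] <- qd
  row[names(exits)] <- surv * exits
  row[state] <- surv * (1 - tot)
  row
}

#' Model run configuration
#'
#' @param start_age Cohort entry age.
#' @param strategy `screening_strategy` or `NULL` for no screening.
#' @param perspective `"societal"` or `"provider"`.
#' @param constants List from [model_constants()].
#' @return Object of class `model_config`.
#' @export
model_config <- function(start_age = 40, strategy = NULL,
                         perspective = c("societal", "provider"),
                         constants = model_constants()) {
  perspective <- match.arg(perspective)
  stopifnot(start_age < constants$max_age)
  if (!is.null(strategy)) {
    stopifnot(inherits(strategy, "screening_strategy"))
    if (strategy$start_age != start_age)
      stop("strategy start_age (", strategy$start_age,
           ") disagrees with config start_age (", start_age, ")")
  }
  structure(list(start_age = start_age, strategy = strategy,
                 perspective = perspective, constants = constants),
            class = "model_config")
}

# prevalence of undiagnosed T2DM at cohort entry, interpolated between
# the tabulated starting ages (constant outside their range)
entry_prevalence <- function(pset, start_age) {
  ages <- as.numeric(names(pset$prevalence))
  stats::approx(ages, unname(pset$prevalence), xout = start_age,
                rule = 2)$y
}

#' Run the cohort model
#'
#' The cohort enters with the starting-age prevalence of (undiagnosed)
#' T2DM in UNDX and the remainder in NGT -- already-diagnosed patients
#' are excluded from the screening program. Each cycle applies the
#' age-specific transition matrix; in screening cycles the NGT and
#' UNDX occupants are screened, accruing the cascade's expected cost
#' and (for UNDX) its detection probability. The horizon closes when
#' the life table's final age (with `qx = 1`) has been traversed.
#'
#' @param config `model_config`.
#' @param pset `parameter_set`.
#' @param life_table `life_table` covering the whole horizon.
#' @return Object of class `cohort_trace`: `occupancy` (cycle-by-state
#'   matrix, rows = time points 0..n_cycles), `screen_cost` (per-cycle
#'   undiscounted screening cost flow), `screened_cycles`, `config`.
#' @export
run_cohort <- function(config, pset, life_table) {
  start_age <- config$start_age
  max_age <- config$constants$max_age
  if (max(life_table$age) < max_age || min(life_table$age) > start_age)
    stop("life table does not cover ages ", start_age, "..", max_age)
  n_cycles <- max_age - start_age + 1L
  screen_set <- integer(0)
  p_detect <- 0
  cost_healthy <- cost_diseased <- 0
  if (!is.null(config$strategy)) {
    casc <- misclassification_outcomes(config$strategy, pset)
    p_detect <- casc$p_detect_given_diseased
    cost_healthy <- casc$expected_cost["healthy", config$perspective]
    cost_diseased <- casc$expected_cost["diseased", config$perspective]
    screen_set <- screening_cycles(config$strategy$interval, n_cycles)
  }
  occ <- matrix(0, n_cycles + 1L, 5L,
                dimnames = list(0:n_cycles, STATES))
  prev <- entry_prevalence(pset, start_age)
  occ[1L, ] <- c(1 - prev, prev, 0, 0, 0)
  screen_cost <- numeric(n_cycles + 1L)
  for (t in 0:(n_cycles - 1L)) {
    screened <- t %in% screen_set
    if (screened)
      screen_cost[t + 1L] <- occ[t + 1L, "NGT"] * cost_healthy +
        occ[t + 1L, "UNDX"] * cost_diseased
    P <- t(vapply(STATES, build_transition_row, numeric(5),
                  age = start_age + t, screened = screened,
                  p_detect = p_detect, pset = pset,
                  life_table = life_table))
    occ[t + 2L, ] <- occ[t + 1L, ] %*% P
  }
  structure(list(occupancy = occ, screen_cost = screen_cost,
                 screened_cycles = screen_set, config = config),
            class = "cohort_trace")
}

#' Composite Simpson's 1/3 within-cycle correction weights
#'
#' Weights over `n_intervals + 1` equally spaced cycle points such that
#' the weighted sum of a flow evaluated at the points approximates its
#' continuous-time integral: (1, 4, 2, 4, ..., 4, 1)/3. An odd number
#' of intervals is closed with the 3/8 rule over the final three. The
#' weights always sum to `n_intervals`.
#'
#' @param n_intervals Number of cycle intervals (`>= 2`).
#' @return Numeric weight vector of length `n_intervals + 1`.
#' @examples
#' simpson_weights(2) # 1/3, 4/3, 1/3
#' @export
simpson_weights <- function(n_intervals) {
  stopifnot(length(n_intervals) == 1L)
  if (n_intervals < 2) stop("need at least 2 intervals for Simpson's rule")
  n13 <- if (n_intervals %% 2 == 0) n_intervals else n_intervals - 3L
  w <- numeric(n_intervals + 1L)
  if (n13 > 0) {
    w13 <- rep(c(4, 2) / 3, length.out = n13 - 1L)
    w[1:(n13 + 1L)] <- c(1 / 3, w13[-length(w13)], 4 / 3, 1 / 3)
  }
  if (n13 < n_intervals) {
    # 3/8 closure over the last three intervals (n13 may be 0 when n=3)
    i <- (n13 + 1L):(n_intervals + 1L)
    w[i] <- w[i] + c(3, 9, 9, 3) / 8
  }
  w
}

#' Discounted economic outcomes of a cohort trace
#'
#' Continuous flows (treatment cost, life years, QALYs) are evaluated
#' at the cycle points, Simpson-weighted across cycles and discounted
#' at `(1 + r)^-t` with cycle 0 undiscounted. Screening costs are
#' point-in-time events: they are discounted with the cycle in which
#' the round occurs but carry no within-cycle correction weight.
#'
#' @param trace `cohort_trace`.
#' @param pset `parameter_set`.
#' @param config `model_config`; defaults to the one stored in the
#'   trace.
#' @return Object of class `econ_outcome` with components
#'   `screening_cost`, `treatment_cost`, `total_cost`, `ly`, `qaly`
#'   (all discounted).
#' @export
accumulate <- function(trace, pset, config = trace$config) {
  occ <- trace$occupancy
  n_pts <- nrow(occ)
  w <- simpson_weights(n_pts - 1L)
  r <- config$constants$discount_rate
  disc <- (1 + r)^(-(0:(n_pts - 1L)))
  cost_flow <- occ %*% state_costs(pset, config$perspective)
  qaly_flow <- occ %*% state_utilities(pset)
  ly_flow <- occ %*% c(1, 1, 1, 1, 0)
  treatment_cost <- sum(w * disc * cost_flow)
  screening_cost <- sum(disc * trace$screen_cost)
  structure(list(screening_cost = screening_cost,
                 treatment_cost = treatment_cost,
                 total_cost = screening_cost + treatment_cost,
                 ly = sum(w * disc * ly_flow),
                 qaly = sum(w * disc * qaly_flow),
                 perspective = config$perspective),
            class = "econ_outcome")
}

#' Run one strategy end to end
#'
#' Convenience wrapper: build the config, run the cohort, accumulate.
#'
#' @param strategy `screening_strategy` or `NULL` (no screening).
#' @param pset `parameter_set`.
#' @param life_table `life_table`.
#' @param start_age Entry age (taken from the strategy when given).
#' @param perspective Costing perspective.
#' @param constants [model_constants()].
#' @return `econ_outcome`.
#' @export
evaluate_strategy <- function(strategy, pset, life_table,
                              start_age = 40,
                              perspective = c("societal", "provider"),
                              constants = model_constants()) {
  perspective <- match.arg(perspective)
  if (!is.null(strategy)) start_age <- strategy$start_age
  cfg <- model_config(start_age, strategy, perspective, constants)
  accumulate(run_cohort(cfg, pset, life_table), pset, cfg)
}

#' Export a cohort trace as a data frame
#'
#' @param x `cohort_trace`.
#' @param ... Unused.
#' @return Data frame with cycle, age, the five occupancy columns and
#'   the undiscounted screening cost flow.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  cyc <- as.integer(rownames(x$occupancy))
  data.frame(cycle = cyc, age = x$config$start_age + cyc,
             as.data.frame(x$occupancy, row.names = FALSE),
             screen_cost = x$screen_cost)
}
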