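#' Moment-matched distribution fitting and the model parameter table
#'
#' Every model input is described by a (mean, SE, distribution) triple, the
#' only uncertainty information the source table provides. Probabilistic
#' draws therefore use method-of-moments fits: beta for probabilities and
#' utilities, gamma for costs, lognormal for relative risks, normal for
#' HbA1c levels. `fixed` rows never vary.
#'
#' @name dmscreen-params
NULL

PARAM_COLS <- c("name", "mean", "se", "dist", "dsa_rule", "se_kind",
                "n_obs", "units", "source")
DIST_KINDS <- c("beta", "gamma", "normal", "lognormal", "fixed")
DSA_RULES  <- c("pct20", "ci95", "none")

#' Fit a beta distribution by matching mean and standard error
#'
#' @param mean Mean, strictly inside (0, 1).
#' @param se Standard error (same scale); `se = 0` denotes a point mass.
#' @return List with elements `shape1`, `shape2` (both `NA` for a point
#'   mass, flagged by `point_mass = TRUE`).
#' @examples
#' beta_from_moments(0.864, 0.082)
#' @export
beta_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L,
            length(se) == 1L, se >= 0)
  if (mean <= 0 || mean >= 1)
    stop("beta mean must be strictly inside (0, 1), got ", mean)
  if (se == 0)
    return(list(shape1 = NA_real_, shape2 = NA_real_, point_mass = TRUE,
                mean = mean))
  if (se^2 >= mean * (1 - mean))
    stop("variance-infeasible: se^2 = ", se^2, " >= mean(1-mean) = ",
         mean * (1 - mean))
  k <- mean * (1 - mean) / se^2 - 1
  list(shape1 = mean * k, shape2 = (1 - mean) * k, point_mass = FALSE,
       mean = mean)
}

#' Fit a gamma distribution by matching mean and standard error
#'
#' @inheritParams beta_from_moments
#' @return List with elements `shape`, `scale`.
#' @examples
#' gamma_from_moments(100, 20) # shape 25, scale 4
#' @export
gamma_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L,
            length(se) == 1L, se >= 0)
  if (mean <= 0) stop("gamma mean must be positive, got ", mean)
  if (se == 0)
    return(list(shape = NA_real_, scale = NA_real_, point_mass = TRUE,
                mean = mean))
  list(shape = (mean / se)^2, scale = se^2 / mean, point_mass = FALSE,
       mean = mean)
}

#' Fit a lognormal distribution by matching arithmetic mean and SE
#'
#' The fitted parameters are on the log scale; the arithmetic mean of
#' draws equals `mean` (not the geometric mean).
#'
#' @inheritParams beta_from_moments
#' @return List with elements `meanlog`, `sdlog`.
#' @examples
#' lognormal_from_moments(1.89, 0.077)
#' @export
lognormal_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L,
            length(se) == 1L, se >= 0)
  if (mean <= 0) stop("lognormal mean must be positive, got ", mean)
  if (se == 0)
    return(list(meanlog = NA_real_, sdlog = NA_real_, point_mass = TRUE,
                mean = mean))
  sdlog2 <- log(1 + (se / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2),
       point_mass = FALSE, mean = mean)
}

#' Load the parameter specification table
#'
#' Reads the packaged transcription of the model input table (or a
#' user-supplied CSV with the same columns) and resolves the stored
#' dispersion entry into a usable standard error. The four primary-data
#' cost rows carry patient-level variances (USD^2) together with the
#' collection sample size; with `cost_se_mode = "variance"` (default)
#' these become SEs of the mean via `sqrt(variance / n)`. With
#' `cost_se_mode = "se"` the stored number is used as-is.
#'
#' @param path CSV path; `NULL` loads the packaged table.
#' @param cost_se_mode How to interpret `se` where `se_kind == "variance"`.
#' @return A `param_specs` data frame with an extra column `se_raw`
#'   keeping the entry as stored.
#' @export
param_specs <- function(path = NULL, cost_se_mode = c("variance", "se")) {
  cost_se_mode <- match.arg(cost_se_mode)
  if (is.null(path))
    path <- system.file("extdata", "table1_parameters.csv",
                        package = "dmscreen", mustWork = TRUE)
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PARAM_COLS, names(sp))
  if (length(missing_cols))
    stop("parameter file missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sp$name))
    stop("duplicated parameter names in ", path)
  if (!all(sp$dist %in% DIST_KINDS))
    stop("unknown distribution kind(s): ",
         paste(setdiff(sp$dist, DIST_KINDS), collapse = ", "))
  if (!all(sp$dsa_rule %in% DSA_RULES))
    stop("unknown dsa rule(s): ",
         paste(setdiff(sp$dsa_rule, DSA_RULES), collapse = ", "))
  sp$se_raw <- sp$se
  conv <- sp$se_kind == "variance" & cost_se_mode == "variance"
  if (any(conv)) {
    if (anyNA(sp$n_obs[conv]))
      stop("variance-kind rows need n_obs to convert to an SE")
    sp$se[conv] <- sqrt(sp$se_raw[conv] / sp$n_obs[conv])
  }
  bad <- sp$dist == "beta" & (sp$mean <= 0 | sp$mean >= 1)
  if (any(bad))
    stop("beta rows with mean outside (0,1): ",
         paste(sp$name[bad], collapse = ", "))
  structure(sp, class = c("param_specs", "data.frame"))
}

param_domain <- function(name) {
  # clipping domain by parameter family, keyed on the naming scheme
  if (grepl("^(prev_|sens_|spec_|p_|u_)|^adherence", name))
    c(0, 1)
  else if (grepl("^hba1c_", name))
    c(4, Inf)
  else
    c(0, Inf)
}

#' Random draws from one parameter specification
#'
#' Draws from the moment-matched distribution of a single table row.
#' This is the raw distribution machinery: no physical truncation is
#' applied here (see [sample_parameter_set()] for the model-facing
#' draw, which floors HbA1c levels and clips probabilities).
#'
#' @param spec One-row `param_specs` data frame (or list with `mean`,
#'   `se`, `dist`).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_spec <- function(spec, n) {
  m <- spec$mean; s <- spec$se
  if (spec$dist == "fixed" || s == 0) return(rep(m, n))
  switch(spec$dist,
    beta = {
      f <- beta_from_moments(m, s)
      stats::rbeta(n, f$shape1, f$shape2)
    },
    gamma = {
      f <- gamma_from_moments(m, s)
      stats::rgamma(n, shape = f$shape, scale = f$scale)
    },
    lognormal = {
      f <- lognormal_from_moments(m, s)
      stats::rlnorm(n, f$meanlog, f$sdlog)
    },
    normal = stats::rnorm(n, m, s),
    stop("unknown distribution kind: ", spec$dist)
  )
}

#' Deterministic sensitivity bounds for one parameter
#'
#' `pct20` gives mean +/- 20 percent; `ci95` gives mean -/+ 1.96 SE.
#' Bounds are clipped to the parameter's domain ([0,1] for
#' probabilities and utilities, a 4 percent floor for HbA1c,
#' nonnegative otherwise).
#'
#' @inheritParams draw_spec
#' @return Named numeric vector `c(low, high)`.
#' @export
dsa_bounds <- function(spec) {
  rule <- spec$dsa_rule
  if (is.null(rule) || rule == "none")
    stop("no DSA rule defined for parameter '", spec$name, "'")
  b <- switch(rule,
    pct20 = c(0.8, 1.2) * spec$mean,
    ci95  = spec$mean + c(-1.96, 1.96) * spec$se,
    stop("unknown dsa rule: ", rule))
  dom <- param_domain(spec$name)
  b <- pmin(pmax(b, dom[1]), dom[2])
  c(low = min(b, spec$mean), high = max(b, spec$mean))
}

#' One joint probabilistic draw of the full parameter set
#'
#' All parameters are drawn independently (the source table reports no
#' correlation structure). Normal HbA1c draws are floored at 4 percent;
#' any probability or utility draw leaving \[0, 1\] is clipped. Both
#' events are counted in the `clip_events` attribute of the result.
#'
#' @param specs `param_specs` table.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A [parameter_set()] built from the drawn values.
#' @export
sample_parameter_set <- function(specs, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  vals <- numeric(nrow(specs))
  clips <- 0L
  for (i in seq_len(nrow(specs))) {
    v <- draw_spec(specs[i, ], 1L)
    dom <- param_domain(specs$name[i])
    v2 <- min(max(v, dom[1]), dom[2])
    if (v2 != v) clips <- clips + 1L
    vals[i] <- v2
  }
  names(vals) <- specs$name
  ps <- parameter_set(values = vals)
  attr(ps, "clip_events") <- clips
  ps
}

#' Model constants
#'
#' Fixed quantities outside the probabilistic parameter table: annual
#' discount rate, willingness-to-pay threshold (one GDP per capita,
#' USD/QALY), the VND/USD exchange rate used to express costs, the
#' 1-year cycle length and the age at which the horizon closes.
#'
#' @param ... Name-value overrides.
#' @return Named list.
#' @export
model_constants <- function(...) {
  k <- list(discount_rate = 0.03, wtp_threshold = 2715.3, fx_rate = 23143,
            cycle_length = 1, max_age = 100)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(k))
  if (length(unknown))
    stop("unknown constant(s): ", paste(unknown, collapse = ", "))
  k[names(ov)] <- ov
  stopifnot(k$discount_rate >= 0, k$wtp_threshold > 0)
  k
}

#' Assemble a structured parameter set
#'
#' Turns a flat named vector of parameter values (by default the point
#' estimates of the packaged table) into the structured list the model
#' engines consume: prevalence by starting age, test operating
#' characteristics, HbA1c levels, relative risks, annual transition
#' probabilities, costs split by component, utilities, and the referral
#' adherence proportion.
#'
#' @param specs `param_specs` table used for default values.
#' @param values Optional named vector overriding/forming all values.
#' @return Object of class `parameter_set`.
#' @export
parameter_set <- function(specs = param_specs(), values = NULL) {
  if (is.null(values)) {
    values <- specs$mean
    names(values) <- specs$name
  }
  need <- function(nm) {
    if (!nm %in% names(values)) stop("missing parameter: ", nm)
    unname(values[[nm]])
  }
  ps <- list(
    prevalence = c(`30` = need("prev_t2dm_30"), `35` = need("prev_t2dm_35"),
                   `40` = need("prev_t2dm_40"), `45` = need("prev_t2dm_45")),
    sens = c(findrisc = need("sens_findrisc"), fcg = need("sens_fcg"),
             fpg = need("sens_fpg")),
    spec = c(findrisc = need("spec_findrisc"), fcg = need("spec_fcg"),
             fpg = need("spec_fpg")),
    hba1c = c(undx = need("hba1c_undx"), dx = need("hba1c_dx"),
              comp = need("hba1c_comp")),
    rr = c(death_t2dm = need("rr_death_t2dm"),
           death_per_hba1c = need("rr_death_per_hba1c"),
           comp_per_hba1c = need("rr_comp_per_hba1c")),
    tp = c(ngt_undx = need("p_ngt_undx"), ngt_dx = need("p_ngt_dx"),
           undx_dx = need("p_undx_dx"), undx_comp = need("p_undx_comp"),
           dx_comp = need("p_dx_comp")),
    cost_test = c(findrisc = need("cost_test_findrisc"),
                  fcg = need("cost_test_fcg"), fpg = need("cost_test_fpg")),
    cost_visit = c(chs = need("cost_nonmed_screen_chs"),
                   dhc = need("cost_nonmed_screen_dhc")),
    cost_med = c(ngt = 0, undx = need("cost_med_undx"),
                 dx = need("cost_med_dx"), comp = need("cost_med_comp")),
    cost_nonmed = c(ngt = 0, undx = need("cost_nonmed_undx"),
                    dx = need("cost_nonmed_dx"),
                    comp = need("cost_nonmed_comp")),
    utility = c(ngt = need("u_ngt"), undx = need("u_undx"),
                dx = need("u_dx"), comp = need("u_comp")),
    adherence_referral = need("adherence_referral")
  )
  stopifnot(all(ps$prevalence >= 0 & ps$prevalence <= 1),
            all(ps$utility >= 0 & ps$utility <= 1),
            all(ps$tp >= 0 & ps$tp <= 1),
            all(ps$cost_med >= 0), all(ps$cost_nonmed >= 0))
  structure(ps, class = "parameter_set")
}

#' Annual treatment cost per health state under a perspective
#'
#' Societal costs add direct non-medical treatment costs to the medical
#' component; the provider perspective counts medical costs only.
#'
#' @param pset `parameter_set`.
#' @param perspective `"societal"` or `"provider"`.
#' @return Named vector over the five states (DEAD costs nothing).
#' @export
state_costs <- function(pset, perspective = c("societal", "provider")) {
  perspective <- match.arg(perspective)
  med <- pset$cost_med[c("ngt", "undx", "dx", "comp")]
  tot <- if (perspective == "societal")
    med + pset$cost_nonmed[c("ngt", "undx", "dx", "comp")]
  else med
  c(NGT = unname(tot["ngt"]), UNDX = unname(tot["undx"]),
    DX = unname(tot["dx"]), COMP = unname(tot["comp"]), DEAD = 0)
}

#' Per-state utility vector
#'
#' @inheritParams state_costs
#' @return Named vector over the five states (DEAD has utility 0).
#' @export
state_utilities <- function(pset) {
  c(NGT = unname(pset$utility["ngt"]), UNDX = unname(pset$utility["undx"]),
    DX = unname(pset$utility["dx"]), COMP = unname(pset$utility["comp"]),
    DEAD = 0)
}
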