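#' Deterministic and probabilistic sensitivity analysis
#'
#' One-way DSA reruns the full model at each parameter's low and high
#' bound (holding the rest at base) and reports the incremental net
#' monetary benefit of a strategy pair, sorted for a tornado diagram.
#' The PSA draws all parameters jointly from their fitted
#' distributions -- one draw shared by every strategy per iteration --
#' and summarises the resulting cost/QALY clouds as cost-effectiveness
#' planes and acceptability curves.
#'
#' @name dmscreen-uncertainty
NULL

#' One-way deterministic sensitivity analysis (tornado)
#'
#' @param specs `param_specs` table; varied rows with
#'   `dsa_rule == "none"` are skipped (with a message).
#' @param alt `screening_strategy` of interest.
#' @param parameters Names of the parameters to vary; default all.
#' @param base Comparator strategy (`NULL` = no screening).
#' @param life_table `life_table`.
#' @param lambda Willingness-to-pay threshold.
#' @param perspective Costing perspective.
#' @param constants [model_constants()].
#' @return Data frame sorted by descending span: `parameter`, `low`,
#'   `high` (the parameter bounds), `nmb_low`, `nmb_high` (incremental
#'   NMB at each bound), `span`. The base-case incremental NMB is
#'   attached as attribute `"base_nmb"`.
#' @export
one_way_dsa <- function(specs, alt, base = NULL, life_table,
                        lambda = model_constants()$wtp_threshold,
                        perspective = "societal",
                        constants = model_constants(),
                        parameters = specs$name) {
  stopifnot(all(parameters %in% specs$name))
  start_age <- alt$start_age
  inc_nmb <- function(values) {
    ps <- parameter_set(specs, values)
    o_alt <- evaluate_strategy(alt, ps, life_table, start_age,
                               perspective, constants)
    o_base <- evaluate_strategy(base, ps, life_table, start_age,
                                perspective, constants)
    nmb(o_alt, lambda) - nmb(o_base, lambda)
  }
  base_values <- stats::setNames(specs$mean, specs$name)
  base_nmb <- inc_nmb(base_values)
  sel <- specs$name %in% parameters
  varied <- sel & specs$dsa_rule != "none"
  if (any(sel & !varied))
    message("skipping parameter(s) without a DSA rule: ",
            paste(specs$name[sel & !varied], collapse = ", "))
  rows <- lapply(which(varied), function(i) {
    b <- dsa_bounds(specs[i, ])
    v_lo <- base_values; v_lo[specs$name[i]] <- b["low"]
    v_hi <- base_values; v_hi[specs$name[i]] <- b["high"]
    data.frame(parameter = specs$name[i], low = unname(b["low"]),
               high = unname(b["high"]), nmb_low = inc_nmb(v_lo),
               nmb_high = inc_nmb(v_hi))
  })
  d <- do.call(rbind, rows)
  d$span <- abs(d$nmb_high - d$nmb_low)
  d <- d[order(-d$span), ]
  rownames(d) <- NULL
  attr(d, "base_nmb") <- base_nmb
  d
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_draws` Monte Carlo iterations. Each iteration samples one
#' joint parameter set (common random parameters across strategies)
#' and reruns every strategy, recording discounted total cost and
#' QALYs. The whole run is reproducible from `seed`.
#'
#' @param specs `param_specs` table.
#' @param strategies Named list of `screening_strategy`s; a `NULL`
#'   element denotes no screening (conventionally named
#'   `"no_screening"`).
#' @param life_table `life_table`.
#' @param n_draws Number of iterations (the reference analysis used
#'   1000).
#' @param seed Integer seed.
#' @param start_age Entry age for the no-screening comparator.
#' @param perspective Costing perspective.
#' @param constants [model_constants()].
#' @return Object of class `psa_draws`: `draws` (long data frame with
#'   `draw`, `strategy`, `cost`, `qaly`), `n_draws`, `seed`,
#'   `strategies`.
#' @export
run_psa <- function(specs, strategies, life_table, n_draws = 1000,
                    seed = 1L, start_age = 40,
                    perspective = "societal",
                    constants = model_constants()) {
  stopifnot(n_draws >= 1, length(strategies) >= 1,
            !is.null(names(strategies)))
  set.seed(as.integer(seed))
  nm <- names(strategies)
  out <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    ps <- sample_parameter_set(specs, seed = NULL)
    res <- lapply(strategies, function(s)
      evaluate_strategy(s, ps, life_table, start_age, perspective,
                        constants))
    out[[k]] <- data.frame(
      draw = k, strategy = nm,
      cost = vapply(res, function(o) o$total_cost, numeric(1)),
      qaly = vapply(res, function(o) o$qaly, numeric(1)),
      row.names = NULL)
  }
  structure(list(draws = do.call(rbind, out), n_draws = n_draws,
                 seed = seed, strategies = nm),
            class = "psa_draws")
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value the probability that a strategy
#' maximises net monetary benefit across the draw set; exact ties
#' split their probability mass equally. Probabilities across the
#' mutually exclusive strategy set sum to 1 at every threshold. A
#' pairwise rule (probability of beating the named comparator only) is
#' available as an option.
#'
#' @param psa `psa_draws`.
#' @param lambda_grid Thresholds (default 0 to 3 GDP per capita in 100
#'   steps).
#' @param rule `"max-nmb"` (joint) or `"pairwise"`.
#' @param base Comparator strategy name, required for the pairwise
#'   rule.
#' @return Data frame of class `ceac_curve`: `lambda` plus one
#'   probability column per strategy.
#' @export
ceac <- function(psa, lambda_grid = seq(0, 3 * 2715.3, length.out = 101),
                 rule = c("max-nmb", "pairwise"), base = NULL) {
  rule <- match.arg(rule)
  d <- psa$draws
  if (!nrow(d)) stop("empty draw set")
  cost <- matrix(d$cost, nrow = psa$n_draws, byrow = TRUE,
                 dimnames = list(NULL, psa$strategies))
  qaly <- matrix(d$qaly, nrow = psa$n_draws, byrow = TRUE,
                 dimnames = list(NULL, psa$strategies))
  probs <- vapply(lambda_grid, function(l) {
    nb <- l * qaly - cost
    if (rule == "max-nmb") {
      best <- nb == apply(nb, 1, max)
      colMeans(best / rowSums(best))
    } else {
      if (is.null(base) || !base %in% psa$strategies)
        stop("pairwise rule needs a valid 'base' strategy name")
      wins <- nb > nb[, base]
      ties <- nb == nb[, base]
      colMeans(wins + ties / 2)
    }
  }, numeric(length(psa$strategies)))
  out <- data.frame(lambda = lambda_grid, t(probs))
  names(out) <- c("lambda", psa$strategies)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Cost-effectiveness plane point cloud
#'
#' Per-draw incremental (QALY, cost) pairs of every strategy against a
#' chosen comparator, with quadrant counts (NE, SE, SW, NW by the sign
#' of delta QALY / delta cost).
#'
#' @param psa `psa_draws`.
#' @param base Comparator strategy name.
#' @return List: `points` (data frame `draw`, `strategy`,
#'   `delta_qaly`, `delta_cost`), `quadrants` (count matrix strategy x
#'   quadrant).
#' @export
ce_plane <- function(psa, base = "no_screening") {
  if (!base %in% psa$strategies)
    stop("base strategy '", base, "' not present in the draw set")
  d <- psa$draws
  b <- d[d$strategy == base, ]
  others <- setdiff(psa$strategies, base)
  pts <- do.call(rbind, lapply(others, function(s) {
    a <- d[d$strategy == s, ]
    data.frame(draw = a$draw, strategy = s,
               delta_qaly = a$qaly - b$qaly,
               delta_cost = a$cost - b$cost)
  }))
  quad <- with(pts, ifelse(delta_qaly >= 0,
                           ifelse(delta_cost >= 0, "NE", "SE"),
                           ifelse(delta_cost >= 0, "NW", "SW")))
  quadrants <- table(strategy = pts$strategy,
                     quadrant = factor(quad,
                                       levels = c("NE", "SE", "SW", "NW")))
  list(points = pts, quadrants = quadrants)
}
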