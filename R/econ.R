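#' Decision metrics: ICER, dominance, net monetary benefit, frontier
#'
#' @name dmscreen-econ
NULL

#' Incremental cost-effectiveness of one strategy against a comparator
#'
#' Classifies the (delta cost, delta QALY) pair by quadrant. A strategy
#' that costs less and yields more QALYs is `dominant`; more costly and
#' less effective is `dominated`; zero QALY difference yields a flag,
#' never a division. Ratios in the southwest quadrant (cheaper, less
#' effective) are reported with their own tag.
#'
#' @param base Comparator `econ_outcome`.
#' @param alt Alternative `econ_outcome`.
#' @return Object of class `comparison_result`: `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer` (NA when flagged), `flag` (one of
#'   `"icer"`, `"icer-southwest"`, `"dominant"`, `"dominated"`,
#'   `"dominated-or-equal"`, `"dominant-or-equal"`, `"equivalent"`).
#' @export
icer <- function(base, alt) {
  stopifnot(inherits(base, "econ_outcome"), inherits(alt, "econ_outcome"))
  if (!identical(base$perspective, alt$perspective))
    stop("comparing outcomes from different perspectives")
  dc <- alt$total_cost - base$total_cost
  dq <- alt$qaly - base$qaly
  dl <- alt$ly - base$ly
  if (dq == 0) {
    flag <- if (dc > 0) "dominated-or-equal"
            else if (dc < 0) "dominant-or-equal" else "equivalent"
    ratio <- NA_real_
  } else if (dc < 0 && dq > 0) {
    flag <- "dominant"; ratio <- NA_real_
  } else if (dc > 0 && dq < 0) {
    flag <- "dominated"; ratio <- NA_real_
  } else {
    flag <- if (dc < 0 && dq < 0) "icer-southwest" else "icer"
    ratio <- dc / dq
  }
  structure(list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
                 icer = ratio, flag = flag),
            class = "comparison_result")
}

#' Net monetary benefit
#'
#' `lambda * QALY - cost` at willingness-to-pay `lambda` (USD/QALY).
#'
#' @param outcome `econ_outcome` (or anything with `qaly` and
#'   `total_cost`).
#' @param lambda Willingness-to-pay threshold, `>= 0`.
#' @return NMB in USD.
#' @export
nmb <- function(outcome, lambda = model_constants()$wtp_threshold) {
  stopifnot(lambda >= 0)
  lambda * outcome$qaly - outcome$total_cost
}

#' Rank strategies by net monetary benefit
#'
#' Descending NMB; exact ties are broken by lower cost, then by the
#' strategy identifier, and flagged.
#'
#' @param outcomes Named list of `econ_outcome`s.
#' @param lambda Willingness-to-pay threshold.
#' @return Data frame: `id`, `cost`, `qaly`, `nmb`, `rank`, `tied`.
#' @export
rank_strategies <- function(outcomes,
                            lambda = model_constants()$wtp_threshold) {
  stopifnot(length(outcomes) >= 2, !is.null(names(outcomes)))
  d <- data.frame(
    id = names(outcomes),
    cost = vapply(outcomes, function(o) o$total_cost, numeric(1)),
    qaly = vapply(outcomes, function(o) o$qaly, numeric(1)),
    row.names = NULL)
  d$nmb <- lambda * d$qaly - d$cost
  d <- d[order(-d$nmb, d$cost, d$id), ]
  d$rank <- seq_len(nrow(d))
  d$tied <- duplicated(d$nmb) | duplicated(d$nmb, fromLast = TRUE)
  rownames(d) <- NULL
  d
}

#' Incremental (efficiency frontier) analysis
#'
#' Sorts strategies by cost, removes strongly dominated entries (at
#' least as costly as another with no more QALYs), then removes
#' extended-dominated entries until the stepwise ICERs along the
#' frontier are strictly increasing.
#'
#' @param outcomes Named list of `econ_outcome`s.
#' @return Data frame of the surviving frontier in cost order:
#'   `id`, `cost`, `qaly`, `icer` (vs the previous frontier member; NA
#'   for the cheapest). Excluded strategies and their exclusion reason
#'   are attached as attribute `"excluded"`.
#' @export
incremental_frontier <- function(outcomes) {
  stopifnot(length(outcomes) >= 1, !is.null(names(outcomes)))
  d <- data.frame(
    id = names(outcomes),
    cost = vapply(outcomes, function(o) o$total_cost, numeric(1)),
    qaly = vapply(outcomes, function(o) o$qaly, numeric(1)),
    row.names = NULL)
  d <- d[order(d$cost, -d$qaly), ]
  excluded <- data.frame(id = character(0), reason = character(0))
  # strong dominance: a cheaper (or equal-cost, higher-QALY) strategy
  # with at least the same QALYs exists
  keep <- rep(TRUE, nrow(d))
  best_q <- -Inf
  for (i in seq_len(nrow(d))) {
    if (d$qaly[i] <= best_q) {
      keep[i] <- FALSE
      excluded <- rbind(excluded,
                        data.frame(id = d$id[i], reason = "dominated"))
    } else best_q <- d$qaly[i]
  }
  d <- d[keep, ]
  # extended dominance: drop members whose stepwise ICER is not
  # strictly increasing
  repeat {
    if (nrow(d) <= 2) break
    ic <- diff(d$cost) / diff(d$qaly)
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    drop_i <- bad[1] + 1L
    excluded <- rbind(excluded,
                      data.frame(id = d$id[drop_i],
                                 reason = "extended-dominated"))
    d <- d[-drop_i, ]
  }
  d$icer <- c(NA_real_, diff(d$cost) / diff(d$qaly))
  rownames(d) <- NULL
  attr(d, "excluded") <- excluded
  d
}
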