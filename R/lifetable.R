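#' Synthetic period life tables under a Gompertz-Makeham law
#'
#' The original analysis used a national statistics-office life table
#' that is not publicly deposited. The stand-in is a single-age period
#' table generated from the Gompertz-Makeham hazard
#' mu(x) = c + a * exp(b * x), calibrated so that life expectancy at
#' birth hits a chosen target.
#'
#' @name dmscreen-lifetable
NULL

#' Build a life table from Gompertz-Makeham parameters
#'
#' Annual death probabilities are `qx = 1 - exp(-(c + a * exp(b * x)))`
#' for integer ages `0..max_age`, with the closing row forced to 1 so
#' the cohort model's horizon is finite.
#'
#' @param makeham_a Gompertz level parameter `a > 0` (per year).
#' @param gompertz_b Gompertz slope `b > 0` (per year of age).
#' @param makeham_c Age-independent hazard `c >= 0` (per year).
#' @param max_age Closing age (default 100).
#' @return A `life_table` data frame with columns `age`, `qx`.
#' @examples
#' lt <- make_life_table(5e-5, 0.095, 5e-4)
#' lt$qx[lt$age == 40]
#' @export
make_life_table <- function(makeham_a, gompertz_b, makeham_c = 0,
                            max_age = 100) {
  stopifnot(makeham_a > 0, gompertz_b > 0, makeham_c >= 0, max_age > 60)
  age <- 0:max_age
  qx <- 1 - exp(-(makeham_c + makeham_a * exp(gompertz_b * age)))
  if (any(qx[age < 60] >= 1))
    stop("calibration error: qx reaches 1 before age 60; ",
         "hazard parameters implausibly large")
  qx[length(qx)] <- 1
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Life expectancy at birth from a life table
#'
#' Standard survivorship accumulation: `l(0) = 1`,
#' `l(x+1) = l(x) (1 - qx)`, with deaths within each year assumed to
#' occur on average at mid-year, so `e0 = sum_x l(x) (1 - qx / 2)`.
#'
#' @param lt `life_table`.
#' @return Years of expected life at birth.
#' @export
life_expectancy <- function(lt) {
  stopifnot(is.data.frame(lt), all(c("age", "qx") %in% names(lt)))
  lx <- cumprod(c(1, 1 - lt$qx[-nrow(lt)]))
  sum(lx * (1 - lt$qx / 2))
}

#' Calibrate a life table to a life-expectancy target
#'
#' One-dimensional root search over the Gompertz level `a` (on the log
#' scale), holding slope and background hazard fixed, until life
#' expectancy at birth matches `target_e0` within `tol`.
#'
#' @param target_e0 Target life expectancy at birth, years (40-95).
#' @param gompertz_b Fixed Gompertz slope (default 0.095).
#' @param makeham_c Fixed background hazard (default 5e-4).
#' @param max_age Closing age.
#' @param tol Calibration tolerance in years (default 0.1).
#' @return Calibrated `life_table`; the achieved `e0` and parameters
#'   are attached as attributes.
#' @examples
#' lt <- calibrate_life_table(73.6)
#' life_expectancy(lt)
#' @export
calibrate_life_table <- function(target_e0, gompertz_b = 0.095,
                                 makeham_c = 5e-4, max_age = 100,
                                 tol = 0.1) {
  stopifnot(target_e0 > 40, target_e0 < 95)
  f <- function(log_a) {
    life_expectancy(make_life_table(exp(log_a), gompertz_b, makeham_c,
                                    max_age)) - target_e0
  }
  lo <- log(1e-8); hi <- log(5e-2)
  if (f(lo) < 0 || f(hi) > 0)
    stop("target e0 = ", target_e0, " not bracketable with b = ",
         gompertz_b, ", c = ", makeham_c)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)
  a <- exp(root$root)
  lt <- make_life_table(a, gompertz_b, makeham_c, max_age)
  e0 <- life_expectancy(lt)
  if (abs(e0 - target_e0) > tol)
    stop("calibration failed: achieved e0 = ", e0)
  attr(lt, "e0") <- e0
  attr(lt, "params") <- c(makeham_a = a, gompertz_b = gompertz_b,
                          makeham_c = makeham_c)
  lt
}

#' Read / write a life table as two-column CSV
#'
#' @param path File path.
#' @return `read_life_table` returns a `life_table`;
#'   `write_life_table` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table CSV must have header columns 'age' and 'qx'")
  if (any(lt$qx <= 0 | lt$qx > 1))
    stop("life table qx values must lie in (0, 1]")
  if (any(diff(lt$age) != 1))
    stop("life table must cover consecutive single ages")
  structure(lt[, c("age", "qx")], class = c("life_table", "data.frame"))
}

#' @rdname read_life_table
#' @param lt `life_table` to write.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "qx")], path,
                   row.names = FALSE)
  invisible(path)
}
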