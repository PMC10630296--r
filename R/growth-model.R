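#' Double-logistic growth parameters
#'
#' Container for the six population-level parameters of the double-logistic
#' growth equation: two additive logistic phases (prepubertal and adolescent)
#' that together describe a smooth, monotonically increasing trait size with
#' an asymptote at growth cessation.
#'
#' @param f asymptotic trait size at growth cessation (mm).
#' @param a1 prepubertal-phase asymptote (mm).
#' @param b1 prepubertal growth-rate parameter (1/year); must be positive.
#' @param c1 age at maximal prepubertal growth rate (years).
#' @param b2 adolescent growth-rate parameter (1/year); must be positive.
#' @param c2 age at maximal adolescent growth rate (years).
#'
#' @details Positivity of \code{b1} and \code{b2} guarantees each phase is
#'   non-decreasing; the summed curve is then monotone whenever
#'   \code{f >= a1}. \code{f < a1} is permitted (the adolescent phase then
#'   removes size) but triggers a warning because monotonicity is no longer
#'   guaranteed.
#'
#' @return An object of class \code{growth_params} (named list).
#' @export
#' @examples
#' gp <- growth_params(f = 100, a1 = 85, b1 = 0.8, c1 = 6, b2 = 0.9, c2 = 12)
#' double_logistic(12, gp)
growth_params <- function(f, a1, b1, c1, b2, c2) {
  vals <- c(f = f, a1 = a1, b1 = b1, c1 = c1, b2 = b2, c2 = c2)
  if (any(!is.finite(vals)))
    stop("all growth parameters must be finite, got: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (b1 <= 0 || b2 <= 0)
    stop("rate parameters b1 and b2 must be positive")
  if (f <= 0 || a1 < 0)
    stop("size parameters must satisfy f > 0 and a1 >= 0")
  if (f < a1)
    warning("f < a1: the adolescent phase is negative and the growth curve ",
            "is not guaranteed to be monotone")
  structure(as.list(vals), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Double-logistic growth parameters:\n")
  cat(sprintf("  f  = %8.3f mm   (asymptote at cessation)\n", x$f))
  cat(sprintf("  a1 = %8.3f mm   (prepubertal asymptote)\n", x$a1))
  cat(sprintf("  b1 = %8.3f /y   c1 = %6.2f y  (prepubertal rate, timing)\n",
              x$b1, x$c1))
  cat(sprintf("  b2 = %8.3f /y   c2 = %6.2f y  (adolescent rate, timing)\n",
              x$b2, x$c2))
  invisible(x)
}

as_growth_params <- function(x) {
  if (inherits(x, "growth_params")) return(x)
  x <- as.list(x)
  growth_params(x$f, x$a1, x$b1, x$c1, x$b2, x$c2)
}

check_ages <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)))
    stop("age must be finite numeric")
  invisible(age)
}

#' Evaluate the double-logistic growth curve
#'
#' Predicted trait size at given ages:
#' \deqn{y(age) = \frac{a_1}{1 + e^{-b_1 (age - c_1)}} +
#'               \frac{f - a_1}{1 + e^{-b_2 (age - c_2)}}}
#'
#' @param age numeric vector of ages (years).
#' @param params a \code{\link{growth_params}} object (or coercible list).
#' @return numeric vector of predicted sizes (mm), same length as \code{age}.
#' @export
double_logistic <- function(age, params) {
  params <- as_growth_params(params)
  check_ages(age)
  params$a1 * stats::plogis(params$b1 * (age - params$c1)) +
    (params$f - params$a1) * stats::plogis(params$b2 * (age - params$c2))
}

#' Growth velocity (first derivative of the growth curve)
#'
#' Closed-form derivative of \code{\link{double_logistic}} with respect to
#' age: \eqn{a_1 b_1 S_1 (1 - S_1) + (f - a_1) b_2 S_2 (1 - S_2)} where
#' \eqn{S_k} are the two logistic terms. Non-negative everywhere when
#' \code{f >= a1}.
#'
#' @inheritParams double_logistic
#' @return numeric vector of growth rates (mm/year).
#' @export
growth_velocity <- function(age, params) {
  params <- as_growth_params(params)
  check_ages(age)
  s1 <- stats::plogis(params$b1 * (age - params$c1))
  s2 <- stats::plogis(params$b2 * (age - params$c2))
  params$a1 * params$b1 * s1 * (1 - s1) +
    (params$f - params$a1) * params$b2 * s2 * (1 - s2)
}

#' Locate peak growth velocity and related milestones
#'
#' Finds the age at peak growth velocity (aPGV) as the global maximum of
#' \code{\link{growth_velocity}} over an age window, by dense grid search
#' followed by golden-section refinement within one grid step of the best
#' grid point. Ties are broken toward the older age. The milestone set also
#' records which growth phase (prepubertal or adolescent) contributes more
#' velocity at the peak.
#'
#' @param params a \code{\link{growth_params}} object.
#' @param age_window numeric length-2, \code{c(lo, hi)} in years,
#'   \code{lo < hi}. Defaults to \code{c(5, 20)}, the standard comparison
#'   window past the early-childhood deceleration.
#' @param grid_step grid spacing in years for the initial search
#'   (default 0.01).
#' @return An object of class \code{milestones}: list with \code{pgv}
#'   (mm/year), \code{apgv} (years), \code{asymptote} (mm, = \code{f}),
#'   and \code{phase} (\code{"prepubertal"} or \code{"adolescent"}).
#' @export
find_milestones <- function(params, age_window = c(5, 20), grid_step = 0.01) {
  params <- as_growth_params(params)
  if (length(age_window) != 2 || any(!is.finite(age_window)) ||
      age_window[1] >= age_window[2])
    stop("age_window must be c(lo, hi) with lo < hi")
  grid <- seq(age_window[1], age_window[2], by = grid_step)
  if (grid[length(grid)] < age_window[2]) grid <- c(grid, age_window[2])
  v <- growth_velocity(grid, params)
  # last index attaining the max: tie toward older age
  best <- max(which(v == max(v)))
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(function(a) growth_velocity(a, params),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-9)
    # keep the refinement only if it does not lose to the grid point
    if (opt$objective >= v[best]) {
      apgv <- opt$maximum
      pgv <- opt$objective
    } else {
      apgv <- grid[best]
      pgv <- v[best]
    }
  } else {
    apgv <- grid[best]
    pgv <- v[best]
  }
  s1 <- stats::plogis(params$b1 * (apgv - params$c1))
  s2 <- stats::plogis(params$b2 * (apgv - params$c2))
  v1 <- params$a1 * params$b1 * s1 * (1 - s1)
  v2 <- (params$f - params$a1) * params$b2 * s2 * (1 - s2)
  structure(list(pgv = pgv, apgv = apgv, asymptote = params$f,
                 phase = if (v1 >= v2) "prepubertal" else "adolescent"),
            class = "milestones")
}

#' @export
print.milestones <- function(x, ...) {
  cat(sprintf("Growth milestones: PGV = %.3f mm/y at aPGV = %.3f y (%s phase); asymptote f = %.2f mm\n",
              x$pgv, x$apgv, x$phase, x$asymptote))
  invisible(x)
}

#' Percent measurement error relative to trait size
#'
#' Expresses an absolute measurement error as a percentage of the measured
#' size: the same 0.2 cm error is 0.25% of an 80 cm infant but only 0.11%
#' of a 180 cm adult, which is why large-magnitude traits such as stature
#' are less sensitive to measurement error than small craniofacial
#' distances.
#'
#' @param abs_error absolute measurement error (same units as \code{size}).
#' @param size measured trait size.
#' @return percent error, \code{100 * abs_error / size}.
#' @export
percent_measurement_error <- function(abs_error, size) {
  if (any(size <= 0)) stop("size must be positive")
  if (any(abs_error < 0)) stop("abs_error must be non-negative")
  100 * abs_error / size
}
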