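#' Overage cost schedule
#'
#' The overage cost of a resource is strictly increasing and convex in the
#' overage level z: overtime gets disproportionately expensive as more
#' consumers exceed the ideal level. The center elicits marginal costs for
#' the first `Z0` units only; beyond that, a zero-intercept quadratic trend
#' `y = a z + b z^2`, least-squares fitted to the `Z0` cumulative cost
#' points, extrapolates the cumulative cost. Note the two pieces are not
#' forced to agree at `z = Z0` (the fitted curve smooths the elicited
#' points); the table is authoritative up to `Z0` and the curve is used
#' strictly beyond it.
#'
#' The default marginal costs are the case-study elicitation: 2,500 NTD for
#' each of the first three overage units, 5,000 for the next three, 10,000
#' for the next three, and 20,000 for the tenth.
#'
#' @param marginal positive, nondecreasing vector of per-unit marginal costs
#'   for overage units `1..Z0` (currency units).
#' @param coefficients optional explicit `c(a, b)` override for the
#'   extrapolation; by default they are fitted with [fit_extrapolation()].
#' @return Object of class `cost_schedule` with elements `marginal`,
#'   `cumulative` and `coefficients` (named `a`, `b`).
#' @seealso [overage_cost()], [fit_extrapolation()]
#' @export
#' @examples
#' sched <- cost_schedule()
#' overage_cost(c(5, 10, 12), sched)
cost_schedule <- function(marginal = c(2500, 2500, 2500, 5000, 5000, 5000,
                                       10000, 10000, 10000, 20000),
                          coefficients = NULL) {
  if (length(marginal) < 2) stop("need at least two marginal costs")
  if (any(marginal <= 0)) stop("marginal costs must be positive")
  if (any(diff(marginal) < 0))
    stop("marginal costs must be nondecreasing (convex cumulative cost)")
  cumulative <- cumsum(marginal)
  if (is.null(coefficients)) {
    coefficients <- fit_extrapolation(seq_along(cumulative), cumulative)
  } else {
    stopifnot(length(coefficients) == 2)
    coefficients <- stats::setNames(as.numeric(coefficients), c("a", "b"))
  }
  structure(
    list(marginal = marginal, cumulative = cumulative,
         coefficients = coefficients),
    class = "cost_schedule"
  )
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat("<cost_schedule> marginal costs for overage units 1..",
      length(x$marginal), ":\n", sep = "")
  print(x$marginal)
  cat(sprintf("extrapolation beyond %d units: y = %.3f z + %.2f z^2\n",
              length(x$marginal), x$coefficients["a"], x$coefficients["b"]))
  invisible(x)
}

#' Fit the zero-intercept quadratic cost extrapolation
#'
#' Ordinary least squares fit of `y = a z + b z^2` (no intercept) to the
#' cumulative overage-cost points.
#'
#' @param z positive, distinct overage levels.
#' @param y cumulative overage costs at those levels.
#' @return Named numeric vector `c(a, b)`.
#' @export
#' @examples
#' fit_extrapolation(1:10, cumsum(c(2500, 2500, 2500, 5000, 5000, 5000,
#'                                  10000, 10000, 10000, 20000)))
fit_extrapolation <- function(z, y) {
  if (length(z) < 2 || length(y) != length(z))
    stop("need at least two (z, y) points")
  if (any(z <= 0) || anyDuplicated(z))
    stop("overage levels must be positive and distinct")
  fit <- stats::lm(y ~ 0 + z + I(z^2))
  co <- stats::coef(fit)
  if (anyNA(co)) stop("degenerate design: cannot fit quadratic trend")
  stats::setNames(as.numeric(co), c("a", "b"))
}

#' Cumulative overage cost at an overage level
#'
#' Zero for `z <= 0`; the summed marginal costs for `1 <= z <= Z0`; the
#' fitted quadratic, rounded to the nearest whole currency unit, for
#' `z > Z0`.
#'
#' @param z integer overage level(s); vectorized.
#' @param schedule a [cost_schedule()].
#' @return Numeric vector of costs in currency units.
#' @export
overage_cost <- function(z, schedule) {
  stopifnot(inherits(schedule, "cost_schedule"))
  z0 <- length(schedule$marginal)
  a <- schedule$coefficients[["a"]]
  b <- schedule$coefficients[["b"]]
  out <- numeric(length(z))
  tab <- z >= 1 & z <= z0
  out[tab] <- schedule$cumulative[z[tab]]
  extra <- z > z0
  out[extra] <- round(a * z[extra] + b * z[extra]^2)
  out
}

#' Scale a cost schedule by a common multiplier
#'
#' Used by sensitivity analysis: the marginal table is scaled and the
#' quadratic extrapolation refitted to the scaled cumulative points.
#'
#' @param schedule a [cost_schedule()].
#' @param multiplier scale factor, >= 0.
#' @return A new `cost_schedule`.
#' @export
scale_schedule <- function(schedule, multiplier) {
  stopifnot(inherits(schedule, "cost_schedule"), multiplier > 0)
  cost_schedule(marginal = schedule$marginal * multiplier)
}

#' Total overage cost across resources
#'
#' @param shows per-set show-up counts.
#' @param config a [center_config()].
#' @param schedule a [cost_schedule()] shared by all resources, or a list of
#'   one schedule per resource.
#' @return Total cost in currency units.
#' @export
#' @examples
#' cs <- default_case_study_config()
#' total_overage_cost(c(0, 29, 0, 0), cs$config, cs$schedule)
total_overage_cost <- function(shows, config, schedule) {
  if (length(shows) != n_sets(config))
    stop("`shows` must have length ", n_sets(config))
  load <- as.vector(config$V %*% shows)
  z <- load - config$resources$ideal_level
  if (inherits(schedule, "cost_schedule")) {
    sum(overage_cost(z, schedule))
  } else {
    stopifnot(length(schedule) == n_resources(config))
    sum(vapply(seq_along(z),
               function(i) overage_cost(z[i], schedule[[i]]), numeric(1)))
  }
}
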