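#' Exact show-up distribution (Poisson-binomial)
#'
#' The number of bookings that are not late-cancelled, out of N accepted
#' bookings with heterogeneous late-cancellation probabilities r_1..r_N, is
#' a sum of independent Bernoulli(1 - r_k) variables: a Poisson-binomial
#' variable. The pmf is computed by the standard dynamic-programming
#' recurrence over bookings, which is mathematically identical to complete
#' enumeration of all `choose(N, x)` show-up subsets but costs O(N^2)
#' instead of O(2^N).
#'
#' @param late_cancel_probs vector of per-booking late-cancellation
#'   probabilities, each in \[0, 1\]. An empty vector yields a point mass at
#'   zero show-ups.
#' @return Object of class `showup_pmf`: a list with `probabilities`
#'   (length N + 1, over counts `0..N`), `n_slots`, and `method`.
#' @export
#' @examples
#' exact_showup_pmf(c(0.9, 0.5))$probabilities  # 0.45, 0.50, 0.05
exact_showup_pmf <- function(late_cancel_probs) {
  r <- as.numeric(late_cancel_probs)
  if (length(r) && (any(r < 0) || any(r > 1) || anyNA(r)))
    stop("late-cancellation probabilities must lie in [0, 1]")
  p <- 1 - r  # show-up probabilities
  pmf <- 1
  for (pk in p) {
    pmf <- c(pmf * (1 - pk), 0) + c(0, pmf * pk)
  }
  new_showup_pmf(pmf, method = "exact")
}

new_showup_pmf <- function(probabilities, method, iterations = NULL) {
  n <- length(probabilities) - 1L
  structure(
    list(probabilities = stats::setNames(probabilities, 0:n),
         n_slots = n, method = method, iterations = iterations),
    class = "showup_pmf"
  )
}

#' @export
print.showup_pmf <- function(x, ...) {
  cat("<showup_pmf> (", x$method, ") over 0..", x$n_slots,
      " show-ups; mean ", format(pmf_mean(x)), "\n", sep = "")
  if (!is.null(x$iterations))
    cat("Monte Carlo iterations used:", x$iterations, "\n")
  print(round(x$probabilities, 6))
  invisible(x)
}

#' Mean of a show-up pmf
#' @param pmf a `showup_pmf`.
#' @return Expected number of show-ups.
#' @export
pmf_mean <- function(pmf) {
  stopifnot(inherits(pmf, "showup_pmf"))
  sum(seq(0, pmf$n_slots) * pmf$probabilities)
}

#' Monte Carlo estimate of the show-up distribution
#'
#' Simulates the show-up count directly: in each iteration every booking k
#' draws a uniform R and shows up iff `R >= r_k`; the pmf is the relative
#' frequency of each count. Iterations accumulate in batches and stop when
#' the largest absolute change of any pmf entry between successive
#' cumulative estimates drops below `tolerance`, or when `max_iterations`
#' is reached. One uniform is consumed per booking per iteration in fixed
#' booking order, so results are reproducible given the seed.
#'
#' @inheritParams exact_showup_pmf
#' @param batch_size iterations per convergence check.
#' @param max_iterations cap on total iterations.
#' @param tolerance convergence threshold on the max absolute pmf change.
#' @param seed integer RNG seed (applied via `set.seed`).
#' @return A `showup_pmf` whose `iterations` element records the total T
#'   used.
#' @seealso [exact_showup_pmf()], the exact reference it converges to.
#' @export
monte_carlo_showup_pmf <- function(late_cancel_probs, batch_size = 1000L,
                                   max_iterations = 100000L,
                                   tolerance = 1e-4, seed = NULL) {
  r <- as.numeric(late_cancel_probs)
  if (length(r) && (any(r < 0) || any(r > 1) || anyNA(r)))
    stop("late-cancellation probabilities must lie in [0, 1]")
  stopifnot(batch_size >= 1, batch_size <= max_iterations, tolerance > 0)
  if (!is.null(seed)) set.seed(seed)
  N <- length(r)
  if (N == 0) return(new_showup_pmf(1, method = "monte-carlo", iterations = 0L))
  counts <- integer(N + 1)
  total <- 0L
  prev <- rep(NA_real_, N + 1)
  while (total < max_iterations) {
    nb <- min(batch_size, max_iterations - total)
    u <- matrix(stats::runif(nb * N), nrow = N)  # column = iteration
    shows <- colSums(u >= r)
    counts <- counts + tabulate(shows + 1L, nbins = N + 1L)
    total <- total + nb
    est <- counts / total
    if (!anyNA(prev) && max(abs(est - prev)) < tolerance) break
    prev <- est
  }
  new_showup_pmf(counts / total, method = "monte-carlo", iterations = total)
}
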