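#' Booking policy specification
#'
#' Three policies are supported: `NO` (no overbooking, uniform rate,
#' `U_i = 0`), `OU` (overbooking, one uniform late-cancellation rate for
#' every slot) and `OC` (overbooking, cluster-specific rates; because
#' cluster mixes differ by season, OC optimizations are run per season).
#'
#' @param kind `"NO"`, `"OU"` or `"OC"`.
#' @param uniform_rate late-cancellation probability shared by all slots
#'   (NO/OU), or a [uniform_rate()] object.
#' @param cluster_model a [cluster_model()] (OC only).
#' @param season season label for OC (`"winter"`, `"summer"`,
#'   `"off_peak"`).
#' @return Object of class `policy_spec`.
#' @export
policy_spec <- function(kind = c("NO", "OU", "OC"), uniform_rate = NULL,
                        cluster_model = NULL, season = NULL) {
  kind <- match.arg(kind)
  if (inherits(uniform_rate, "uniform_rate")) uniform_rate <- uniform_rate$rate
  if (kind %in% c("NO", "OU")) {
    if (is.null(uniform_rate) || uniform_rate < 0 || uniform_rate > 1)
      stop(kind, " policy needs a uniform late-cancellation rate in [0, 1]")
  } else {
    if (!inherits(cluster_model, "cluster_model"))
      stop("OC policy needs a cluster_model")
    if (is.null(season)) stop("OC policy needs a season")
  }
  structure(list(kind = kind, uniform_rate = uniform_rate,
                 cluster_model = cluster_model, season = season),
            class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  cat("<policy_spec> ", x$kind,
      if (x$kind == "OC") paste0(" (season: ", x$season, ")")
      else sprintf(" (uniform rate %.4f)", x$uniform_rate), "\n", sep = "")
  invisible(x)
}

# Largest-remainder apportionment of n slots to shares; ties broken by
# index order. Returns integer counts summing to n.
largest_remainder <- function(shares, n) {
  stopifnot(all(shares >= 0), sum(shares) > 0)
  q <- n * shares / sum(shares)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Season-specific cluster shares and rates from a cluster model.
season_cluster_mix <- function(model, season) {
  cl <- model$clusters
  if (is.null(cl)) stop("degenerate cluster model has no season mix")
  if (!"season" %in% model$factors)
    stop("cluster model has no season factor")
  sub <- cl[as.character(cl$season) == season & cl$bookings > 0, ,
            drop = FALSE]
  if (nrow(sub) == 0) stop("no bookings for season ", season)
  list(shares = sub$bookings / sum(sub$bookings), rates = sub$rate)
}

#' Per-slot late-cancellation probabilities for hypothetical bookings
#'
#' Bridges probability estimation and the optimizer: for a candidate
#' booking-limit combination, assigns a late-cancellation probability to
#' every slot of every set. NO/OU assign the uniform rate everywhere; OC
#' assigns cluster rates in proportion to the season's within-cluster
#' booking shares using largest-remainder rounding (slots listed in cluster
#' order), so the slot mix is deterministic.
#'
#' @param N integer vector of per-set booking limits.
#' @param policy a [policy_spec()].
#' @return List of numeric vectors, one per set, each of length `N[j]`.
#' @export
slot_probabilities <- function(N, policy) {
  stopifnot(inherits(policy, "policy_spec"), all(N >= 0))
  if (policy$kind %in% c("NO", "OU")) {
    return(lapply(N, function(n) rep(policy$uniform_rate, n)))
  }
  mix <- season_cluster_mix(policy$cluster_model, policy$season)
  lapply(N, function(n) {
    if (n == 0) return(numeric(0))
    counts <- largest_remainder(mix$shares, n)
    rep(mix$rates, counts)
  })
}

#' Realized net reward of a show-up vector
#'
#' Revenue (show-ups times set prices) minus the total overage cost across
#' resources.
#'
#' @inheritParams total_overage_cost
#' @return Net reward in currency units.
#' @export
net_reward <- function(shows, config, schedule) {
  if (length(shows) != n_sets(config))
    stop("`shows` must have length ", n_sets(config))
  sum(shows * config$sets$price) - total_overage_cost(shows, config, schedule)
}

# exact pmfs for each set under a policy, for limits N
set_pmfs <- function(N, policy) {
  lapply(slot_probabilities(N, policy), exact_showup_pmf)
}

# expected total overage cost given per-set pmfs (list of numeric vectors
# over 0..N_j), via per-resource load convolution
expected_cost_from_pmfs <- function(pmf_list, config, schedule) {
  per_res_sched <- inherits(schedule, "cost_schedule")
  total <- 0
  for (i in seq_len(n_resources(config))) {
    uses <- which(config$V[i, ] == 1L)
    load <- 1
    for (j in uses) load <- conv_pmf(load, pmf_list[[j]])
    z <- seq_along(load) - 1 - config$resources$ideal_level[i]
    sched_i <- if (per_res_sched) schedule else schedule[[i]]
    total <- total + sum(load * overage_cost(z, sched_i))
  }
  total
}

conv_pmf <- function(a, b) {
  if (length(a) == 1) return(a * b)
  if (length(b) == 1) return(a * b)
  out <- numeric(length(a) + length(b) - 1)
  for (k in seq_along(b)) {
    idx <- k:(k + length(a) - 1)
    out[idx] <- out[idx] + a * b[k]
  }
  out
}

#' Expected net reward of a booking-limit combination
#'
#' The objective of the stochastic program: the expectation of the net
#' reward over the joint distribution of per-set show-up counts, each set's
#' count following the exact (Poisson-binomial) show-up distribution of its
#' slots under the policy.
#'
#' Two equivalent evaluation methods are available. `"convolution"`
#' (default) uses the decomposition E\[reward\] = sum_j P_j E\[X_j\] -
#' sum_i E\[f_i(load_i - K_i)\], where each resource load pmf is the
#' convolution of the pmfs of the sets using it; it is exact and fast.
#' `"joint"` literally sums the net reward over the joint support
#' `prod(N + 1)` weighted by the product of per-set probabilities; it is
#' the textbook definition and serves as a cross-check, guarded by
#' `joint_cap`.
#'
#' @param N integer vector of per-set booking limits.
#' @param policy a [policy_spec()].
#' @param config a [center_config()].
#' @param schedule a [cost_schedule()] (or per-resource list).
#' @param method `"convolution"` or `"joint"`.
#' @param joint_cap maximum joint-support size for `method = "joint"`.
#' @return Expected net reward in currency units.
#' @export
#' @examples
#' toy <- center_config(
#'   sets = data.frame(name = "s", price = 10, original_limit = 2),
#'   resources = data.frame(name = "r", ideal_level = 1, max_overage = 1),
#'   requirements = list(s = "r"))
#' sched <- cost_schedule(marginal = c(3, 3))
#' pol <- policy_spec("OU", uniform_rate = 0.5)
#' expected_net_reward(c(2), pol, toy, sched)  # 9.25
expected_net_reward <- function(N, policy, config, schedule,
                                method = c("convolution", "joint"),
                                joint_cap = 1e7) {
  method <- match.arg(method)
  if (length(N) != n_sets(config))
    stop("`N` must have length ", n_sets(config))
  pmfs <- set_pmfs(N, policy)
  probs <- lapply(pmfs, `[[`, "probabilities")
  if (method == "convolution") {
    revenue <- sum(config$sets$price * vapply(pmfs, pmf_mean, numeric(1)))
    return(revenue - expected_cost_from_pmfs(probs, config, schedule))
  }
  if (prod(N + 1) > joint_cap)
    stop("joint support size ", prod(N + 1), " exceeds joint_cap; use ",
         "method = \"convolution\" or Monte Carlo evaluation")
  grid <- expand.grid(lapply(N, function(n) 0:n), KEEP.OUT.ATTRS = FALSE)
  total <- 0
  for (row in seq_len(nrow(grid))) {
    x <- as.integer(grid[row, ])
    w <- prod(vapply(seq_along(x),
                     function(j) probs[[j]][x[j] + 1], numeric(1)))
    total <- total + w * net_reward(x, config, schedule)
  }
  total
}

# Precompute per-set pmfs and their means for every N_j = 0..cap_j under a
# policy, so searches do not recompute Poisson-binomial DPs per combination.
pmf_tables <- function(caps, policy) {
  lapply(seq_along(caps), function(j) {
    lapply(0:caps[j], function(n) {
      pm <- slot_probabilities(replace(integer(length(caps)), j, n),
                               policy)[[j]]
      p <- exact_showup_pmf(pm)$probabilities
      list(p = p, mean = sum(seq(0, n) * p))
    })
  })
}

evaluate_combination <- function(N, tables, config, schedule) {
  probs <- lapply(seq_along(N), function(j) tables[[j]][[N[j] + 1]]$p)
  means <- vapply(seq_along(N), function(j) tables[[j]][[N[j] + 1]]$mean,
                  numeric(1))
  revenue <- sum(config$sets$price * means)
  cost <- expected_cost_from_pmfs(probs, config, schedule)
  served <- sum(means)
  exp_ovg <- expected_total_overage(probs, config)
  c(reward = revenue - cost, expected_cost = cost, served = served,
    overage = exp_ovg,
    overage_pct = if (served > 0) exp_ovg / served else 0)
}

# expected total overage level across resources
expected_total_overage <- function(pmf_list, config) {
  total <- 0
  for (i in seq_len(n_resources(config))) {
    uses <- which(config$V[i, ] == 1L)
    load <- 1
    for (j in uses) load <- conv_pmf(load, pmf_list[[j]])
    z <- seq_along(load) - 1 - config$resources$ideal_level[i]
    total <- total + sum(load * pmax(z, 0))
  }
  total
}

#' Complete search for optimal booking limits
#'
#' Evaluates the expected net reward of every feasible booking-limit
#' combination in the search space and returns the maximizer
#' (lexicographically smallest combination on ties) together with the full
#' evaluation list, which downstream Pareto analysis reuses.
#'
#' @param space a [search_space()].
#' @param policy a [policy_spec()].
#' @param config a [center_config()].
#' @param schedule a [cost_schedule()].
#' @return Object of class `optimization_result`: `optimal_limits`,
#'   `expected_net_reward`, `evaluations` (data frame with the limit
#'   columns plus `reward`, `expected_cost`, `served`, `overage`,
#'   `overage_pct`), `algorithm`.
#' @export
complete_search <- function(space, policy, config, schedule) {
  combos <- enumerate_search_space(space)
  caps <- apply(space$V, 2, function(col) min(space$rhs[col == 1L]))
  tables <- pmf_tables(caps, policy)
  ev <- t(apply(combos, 1, evaluate_combination, tables = tables,
                config = config, schedule = schedule))
  best <- which.max(ev[, "reward"])  # which.max: first (lex smallest) tie
  evaluations <- data.frame(combos, ev, check.names = FALSE)
  structure(
    list(optimal_limits = stats::setNames(combos[best, ], colnames(combos)),
         expected_net_reward = unname(ev[best, "reward"]),
         evaluations = evaluations, algorithm = "complete",
         policy = policy$kind, season = policy$season),
    class = "optimization_result"
  )
}

#' Greedy search for booking limits
#'
#' Starts from a feasible combination (all zeros by default, optionally the
#' center's original limits) and repeatedly increments the booking limit of
#' the set whose unit increment yields the highest expected net reward,
#' stopping when no feasible increment improves the objective. Ties on
#' potential are broken by set index. Greedy may miss the true optimum; if
#' a complete-search result is supplied, the optimality gap is reported.
#'
#' @inheritParams complete_search
#' @param start integer vector of starting limits (default all zeros).
#' @param complete optional `optimization_result` from [complete_search()]
#'   to compute `gap_to_complete`.
#' @return An `optimization_result` (with `gap_to_complete` when available;
#'   `evaluations` holds the greedy trajectory).
#' @export
greedy_search <- function(space, policy, config, schedule,
                          start = NULL, complete = NULL) {
  m <- ncol(space$V)
  N <- if (is.null(start)) integer(m) else as.integer(start)
  if (!is_feasible(N, space)) stop("starting combination is infeasible")
  caps <- apply(space$V, 2, function(col) min(space$rhs[col == 1L]))
  tables <- pmf_tables(caps, policy)
  cur <- evaluate_combination(N, tables, config, schedule)
  path <- list(c(N, cur))
  repeat {
    best_j <- 0L
    best_val <- cur["reward"]
    best_ev <- NULL
    for (j in seq_len(m)) {
      cand <- N
      cand[j] <- cand[j] + 1L
      if (!is_feasible(cand, space)) next
      evj <- evaluate_combination(cand, tables, config, schedule)
      if (evj["reward"] > best_val) {  # strict: ties keep lower set index
        best_val <- evj["reward"]
        best_j <- j
        best_ev <- evj
      }
    }
    if (best_j == 0L) break
    N[best_j] <- N[best_j] + 1L
    cur <- best_ev
    path[[length(path) + 1L]] <- c(N, cur)
  }
  evaluations <- as.data.frame(do.call(rbind, path))
  names(evaluations)[seq_len(m)] <- colnames(space$V)
  res <- structure(
    list(optimal_limits = stats::setNames(N, colnames(space$V)),
         expected_net_reward = unname(cur["reward"]),
         evaluations = evaluations, algorithm = "greedy",
         policy = policy$kind, season = policy$season),
    class = "optimization_result"
  )
  if (!is.null(complete))
    res$gap_to_complete <-
      complete$expected_net_reward - res$expected_net_reward
  res
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result> ", x$algorithm, " search",
      if (!is.null(x$policy)) paste0(", policy ", x$policy), "\n", sep = "")
  cat("optimal limits:\n")
  print(x$optimal_limits)
  cat(sprintf("expected net reward: %.2f\n", x$expected_net_reward))
  if (!is.null(x$gap_to_complete))
    cat(sprintf("gap to complete search: %.2f\n", x$gap_to_complete))
  invisible(x)
}
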