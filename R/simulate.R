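#' Simulation design for policy evaluation
#'
#' @param weeks number of simulated weeks (50 by default).
#' @param days_per_week operating days per week; the center's calendar is
#'   not standardized, so this is prominently configurable (default 5).
#' @param seed integer RNG seed.
#' @param season season whose booking mix and rates drive the simulation.
#' @param demand `"saturated"` (every slot is booked, the observed regime
#'   for the motivating center) or `"stochastic"` (Poisson demand per set,
#'   truncated at the limits, for robustness studies).
#' @param arrival_rates per-set mean daily booking requests
#'   (`demand = "stochastic"` only).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(weeks = 50, days_per_week = 5, seed = 1,
                       season = "winter",
                       demand = c("saturated", "stochastic"),
                       arrival_rates = NULL) {
  demand <- match.arg(demand)
  stopifnot(weeks >= 1, days_per_week >= 1)
  if (demand == "stochastic" && is.null(arrival_rates))
    stop("stochastic demand needs per-set arrival rates")
  structure(list(weeks = as.integer(weeks),
                 days_per_week = as.integer(days_per_week),
                 seed = as.integer(seed), season = season, demand = demand,
                 arrival_rates = arrival_rates),
            class = "sim_config")
}

#' Discrete-event simulation of a booking policy
#'
#' Simulates realized weekly performance of a fixed booking-limit
#' combination. Each day, accepted bookings fill the limits (saturated
#' mode); every accepted booking is assigned to a cluster by sampling the
#' season's cluster mix and cancels late with its cluster's rate (or with
#' the single rate of a uniform probability model). Daily revenue,
#' per-resource overage and overage cost are computed from the realized
#' show-ups and aggregated into weeks. The evaluation probabilities should
#' be the best available ("true") ones — in a policy comparison the
#' cluster rates — regardless of which policy chose the limits.
#'
#' @param limits integer per-set booking limits (must be feasible for the
#'   space implied by `config` with its configured overages).
#' @param prob_model either a [cluster_model()] (cluster rates, using
#'   `sim$season`'s mix) or a single numeric uniform late-cancellation
#'   rate / [uniform_rate()] object.
#' @param sim a [sim_config()].
#' @param config a [center_config()].
#' @param schedule a [cost_schedule()].
#' @return Object of class `policy_evaluation`: weekly vectors
#'   `net_reward`, `consumers_served`, `overage` (total), per-resource
#'   matrix `overage_by_resource`, `overage_pct`, plus the daily show-up
#'   array and labels.
#' @export
simulate_weeks <- function(limits, prob_model, sim, config, schedule) {
  stopifnot(inherits(sim, "sim_config"))
  m <- n_sets(config)
  if (length(limits) != m) stop("`limits` must have length ", m)
  sp <- search_space(config, overbooking = TRUE)
  if (!is_feasible(limits, sp))
    stop("infeasible booking limits for this center configuration")
  if (inherits(prob_model, "cluster_model")) {
    mix <- season_cluster_mix(prob_model, sim$season)
  } else {
    r <- if (inherits(prob_model, "uniform_rate")) prob_model$rate
         else as.numeric(prob_model)
    stopifnot(r >= 0, r <= 1)
    mix <- list(shares = 1, rates = r)
  }
  set.seed(sim$seed)
  K <- config$resources$ideal_level
  prices <- config$sets$price
  n_days <- sim$weeks * sim$days_per_week
  shows_daily <- matrix(0L, n_days, m,
                        dimnames = list(NULL, config$sets$name))
  ovg_daily <- matrix(0, n_days, n_resources(config),
                      dimnames = list(NULL, config$resources$name))
  cost_daily <- numeric(n_days)
  for (d in seq_len(n_days)) {
    booked <- limits
    if (sim$demand == "stochastic")
      booked <- pmin(limits, stats::rpois(m, sim$arrival_rates))
    shows <- integer(m)
    for (j in seq_len(m)) {
      if (booked[j] == 0) next
      cl <- sample.int(length(mix$shares), booked[j], replace = TRUE,
                       prob = mix$shares)
      shows[j] <- sum(stats::runif(booked[j]) >= mix$rates[cl])
    }
    shows_daily[d, ] <- shows
    z <- pmax(as.vector(config$V %*% shows) - K, 0)
    ovg_daily[d, ] <- z
    cost_daily[d] <- sum(overage_cost(z, schedule))
  }
  wk <- rep(seq_len(sim$weeks), each = sim$days_per_week)
  revenue_daily <- as.vector(shows_daily %*% prices)
  weekly <- function(x) as.vector(tapply(x, wk, sum))
  served <- weekly(rowSums(shows_daily))
  ovg_total <- weekly(rowSums(ovg_daily))
  structure(
    list(net_reward = weekly(revenue_daily - cost_daily),
         consumers_served = served,
         overage = ovg_total,
         overage_by_resource = apply(ovg_daily, 2, weekly),
         overage_cost = weekly(cost_daily),
         revenue = weekly(revenue_daily),
         shows_daily = shows_daily,
         limits = limits, season = sim$season,
         days_per_week = sim$days_per_week, seed = sim$seed),
    class = "policy_evaluation"
  )
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat("<policy_evaluation> ", length(x$net_reward), " weeks, season ",
      x$season, "\n", sep = "")
  cat("limits:", paste(x$limits, collapse = ", "), "\n")
  cat(sprintf("mean weekly net reward: %.0f\n", mean(x$net_reward)))
  cat(sprintf("mean weekly consumers served: %.1f\n",
              mean(x$consumers_served)))
  cat(sprintf("mean weekly overage percentage: %.2f%%\n",
              100 * mean(overage_percentage(x))))
  invisible(x)
}

#' Weekly overage percentages of a simulated evaluation
#'
#' The headline ratio aggregates resources: total weekly overage divided by
#' weekly consumers served. Weeks with zero consumers served report 0 with
#' a warning. Per-resource ratios are available via
#' `attr(, "by_resource")`.
#'
#' @param evaluation a `policy_evaluation` from [simulate_weeks()].
#' @return Numeric vector of weekly ratios, with a `by_resource` attribute
#'   (matrix weeks x resources).
#' @export
overage_percentage <- function(evaluation) {
  stopifnot(inherits(evaluation, "policy_evaluation"))
  served <- evaluation$consumers_served
  ratio <- ifelse(served > 0, evaluation$overage / served, 0)
  if (any(served == 0))
    warning("week(s) with zero consumers served; overage percentage ",
            "reported as 0")
  br <- sweep(evaluation$overage_by_resource, 1,
              pmax(served, 1), "/")
  br[served == 0, ] <- 0
  attr(ratio, "by_resource") <- br
  ratio
}

#' Compare simulated policies with Tukey's HSD
#'
#' One-way analysis of the weekly net rewards across policies followed by
#' Tukey's honestly-significant-difference procedure for
#' multiplicity-adjusted pairwise p-values.
#'
#' @param evaluations named list (>= 2) of `policy_evaluation` objects with
#'   equal numbers of weeks.
#' @return Data frame with one row per pair: `pair`, `diff` (mean
#'   difference), `lwr`, `upr` (95% family-wise interval), `p_adj`.
#' @export
compare_policies <- function(evaluations) {
  if (length(evaluations) < 2) stop("need at least two policies to compare")
  if (is.null(names(evaluations)) || any(names(evaluations) == ""))
    stop("`evaluations` must be a named list")
  wk <- vapply(evaluations, function(e) length(e$net_reward), integer(1))
  if (length(unique(wk)) != 1)
    stop("all policies must be simulated for the same number of weeks")
  dat <- data.frame(
    reward = unlist(lapply(evaluations, `[[`, "net_reward")),
    policy = factor(rep(names(evaluations), each = wk[1]))
  )
  hsd <- stats::TukeyHSD(stats::aov(reward ~ policy, data = dat))$policy
  data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
             lwr = hsd[, "lwr"], upr = hsd[, "upr"],
             p_adj = hsd[, "p adj"], row.names = NULL)
}

#' Sensitivity of policies to overage-cost scaling
#'
#' Two questions about cost misestimation: (`reoptimize`) how do the
#' optimal limits and achievable reward move when overage truly costs
#' `multiplier` times more and the center re-optimizes; (`underestimate`)
#' how much reward is lost when the center keeps the limits optimized
#' under the baseline costs while the true costs are `multiplier` times
#' higher. The NO policy never overbooks, so it is unaffected in
#' reoptimize mode.
#'
#' @param multipliers numeric vector of cost scale factors (>= 1).
#' @param policies named list of [policy_spec()]s.
#' @param config a [center_config()].
#' @param schedule the baseline [cost_schedule()].
#' @param mode `"reoptimize"` or `"underestimate"`.
#' @return Data frame with one row per (multiplier, policy): the limit
#'   columns, `expected_net_reward`, `multiplier`, `policy`.
#' @export
sensitivity_analysis <- function(multipliers, policies, config, schedule,
                                 mode = c("reoptimize", "underestimate")) {
  mode <- match.arg(mode)
  if (!length(multipliers)) stop("empty multiplier list")
  stopifnot(all(multipliers >= 1))
  base_opt <- lapply(names(policies), function(p) {
    sp <- search_space(config, overbooking = policies[[p]]$kind != "NO")
    complete_search(sp, policies[[p]], config, schedule)
  })
  names(base_opt) <- names(policies)
  rows <- list()
  for (mult in multipliers) {
    sched_m <- if (mult == 1) schedule else scale_schedule(schedule, mult)
    for (p in names(policies)) {
      if (mode == "reoptimize") {
        res <- if (mult == 1) base_opt[[p]] else {
          sp <- search_space(config, overbooking = policies[[p]]$kind != "NO")
          complete_search(sp, policies[[p]], config, sched_m)
        }
        lim <- res$optimal_limits
        rew <- res$expected_net_reward
      } else {
        lim <- base_opt[[p]]$optimal_limits
        rew <- expected_net_reward(lim, policies[[p]], config, sched_m)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        t(lim), expected_net_reward = rew, multiplier = mult, policy = p,
        check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pareto frontier of booking-limit combinations
#'
#' A combination is Pareto-efficient when no other combination has both a
#' higher expected net reward and a lower expected overage percentage
#' (weak domination: dominated means another point is at least as good on
#' both axes and strictly better on one). Optionally also reports the
#' reward-maximizing combination among those with expected overage
#' percentage at or below a bound.
#'
#' @param evaluations data frame with columns `reward` and `overage_pct`
#'   (e.g. the `evaluations` element of a [complete_search()] result);
#'   other columns (the limits) are carried along.
#' @param max_overage_pct optional upper bound on expected overage
#'   percentage.
#' @return List with `frontier` (data frame of non-dominated rows, sorted
#'   by overage percentage) and, when a bound is given, `constrained_best`
#'   (single row, or `NULL` when no point satisfies the bound).
#' @export
pareto_frontier <- function(evaluations, max_overage_pct = NULL) {
  stopifnot(is.data.frame(evaluations), nrow(evaluations) >= 1,
            all(c("reward", "overage_pct") %in% names(evaluations)))
  r <- evaluations$reward
  o <- evaluations$overage_pct
  ord <- order(o, -r)
  keep_idx <- logical(length(r))
  best_r <- -Inf
  best_o <- Inf
  for (i in ord) {
    # scanning by increasing overage: a point survives iff its reward beats
    # every point with smaller-or-equal overage, except exact duplicates of
    # the current frontier point, which are mutually non-dominating
    if (r[i] > best_r) {
      keep_idx[i] <- TRUE
      best_r <- r[i]
      best_o <- o[i]
    } else if (r[i] == best_r && o[i] == best_o) {
      keep_idx[i] <- TRUE  # exact duplicate of a frontier point
    }
  }
  frontier <- evaluations[keep_idx, , drop = FALSE]
  frontier <- frontier[order(frontier$overage_pct), , drop = FALSE]
  out <- list(frontier = frontier)
  if (!is.null(max_overage_pct)) {
    ok <- evaluations[o <= max_overage_pct, , drop = FALSE]
    out$constrained_best <- if (nrow(ok)) {
      ok[which.max(ok$reward), , drop = FALSE]
    } else NULL
  }
  out
}
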