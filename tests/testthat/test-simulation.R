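cs <- default_case_study_config()

test_that("deterministic limits: no cancellations and free overage", {
  free <- cost_schedule(marginal = c(1e-12, 1e-12))
  sc <- sim_config(weeks = 4, days_per_week = 5, seed = 1,
                   season = "winter")
  limits <- c(1, 23, 2, 2)
  ev <- simulate_weeks(limits, 0, sc, cs$config, free)
  expect_equal(ev$net_reward,
               rep(5 * sum(limits * cs$config$sets$price), 4),
               tolerance = 1e-6)
  expect_equal(ev$consumers_served, rep(5 * sum(limits), 4))

  # certain cancellation: nothing happens
  ev1 <- simulate_weeks(limits, 1, sc, cs$config, cs$schedule)
  expect_equal(ev1$net_reward, rep(0, 4))
  expect_equal(ev1$consumers_served, rep(0, 4))
})

test_that("simulation is seed-reproducible and self-consistent", {
  sc <- sim_config(weeks = 6, days_per_week = 5, seed = 99,
                   season = "winter")
  lim <- c(1, 35, 3, 3)
  e1 <- simulate_weeks(lim, cs$cluster_model, sc, cs$config, cs$schedule)
  e2 <- simulate_weeks(lim, cs$cluster_model, sc, cs$config, cs$schedule)
  expect_identical(e1$net_reward, e2$net_reward)
  expect_identical(e1$shows_daily, e2$shows_daily)

  # weekly net reward re-derivable from the daily show-up log
  wk <- rep(seq_len(sc$weeks), each = sc$days_per_week)
  recomputed <- sapply(seq_len(sc$weeks), function(w) {
    days <- which(wk == w)
    sum(sapply(days, function(d)
      net_reward(e1$shows_daily[d, ], cs$config, cs$schedule)))
  })
  expect_equal(e1$net_reward, recomputed)
  # served never exceeds the booked capacity
  expect_true(all(e1$consumers_served <= sc$days_per_week * sum(lim)))
})

test_that("simulated mean shows match the exact show-up distribution", {
  sc <- sim_config(weeks = 50, days_per_week = 5, seed = 7,
                   season = "winter")
  lim <- c(1, 35, 3, 3)
  ev <- simulate_weeks(lim, cs$cluster_model, sc, cs$config, cs$schedule)
  # under cluster sampling, each booking's marginal cancellation rate is
  # the share-weighted mean of the winter cluster rates
  mix <- overbookr:::season_cluster_mix(cs$cluster_model, "winter")
  rbar <- sum(mix$shares * mix$rates)
  n_days <- sc$weeks * sc$days_per_week
  for (j in which(lim > 0)) {
    mu <- lim[j] * (1 - rbar)
    sd_day <- sqrt(lim[j] * rbar * (1 - rbar))
    mc_se <- sd_day / sqrt(n_days)
    expect_lt(abs(mean(ev$shows_daily[, j]) - mu), 3 * mc_se + 1e-9)
  }
})

test_that("overage percentage aggregates overage over consumers served", {
  ev <- list(consumers_served = c(30, 0), overage = c(3, 0),
             overage_by_resource = matrix(c(3, 0, 0, 0), 2, 2))
  class(ev) <- "policy_evaluation"
  expect_warning(op <- overage_percentage(ev), "zero consumers")
  expect_equal(as.vector(op), c(0.1, 0))

  ev2 <- list(consumers_served = c(10, 20), overage = c(0, 0),
              overage_by_resource = matrix(0, 2, 2))
  class(ev2) <- "policy_evaluation"
  expect_equal(as.vector(overage_percentage(ev2)), c(0, 0))
})

test_that("Tukey HSD comparison flags separated groups and not clones", {
  mk <- function(x) structure(list(net_reward = x),
                              class = "policy_evaluation")
  same <- rnorm(20, 100, 5)
  out <- compare_policies(list(a = mk(same), b = mk(same)))
  expect_equal(out$p_adj, 1, tolerance = 1e-6)
  expect_equal(out$diff, 0)

  far <- compare_policies(list(lo = mk(rnorm(20, 0, 1)),
                               hi = mk(rnorm(20, 1000, 1))))
  expect_lt(far$p_adj, 0.001)

  expect_error(compare_policies(list(a = mk(same))), "two")
  expect_error(compare_policies(list(a = mk(same), b = mk(same[1:10]))),
               "same number")
})

test_that("Tukey adjusted p-values match a hand computation", {
  # three equal-size groups; studentized-range computation from first
  # principles: q = |diff| / sqrt(MSE / n), p = P(Q_{k, df} > q)
  g <- list(a = c(10, 12, 11, 13), b = c(14, 15, 13, 16),
            c = c(20, 22, 21, 19))
  mk <- function(x) structure(list(net_reward = x),
                              class = "policy_evaluation")
  out <- compare_policies(lapply(g, mk))
  n <- 4
  k <- 3
  df <- 9
  mse <- sum(sapply(g, function(x) sum((x - mean(x))^2))) / df
  for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
    q <- abs(mean(g[[pair[1]]]) - mean(g[[pair[2]]])) / sqrt(mse / n)
    p_hand <- 1 - ptukey(q, nmeans = k, df = df)
    row <- out[out$pair == paste(pair, collapse = "-"), ]
    expect_equal(row$p_adj, p_hand, tolerance = 1e-8)
  }
})

test_that("pareto frontier keeps exactly the non-dominated points", {
  ev <- data.frame(reward = c(10, 8), overage_pct = c(0.05, 0.06))
  pf <- pareto_frontier(ev)
  expect_equal(nrow(pf$frontier), 1)
  expect_equal(pf$frontier$reward, 10)

  ev3 <- data.frame(reward = c(10, 12, 14), overage_pct = c(0.02, 0.05, 0.09))
  expect_equal(nrow(pareto_frontier(ev3)$frontier), 3)

  set.seed(41)
  cloud <- data.frame(reward = round(runif(120, 0, 50)),
                      overage_pct = round(runif(120, 0, 0.2), 2))
  pf <- pareto_frontier(cloud)
  # O(n^2) pairwise-domination oracle
  dominated <- sapply(seq_len(nrow(cloud)), function(i) {
    any(cloud$reward >= cloud$reward[i] &
          cloud$overage_pct <= cloud$overage_pct[i] &
          (cloud$reward > cloud$reward[i] |
             cloud$overage_pct < cloud$overage_pct[i]))
  })
  expect_equal(nrow(pf$frontier), sum(!dominated))
  expect_setequal(
    paste(pf$frontier$reward, pf$frontier$overage_pct),
    paste(cloud$reward[!dominated], cloud$overage_pct[!dominated]))

  # constrained best under a maximum allowable overage percentage
  pf7 <- pareto_frontier(cloud, max_overage_pct = 0.07)
  ok <- cloud[cloud$overage_pct <= 0.07, ]
  expect_equal(pf7$constrained_best$reward, max(ok$reward))
  # the reward maximizer is always on the frontier
  expect_true(max(cloud$reward) %in% pf$frontier$reward)
})

test_that("cost sensitivity: NO is immune, overbooking shrinks", {
  pol <- list(NO = policy_spec("NO", uniform_rate = cs$uniform_rate$rate),
              OU = policy_spec("OU", uniform_rate = cs$uniform_rate$rate))
  out <- sensitivity_analysis(c(1, 3), pol, cs$config, cs$schedule,
                              mode = "reoptimize")
  no <- out[out$policy == "NO", ]
  expect_equal(no$expected_net_reward[1], no$expected_net_reward[2])
  expect_equal(unlist(no[1, 1:4]), unlist(no[2, 1:4]))
  ou <- out[out$policy == "OU", ]
  expect_lte(ou$expected_net_reward[2], ou$expected_net_reward[1])

  # underestimate mode keeps the baseline limits but pays the true costs
  under <- sensitivity_analysis(c(1, 3), pol, cs$config, cs$schedule,
                                mode = "underestimate")
  ou_u <- under[under$policy == "OU", ]
  expect_equal(unlist(ou_u[1, 1:4]), unlist(ou_u[2, 1:4]))
  expect_lte(ou_u$expected_net_reward[2], ou_u$expected_net_reward[1])
  # at multiplier 1 both modes coincide with the baseline optimization
  expect_equal(ou$expected_net_reward[1], ou_u$expected_net_reward[1])

  expect_error(sensitivity_analysis(numeric(0), pol, cs$config,
                                    cs$schedule), "empty")
})
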