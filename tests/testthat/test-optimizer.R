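test_that("net reward combines revenue with the printed overage cost", {
  cs <- default_case_study_config()
  expect_equal(net_reward(c(0, 0, 0, 0), cs$config, cs$schedule), 0)
  p2 <- cs$config$sets$price[2]
  expect_equal(net_reward(c(0, 24, 0, 0), cs$config, cs$schedule), 24 * p2)
  expect_equal(net_reward(c(0, 29, 0, 0), cs$config, cs$schedule),
               29 * p2 - 17500)
})

test_that("slot probabilities follow the policy", {
  pol <- policy_spec("OU", uniform_rate = 0.0334)
  sl <- slot_probabilities(c(13, 2), pol)
  expect_equal(sl[[1]], rep(0.0334, 13))
  expect_equal(sl[[2]], rep(0.0334, 2))

  cm <- default_case_study_config()$cluster_model
  oc <- policy_spec("OC", cluster_model = cm, season = "winter")
  sl4 <- slot_probabilities(c(4), oc)[[1]]
  # independent largest-remainder apportionment of 4 slots to the winter
  # cluster shares (583, 247, 842, 433)/2105
  shares <- c(583, 247, 842, 433) / 2105
  q <- 4 * shares
  counts <- floor(q)
  rem <- order(-(q - counts))[seq_len(4 - sum(counts))]
  counts[rem] <- counts[rem] + 1
  rates <- c(20/583, 15/247, 31/842, 22/433)
  expect_equal(sl4, rep(rates, counts))

  # single nonempty cluster: every slot gets its rate
  fb <- structure(list(q1 = 1, q2 = 10, rate = 0.1),
                  class = "uniform_rate")
  cm1 <- cluster_model(
    data.frame(season = "winter", bookings = 10, late_cancellations = 1),
    fb)
  oc1 <- policy_spec("OC", cluster_model = cm1, season = "winter")
  expect_equal(slot_probabilities(c(5), oc1)[[1]], rep(0.1, 5))

  expect_error(policy_spec("OC", season = "winter"), "cluster_model")
})

test_that("largest-remainder counts sum to n and respect quotas", {
  set.seed(31)
  cm <- default_case_study_config()$cluster_model
  for (season in c("winter", "summer", "off_peak")) {
    oc <- policy_spec("OC", cluster_model = cm, season = season)
    for (n in c(1, 4, 13, 36)) {
      sl <- slot_probabilities(c(n), oc)[[1]]
      expect_length(sl, n)
      # every assigned rate is one of the season's cluster rates
      mix <- overbookr:::season_cluster_mix(cm, season)
      expect_true(all(sl %in% mix$rates))
      # counts differ from exact quotas by less than 1 (quota property)
      cnt <- as.vector(table(factor(sl, levels = mix$rates)))
      expect_true(all(abs(cnt - n * mix$shares) < 1))
    }
  }
})

test_that("expected net reward matches the hand-enumerated toy instance", {
  toy <- one_set_config(price = 10, K = 1, U = 1)
  sched <- cost_schedule(marginal = c(3, 3))
  pol <- policy_spec("OU", uniform_rate = 0.5)
  expect_equal(expected_net_reward(2, pol, toy, sched), 9.25)
  expect_equal(expected_net_reward(0, pol, toy, sched), 0)
})

test_that("convolution and joint evaluation agree on random instances", {
  set.seed(32)
  for (i in 1:10) {
    inst <- random_instance(n_sets = 2, n_res = 2, max_cap = 4)
    pol <- policy_spec("OU", uniform_rate = runif(1, 0.02, 0.4))
    N <- sapply(seq_len(2), function(j) sample(0:4, 1))
    expect_equal(
      expected_net_reward(N, pol, inst$config, inst$schedule),
      expected_net_reward(N, pol, inst$config, inst$schedule,
                          method = "joint"),
      tolerance = 1e-9)
  }
  expect_error(
    expected_net_reward(c(40, 40, 40, 40),
                        policy_spec("OU", uniform_rate = 0.1),
                        default_case_study_config()$config,
                        default_case_study_config()$schedule,
                        method = "joint", joint_cap = 100),
    "joint_cap")
})

test_that("with zero overage costs the objective is pure expected revenue", {
  cs <- default_case_study_config()
  free <- cost_schedule(marginal = c(1e-12, 1e-12))
  pol <- policy_spec("OU", uniform_rate = 0.0334)
  N <- c(3, 5, 2, 1)
  expect_equal(expected_net_reward(N, pol, cs$config, free),
               sum(cs$config$sets$price * N * (1 - 0.0334)),
               tolerance = 1e-6)
  # and it is nondecreasing in every component
  for (j in 1:4) {
    N2 <- N
    N2[j] <- N2[j] + 1
    expect_gte(expected_net_reward(N2, pol, cs$config, free),
               expected_net_reward(N, pol, cs$config, free))
  }
})

test_that("complete search under no overbooking saturates the constraints", {
  cs <- default_case_study_config()
  sp <- search_space(cs$config, overbooking = FALSE)
  pol <- policy_spec("NO", uniform_rate = 0.0334)
  res <- complete_search(sp, pol, cs$config, cs$schedule)
  expect_equal(sum(res$optimal_limits), 28)
  expect_true(is_feasible(res$optimal_limits, sp))
  # the maximizer is the max of its own evaluation list
  expect_equal(res$expected_net_reward, max(res$evaluations$reward))

  # single set, U = 0: revenue is monotone, so N* = K
  one <- one_set_config(price = 10, K = 3, U = 0)
  res1 <- complete_search(search_space(one, overbooking = FALSE),
                          policy_spec("NO", uniform_rate = 0.1),
                          one, cost_schedule(marginal = c(3, 3)))
  expect_equal(unname(res1$optimal_limits), 3)
})

test_that("complete search equals brute-force re-evaluation on small instances", {
  set.seed(33)
  for (i in 1:5) {
    inst <- random_instance(n_sets = 2, n_res = 2, max_cap = 4)
    pol <- policy_spec("OU", uniform_rate = runif(1, 0.05, 0.3))
    sp <- search_space(inst$config)
    res <- complete_search(sp, pol, inst$config, inst$schedule)
    combos <- enumerate_search_space(sp)
    rewards <- apply(combos, 1, function(N)
      expected_net_reward(N, pol, inst$config, inst$schedule,
                          method = "joint"))
    expect_equal(res$expected_net_reward, max(rewards), tolerance = 1e-9)
    expect_equal(unname(res$optimal_limits),
                 unname(combos[which.max(rewards), ]),
                 tolerance = 1e-9)
  }
})

test_that("greedy search ascends and reports a nonnegative optimality gap", {
  # concave single-set instance: greedy reaches the complete-search optimum
  one <- one_set_config(price = 10, K = 2, U = 3)
  sched <- cost_schedule(marginal = c(4, 8, 16))
  pol <- policy_spec("OU", uniform_rate = 0.3)
  sp <- search_space(one)
  comp <- complete_search(sp, pol, one, sched)
  gr <- greedy_search(sp, pol, one, sched, complete = comp)
  expect_equal(gr$optimal_limits, comp$optimal_limits)
  expect_equal(gr$gap_to_complete, 0)

  # starting at the optimum: one sweep, no move
  gr2 <- greedy_search(sp, pol, one, sched, start = comp$optimal_limits)
  expect_equal(gr2$optimal_limits, comp$optimal_limits)

  set.seed(34)
  gaps <- replicate(20, {
    inst <- random_instance(n_sets = 3, n_res = 2, max_cap = 5)
    p <- policy_spec("OU", uniform_rate = runif(1, 0.05, 0.4))
    spr <- search_space(inst$config)
    cr <- complete_search(spr, p, inst$config, inst$schedule)
    gr <- greedy_search(spr, p, inst$config, inst$schedule, complete = cr)
    gr$gap_to_complete
  })
  expect_true(all(gaps >= -1e-9))
})
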