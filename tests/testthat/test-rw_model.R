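test_that("primitive model operations match hand arithmetic", {
  expect_equal(prediction_error(1, 1, 0.5), 0.5)
  expect_equal(prediction_error(0.8, 1, 0.25), 0.55)
  # literal coding: a non-reward wipes rho out of the error
  expect_equal(prediction_error(0.7, 0, 0.3), -0.3)
  expect_equal(prediction_error(0.2, 0, 0.3), -0.3)

  expect_equal(update_value(0.5, 1e-12, 0.9), 0.5, tolerance = 1e-9)
  expect_equal(update_value(0.5, 0.5, 0.5), 0.75)
  expect_equal(update_value(0.75, 0.2, -0.75), 0.6)
  expect_equal(update_value(0.9, 0.9, 1), 1)  # clipped

  expect_equal(choice_probability(10, 0.5, 0.5), 0.5)
  expect_equal(choice_probability(50, 0.75, 0.25), 1, tolerance = 1e-10)
  expect_equal(choice_probability(1, 0.85, 0.15), 1 / (1 + exp(-0.7)))
})

test_that("choice probabilities are complementary and monotone", {
  set.seed(4)
  for (i in 1:50) {
    th <- runif(1, 1, 50); a <- runif(1); b <- runif(1)
    expect_equal(choice_probability(th, a, b) + choice_probability(th, b, a), 1)
  }
  gaps <- seq(-1, 1, by = 0.1)
  p <- choice_probability(5, (1 + gaps) / 2, (1 - gaps) / 2)
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(choice_probability(seq(1, 50, 5), 0.7, 0.3)) > 0))
})

test_that("a two-event hand trace reproduces the recursion", {
  p <- rw_params(0.5, 0.3, 1, 0.5, 10, 10)
  st <- value_state("77")
  s1 <- rw_step(st, p, "77", "A", "reward")
  expect_equal(s1$p_choice, 0.5)           # fresh state: equal values
  expect_equal(s1$state$p_a[["77"]], 0.75) # 0.5 + 0.5*(1*1 - 0.5)
  s2 <- rw_step(s1$state, p, "77", "A", "reward")
  expect_equal(s2$p_choice, 1 / (1 + exp(-10 * 0.5)))
  expect_error(rw_step(st, p, "99", "A", "reward"), "unknown stimulus")
})

test_that("likelihood equals chance for first presentations", {
  p <- default_rw_params()
  ev1 <- make_events("10", "A", "reward")
  expect_equal(negative_log_likelihood(p, ev1), log(2), tolerance = 1e-12)
  ev4 <- make_events(c("10", "12", "14", "16"), rep("B", 4),
                     c("reward", "nonreward", "reward", "nonreward"))
  expect_equal(negative_log_likelihood(p, ev4), 4 * log(2), tolerance = 1e-12)
})

test_that("likelihood matches the brute-force oracle on random sequences", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    ev <- make_events(sample(c("10", "12"), n, replace = TRUE),
                      sample(c("A", "B"), n, replace = TRUE),
                      sample(c("reward", "nonreward"), n, replace = TRUE))
    p <- rw_params(runif(1), runif(1), runif(1), runif(1),
                   runif(1, 1, 50), runif(1, 1, 50))
    for (coding in c("signed", "literal"))
      expect_equal(negative_log_likelihood(p, ev, coding),
                   oracle_nll(p, ev, coding), tolerance = 1e-10)
  }
})

test_that("mixed-condition or unordered input is rejected", {
  p <- default_rw_params()
  ev <- make_events(c("10", "12"), c("A", "B"), c("reward", "reward"))
  ev$condition <- c("social", "nonsocial")
  expect_error(negative_log_likelihood(p, ev), "mix conditions")
  ev2 <- make_events(c("10", "12"), c("A", "B"), c("reward", "reward"))
  ev2$cycle <- c(2, 1)
  expect_error(negative_log_likelihood(p, ev2), "presentation order")
})

test_that("literal coding makes the trajectory independent of rho_loss", {
  ev <- make_events(rep("10", 8), rep("A", 8), rep("nonreward", 8))
  base <- rw_params(0.5, 0.4, 0.8, 0.1, 5, 5)
  alt <- rw_params(0.5, 0.4, 0.8, 0.9, 5, 5)
  expect_equal(negative_log_likelihood(base, ev, "literal"),
               negative_log_likelihood(alt, ev, "literal"), tolerance = 1e-14)
  expect_equal(choice_probabilities(base, ev, "literal"),
               choice_probabilities(alt, ev, "literal"), tolerance = 1e-14)
  # under signed coding rho_loss matters
  expect_false(isTRUE(all.equal(negative_log_likelihood(base, ev, "signed"),
                                negative_log_likelihood(alt, ev, "signed"))))
})

test_that("constant reward drives the chosen value to rho_win", {
  rho <- 0.73
  p <- rw_params(0.3, 0.3, rho, 0.5, 5, 5)
  st <- value_state("10")
  for (i in 1:200) st <- rw_step(st, p, "10", "A", "reward")$state
  expect_equal(st$p_a[["10"]], rho, tolerance = 1e-8)
})

test_that("simulation is deterministic and learns under strong parameters", {
  cfg <- task_config()
  sched <- build_schedule(cfg, seed = 8)
  strong <- rw_params(0.7, 0.7, 0.95, 0.95, 15, 15)
  s1 <- simulate_agent(strong, sched, cfg, seed = 21)
  s2 <- simulate_agent(strong, sched, cfg, seed = 21)
  expect_identical(s1, s2)
  # many strong learners: late cycles near ceiling, first cycle near chance
  accs <- replicate(60, {
    sim <- simulate_agent(strong, build_schedule(cfg, seed = NULL), cfg)
    c(first = mean(sim$is_correct[sim$cycle == 1]),
      late = mean(sim$is_correct[sim$cycle >= 9]))
  })
  expect_equal(mean(accs["first", ]), 0.5, tolerance = 0.08)
  expect_gt(mean(accs["late", ]), 0.85)
})
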