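test_that("logistic transform maps the raw box into the parameter space", {
  p <- to_constrained(c(0, 0, 0, 0, 1, 50))
  expect_equal(as.numeric(p[1:4]), rep(0.5, 4))
  expect_equal(p[["theta_win"]], 1)    # theta passes through untransformed
  expect_equal(p[["theta_loss"]], 50)
  lo <- to_constrained(c(-10, 10, -10, 10, 25, 25))
  expect_equal(lo[["alpha_win"]], 4.539787e-05, tolerance = 1e-6)
  expect_equal(lo[["alpha_loss"]], 0.9999546, tolerance = 1e-7)
  expect_error(to_constrained(c(11, 0, 0, 0, 5, 5)), "box")
  expect_error(to_constrained(c(0, 0, 0, 0, 0.5, 5)), "box")
})

test_that("penalized objective reduces to the likelihood when penalties are off", {
  ev <- make_events(c("10", "12", "10", "12"), c("A", "B", "A", "B"),
                    c("reward", "nonreward", "reward", "reward"))
  raw <- c(0.3, -0.2, 1, 0.5, 8, 4)
  off <- fit_config(lambda_l1 = 0, lambda_l2 = 0)
  expect_equal(penalized_objective(raw, ev, config = off),
               negative_log_likelihood(to_constrained(raw), ev))
  # raw alpha/rho of 0 incur no penalty
  raw0 <- c(0, 0, 0, 0, 8, 4)
  on <- fit_config()
  expect_equal(penalized_objective(raw0, ev, config = on),
               negative_log_likelihood(to_constrained(raw0), ev))
  # (1, -1, 2, 0): L1 = 0.01*4, L2 = 0.01*6; theta never penalized
  rawp <- c(1, -1, 2, 0, 8, 4)
  expect_equal(penalized_objective(rawp, ev, config = on) -
                 negative_log_likelihood(to_constrained(rawp), ev),
               0.10, tolerance = 1e-12)
})

test_that("fitting a known learner is deterministic and beats its starts", {
  cfg <- task_config()
  sched <- build_schedule(cfg, seed = 3)
  truth <- rw_params(0.4, 0.3, 0.8, 0.4, 8, 4)
  ev <- simulate_agent(truth, sched, cfg, seed = 5)
  ev <- ev[ev$condition == "social", ]
  f1 <- fit_participant_condition(ev, config = fit_config(n_restarts = 6), seed = 13)
  f2 <- fit_participant_condition(ev, config = fit_config(n_restarts = 6), seed = 13)
  expect_identical(f1[c("params", "raw", "objective", "nll")],
                   f2[c("params", "raw", "objective", "nll")])
  expect_true(f1$converged)
  expect_false(f1$failed)
  # penalized objective dominated by the unpenalized likelihood part
  expect_gte(f1$objective, f1$nll)
  # optimum at least as good as every restart's start point
  set.seed(13)
  starts <- matrix(runif(6 * 6, c(rep(-10, 4), 1, 1), c(rep(10, 4), 50, 50)),
                   ncol = 6)
  start_obj <- apply(starts, 2, penalized_objective, events = ev,
                     config = fit_config(n_restarts = 6))
  expect_true(all(f1$objective <= start_obj + 1e-8))
})

test_that("random responders fit to the chance likelihood bound", {
  set.seed(77)
  ev <- make_events(sample(c("10", "12", "14", "16"), 48, replace = TRUE),
                    sample(c("A", "B"), 48, replace = TRUE),
                    sample(c("reward", "nonreward"), 48, replace = TRUE))
  f <- fit_participant_condition(ev, config = fit_config(n_restarts = 6), seed = 2)
  expect_equal(f$nll, 48 * log(2), tolerance = 0.1)
  expect_error(fit_participant_condition(ev[1:5, ]), ">= 8 events")
})

test_that("stronger shrinkage weakly contracts the raw alpha/rho optimum", {
  cfg <- task_config()
  sched <- build_schedule(cfg, seed = 31)
  ev <- simulate_agent(rw_params(0.6, 0.2, 0.9, 0.3, 12, 3), sched, cfg,
                       seed = 32)
  ev <- ev[ev$condition == "nonsocial", ]
  norms <- vapply(c(0, 0.01, 0.5, 5), function(lam) {
    f <- fit_participant_condition(
      ev, config = fit_config(lambda_l1 = lam, lambda_l2 = lam,
                              n_restarts = 6), seed = 4)
    sum(abs(f$raw[1:4]))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-4))
})

test_that("literal-coding fits leave rho_loss at its shrinkage target", {
  cfg <- task_config()
  sched <- build_schedule(cfg, seed = 51)
  ev <- simulate_agent(rw_params(0.5, 0.4, 0.8, 0.7, 8, 8), sched, cfg,
                       coding = "literal", seed = 52)
  ev <- ev[ev$condition == "social", ]
  f <- fit_participant_condition(ev, coding = "literal",
                                 config = fit_config(n_restarts = 8), seed = 6)
  # likelihood is flat in raw rho_loss; only the penalty acts, pulling it to 0
  expect_equal(unname(f$raw["raw_rho_loss"]), 0, tolerance = 1e-3)
  expect_equal(f$params[["rho_loss"]], 0.5, tolerance = 1e-3)
})

test_that("cohort fitting yields one row per participant and condition", {
  d <- small_cohort()
  pt <- small_param_table()
  expect_equal(nrow(pt), 2L * length(unique(d$trials$participant_id)))
  expect_identical(names(pt),
                   c("participant_id", "condition", "alpha_win", "alpha_loss",
                     "rho_win", "rho_loss", "theta_win", "theta_loss", "nll",
                     "penalized_obj", "converged", "n_events"))
  expect_true(all(pt$n_events == 48L))
  expect_true(all(pt$alpha_win > 0 & pt$alpha_win < 1))
  expect_true(all(pt$theta_win >= 1 & pt$theta_win <= 50))

  # a participant missing one condition is reported and skipped
  tr <- d$trials
  tr <- tr[!(tr$participant_id == tr$participant_id[1] &
               tr$condition == "social"), ]
  expect_warning(
    pt2 <- fit_cohort(tr[tr$participant_id %in% unique(tr$participant_id)[1:2], ],
                      config = fit_config(n_restarts = 2), seed = 1),
    "missing a condition")
  expect_equal(nrow(pt2), 2L)

  expect_warning(empty <- fit_cohort(tr[0, ]), "empty")
  expect_equal(nrow(empty), 0L)
})
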