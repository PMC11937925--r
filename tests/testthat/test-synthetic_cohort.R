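test_that("AQ moment matching hits its targets and respects the score range", {
  m <- aq_model()
  expect_gt(m$a, 0); expect_gt(m$b, 0)
  x <- sample_aq(2e4, m, seed = 10)
  expect_true(all(x >= 0 & x <= 33))
  expect_equal(mean(x), 9.45, tolerance = 0.12)   # MC se ~ 0.035
  expect_equal(sd(x), 4.88, tolerance = 0.12)
  skew <- mean(((x - mean(x)) / sd(x))^3)
  expect_gt(skew, 0)  # right skew emerges from the low mean
  # degenerate spread: everyone at the rounded mean
  x0 <- sample_aq(50, list(sd = 0, mean = 9.45, n_items = 33))
  expect_true(all(x0 == 9L))
  # infeasible targets rejected
  expect_error(aq_model(mean = 40), "mean")
  expect_error(aq_model(sd = 1), "underdispersion")
  expect_error(aq_model(sd = 40), "too large")
})

test_that("AQ-parameter linkage has the configured sign and vanishes at null", {
  n <- 4000
  aq_c <- seq(-10, 10, length.out = n)
  cfg_eff <- cohort_config()
  cfg_null <- cohort_config(slope_rho_win = 0, slope_theta_loss = 0)
  set.seed(5)
  draw <- function(cfg) {
    t(vapply(aq_c, function(a) {
      p <- sample_parameters(a, cfg)[[1]]
      c(p[["rho_win"]], p[["theta_loss"]])
    }, numeric(2)))
  }
  eff <- draw(cfg_eff)
  null <- draw(cfg_null)
  expect_lt(cor(aq_c, eff[, 1]), -0.2)  # negative rho_win slope
  expect_gt(cor(aq_c, eff[, 2]), 0.2)   # positive theta_loss slope
  expect_lt(abs(cor(aq_c, null[, 1])), 0.06)
  expect_lt(abs(cor(aq_c, null[, 2])), 0.06)
})

test_that("generated parameters respect their boxes", {
  set.seed(9)
  for (a in c(-12, 0, 12)) {
    ps <- sample_parameters(a, cohort_config())
    for (p in ps) {
      expect_true(all(p[1:4] > 0 & p[1:4] < 1))
      expect_true(all(p[5:6] >= 1 & p[5:6] <= 50))
    }
  }
})

test_that("dataset generation is aligned, complete and reproducible", {
  cfg <- cohort_config(n_participants = 6L, seed = 77L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$truth, d2$truth)
  expect_equal(nrow(d1$trials), 6L * 96L)
  expect_equal(nrow(d1$aq), 6L)
  expect_equal(nrow(d1$truth), 12L)
  expect_setequal(unique(d1$trials$participant_id), d1$aq$participant_id)
  # re-simulating one participant from the stored truth reproduces the data
  id <- d1$aq$participant_id[3]
  tru <- d1$truth[d1$truth$participant_id == id, ]
  params <- lapply(seq_len(2), function(k)
    rw_params(tru$true_alpha_win[k], tru$true_alpha_loss[k],
              tru$true_rho_win[k], tru$true_rho_loss[k],
              tru$true_theta_win[k], tru$true_theta_loss[k]))
  names(params) <- tru$condition
  sched <- build_schedule(cfg$task, seed = child_seed(cfg$seed, 3L * 3L - 1L))
  resim <- simulate_agent(params, sched, cfg$task,
                          seed = child_seed(cfg$seed, 3L * 3L))
  got <- d1$trials[d1$trials$participant_id == id, ]
  rownames(got) <- NULL
  expect_identical(got[, names(resim)], resim)
})

test_that("CSV round-trip preserves the trial table", {
  cfg <- cohort_config(n_participants = 3L, seed = 5L)
  dir <- withr::local_tempdir()
  d <- generate_dataset(cfg, dir = dir)
  back <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(d$trials))
  expect_identical(back$choice, d$trials$choice)
  expect_identical(names(back), names(d$trials))
})

test_that("cohorts of strong learners show rising accuracy across cycles", {
  cfg <- cohort_config(n_participants = 20L, seed = 31L,
                       location = c(alpha_win = 0.5, alpha_loss = 0.5,
                                    rho_win = 2, rho_loss = 2,
                                    theta_win = 12, theta_loss = 12),
                       spread = c(alpha_win = 0.3, alpha_loss = 0.3,
                                  rho_win = 0.3, rho_loss = 0.3,
                                  theta_win = 2, theta_loss = 2))
  d <- generate_dataset(cfg)
  acc <- tapply(as.numeric(d$trials$is_correct), d$trials$cycle, mean)
  expect_equal(unname(acc["1"]), 0.5, tolerance = 0.12)
  expect_gt(mean(acc[as.character(9:12)]), mean(acc[as.character(1:4)]))
})
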