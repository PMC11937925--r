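test_that("signed-rank test matches exact enumeration and the textbook routine", {
  # all-positive differences, n = 5: V = 15, two-sided exact p = 2/32
  r <- wilcoxon_signed_rank(6:10, 1:5)
  expect_equal(r$statistic, 15)
  expect_equal(r$p, 2 / 32)
  expect_identical(r$method, "exact")

  # identical columns: degenerate
  dg <- wilcoxon_signed_rank(1:8, 1:8)
  expect_true(dg$degenerate)

  # agreement with stats::wilcox.test across random paired samples
  set.seed(123)
  for (i in 1:20) {
    n <- sample(c(8, 10, 12, 25, 40), 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE,
                       exact = (ours$method == "exact"), correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("win parameters exceed loss parameters in a win-biased cohort", {
  pt <- small_param_table()
  w <- wilcoxon_win_vs_loss(pt)
  expect_setequal(w$parameter, c("alpha", "rho", "theta"))
  # generator places win locations above loss locations for alpha and rho
  expect_gt(w$median_win[w$parameter == "rho"],
            w$median_loss[w$parameter == "rho"])
  expect_true(all(w$n <= length(unique(pt$participant_id))))
})

test_that("beta-likelihood mixed model is consistent and order-invariant", {
  cfg <- cohort_config(slope_rho_win = -0.12)
  tp <- truth_param_table(cfg, seed = 404)
  b <- fit_beta_mixed(tp$params, tp$aq, "rho_win")
  fx <- b$fixed
  expect_equal(fx$or, exp(fx$estimate), tolerance = 1e-12)
  expect_gt(b$phi, 0)
  # generated negative AQ slope surfaces as OR < 1
  expect_lt(fx$or[fx$term == "aq_c"], 1)
  # shuffling participant rows leaves the fixed effects unchanged
  perm <- sample(nrow(tp$params))
  b2 <- fit_beta_mixed(tp$params[perm, ], tp$aq, "rho_win")
  expect_equal(b$fixed$estimate, b2$fixed$estimate, tolerance = 1e-6)
})

test_that("an intercept-only symmetric cohort centres near 0.5", {
  set.seed(31)
  n <- 60
  v <- plogis(rnorm(2 * n, 0, 0.4))
  pt <- data.frame(participant_id = rep(sprintf("P%02d", 1:n), each = 2),
                   condition = rep(c("nonsocial", "social"), n),
                   rho_win = v, stringsAsFactors = FALSE)
  aq <- data.frame(participant_id = sprintf("P%02d", 1:n),
                   aq_score = sample(0:20, n, TRUE))
  b <- fit_beta_mixed(pt, aq, "rho_win")
  mu <- plogis(b$fixed$estimate[b$fixed$term == "(Intercept)"])
  expect_equal(mu, 0.5, tolerance = 0.06)
})

test_that("theta LMM reports Satterthwaite t, df and the effect size identity", {
  cfg <- cohort_config(slope_theta_loss = 0.3)
  tp <- truth_param_table(cfg, seed = 505)
  l <- fit_lmm_theta(tp$params, tp$aq, "theta_loss")
  fx <- l$fixed
  expect_equal(fx$r, fx$t / sqrt(fx$t^2 + fx$df), tolerance = 1e-12)
  expect_true(all(abs(fx$r) < 1))
  # sign recovery is stochastic per cohort; demand a positive majority
  ests <- vapply(505:509, function(s) {
    tp_s <- truth_param_table(cfg, seed = s)
    f <- fit_lmm_theta(tp_s$params, tp_s$aq, "theta_loss")$fixed
    f$estimate[f$term == "aq_c"]
  }, numeric(1))
  expect_gte(sum(ests > 0), 4)
  expect_gt(mean(ests), 0)
})

test_that("simple slopes equal the interaction fit's linear combinations", {
  cfg <- cohort_config()
  tp <- truth_param_table(cfg, seed = 606)
  ss <- simple_slopes(tp$params, tp$aq, "rho_win")
  expect_equal(nrow(ss), 2L)
  b <- fit_beta_mixed(tp$params, tp$aq, "rho_win", include_interaction = TRUE)
  est <- setNames(b$fixed$estimate, b$fixed$term)
  expect_equal(ss$estimate[ss$condition == "nonsocial"],
               unname(est["aq_c"]), tolerance = 1e-4)
  expect_equal(ss$estimate[ss$condition == "social"],
               unname(est["aq_c"] + est["conditionsocial:aq_c"]),
               tolerance = 1e-4)
  # no condition-specific slopes in truth: CIs overlap
  expect_lt(max(ss$ci_low), min(ss$ci_high))
})

test_that("permutation p obeys the add-one rule, bounds and determinism", {
  cfg <- cohort_config(slope_rho_win = -0.25)  # strong effect
  tp <- truth_param_table(cfg, seed = 707)
  pr <- permutation_test_aq(tp$params, tp$aq, "rho_win", n_perm = 99,
                            seed = 3, engine = "fixed")
  pr2 <- permutation_test_aq(tp$params, tp$aq, "rho_win", n_perm = 99,
                             seed = 3, engine = "fixed")
  expect_identical(pr$p, pr2$p)
  expect_gte(pr$p, 1 / 100)
  # the strong effect beats every permutation: p at the lower bound
  expect_equal(pr$p, 1 / 100)
  expect_error(permutation_test_aq(tp$params, tp$aq, n_perm = 5), "19")
})

test_that("cluster bootstrap CI brackets a strong effect, deterministically", {
  cfg <- cohort_config(slope_rho_win = -0.25)
  tp <- truth_param_table(cfg, seed = 808)
  b1 <- bootstrap_aq(tp$params, tp$aq, "rho_win", n_boot = 199, seed = 9,
                     engine = "fixed")
  b2 <- bootstrap_aq(tp$params, tp$aq, "rho_win", n_boot = 199, seed = 9,
                     engine = "fixed")
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_lt(b1$ci_low, b1$observed)
  expect_gt(b1$ci_high, b1$observed)
  expect_lt(b1$ci_high, 0)  # strong negative effect excludes zero
  expect_error(bootstrap_aq(tp$params, tp$aq, n_boot = 50), "199")
})
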