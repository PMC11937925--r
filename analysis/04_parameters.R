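#!/usr/bin/env Rscript

# Stage 4: group-level statistics on the fitted learner parameters.
#
# Win-vs-loss signed-rank comparisons; beta-likelihood mixed regressions
# of each bounded parameter on condition and centred AQ; a Gaussian LMM
# for the inverse temperatures; simple slopes for the AQ effect on
# rho_win; and permutation/bootstrap robustness checks of that effect.

suppressPackageStartupMessages(library(rwvalence))

params <- read.csv("results/parameters.csv", stringsAsFactors = FALSE)
aq <- read.csv("results/data/aq.csv", stringsAsFactors = FALSE)

w <- wilcoxon_win_vs_loss(params)
write.csv(w, "results/wilcoxon.csv", row.names = FALSE)
cat("win vs loss (signed-rank, conditions averaged):\n")
print(cbind(w[, c("parameter", "statistic", "n", "method")],
            p = signif(w$p, 3),
            median_win = round(w$median_win, 3),
            median_loss = round(w$median_loss, 3)))

cat("\nbeta-likelihood mixed regressions (AQ effect as OR):\n")
beta_rows <- list()
for (target in c("alpha_win", "alpha_loss", "rho_win", "rho_loss")) {
  b <- fit_beta_mixed(params, aq, target)
  fx <- b$fixed[b$fixed$term == "aq_c", ]
  beta_rows[[target]] <- data.frame(target = target, or = fx$or,
                                    ci_low = fx$ci_low, ci_high = fx$ci_high,
                                    p = fx$p)
  cat(sprintf("  %-10s AQ OR = %.3f [%.3f, %.3f], p = %.3f\n", target,
              fx$or, fx$ci_low, fx$ci_high, fx$p))
}
write.csv(do.call(rbind, beta_rows), "results/beta_aq_effects.csv",
          row.names = FALSE)

cat("\nlinear mixed models for theta (AQ effect):\n")
for (target in c("theta_win", "theta_loss")) {
  l <- fit_lmm_theta(params, aq, target)
  fx <- l$fixed[l$fixed$term == "aq_c", ]
  cat(sprintf("  %-10s beta = %.3f, t(%.0f) = %.2f, p = %.3f, r = %.2f\n",
              target, fx$estimate, fx$df, fx$t, fx$p, fx$r))
  write.csv(l$fixed, sprintf("results/lmm_%s.csv", target),
            row.names = FALSE)
}

ss <- simple_slopes(params, aq, "rho_win")
write.csv(ss, "results/simple_slopes_rho_win.csv", row.names = FALSE)
cat("\nsimple slopes of AQ on rho_win:\n")
print(cbind(ss[, "condition", drop = FALSE],
            round(ss[, c("or", "ci_low", "ci_high", "p")], 3)))

cat("\nrobustness of the AQ -> rho_win effect:\n")
pr <- permutation_test_aq(params, aq, "rho_win", n_perm = 499L, seed = 404L)
cat(sprintf("  permutation: observed coef %.4f, empirical p = %.3f (%d perms)\n",
            pr$observed, pr$p, pr$n_resamples))
bt <- bootstrap_aq(params, aq, "rho_win", n_boot = 499L, seed = 505L)
cat(sprintf("  cluster bootstrap: 95%% CI [%.4f, %.4f]\n",
            bt$ci_low, bt$ci_high))
writeLines(c(sprintf("permutation_p = %.6f", pr$p),
             sprintf("bootstrap_ci = [%.6f, %.6f]", bt$ci_low, bt$ci_high)),
           "results/robustness_rho_win.txt")
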