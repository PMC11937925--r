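#!/usr/bin/env Rscript

# Stage 3: behavioural (model-free) analysis of learning performance.
#
# Per-cycle accuracy, the event-level mixed logistic learning model
# correct ~ condition * cycle * AQ_centred + (1 + condition + cycle | id),
# and the likelihood-ratio test for the by-participant random slopes
# (5 df: unstructured 3x3 covariance vs intercept only).

suppressPackageStartupMessages(library(rwvalence))

trials <- read.csv("results/data/trials.csv", stringsAsFactors = FALSE)
aq <- read.csv("results/data/aq.csv", stringsAsFactors = FALSE)

acc <- aggregate_accuracy(trials)
write.csv(acc, "results/accuracy.csv", row.names = FALSE)
curve <- tapply(acc$accuracy, acc$cycle, mean)
cat("cohort learning curve (mean accuracy by cycle):\n")
print(round(curve, 3))

g <- fit_learning_model(trials, aq)
write.csv(g$fixed, "results/glmm_fixed.csv", row.names = FALSE)
cat("\nfixed effects (odds ratios, Wald 95% CI):\n")
print(cbind(round(g$fixed[, c("or", "ci_low", "ci_high")], 3),
            p = signif(g$fixed$p, 3)))
cyc <- g$fixed[g$fixed$term == "cycle", ]
cat(sprintf("\ncycle effect: OR = %.3f [%.3f, %.3f] -- the cohort learns\n",
            cyc$or, cyc$ci_low, cyc$ci_high))

lr <- random_slope_lr_test(trials, aq)
cat(sprintf("random-slope LR test: chi2(%d) = %.1f, p = %.2g\n",
            lr$df, lr$statistic, lr$p))
writeLines(c("random_slope_lr_test",
             sprintf("chi2 = %.4f", lr$statistic),
             sprintf("df = %d", lr$df),
             sprintf("p = %.6g", lr$p)),
           "results/lr_test.txt")
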