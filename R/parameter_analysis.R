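#' Wilcoxon signed-rank test (paired)
#'
#' Direct implementation of the signed-rank test: zero differences are
#' dropped, absolute differences midranked, and the statistic is the sum of
#' ranks of positive differences. For `n <= 12` non-zero pairs the null is
#' enumerated exactly over all sign patterns; beyond that a normal
#' approximation with continuity and tie corrections is used. Two-sided.
#'
#' @param x,y paired numeric vectors.
#' @return list: `statistic` (V, sum of positive ranks), `p`, `n` (non-zero
#'   pairs), `method`, `degenerate` (TRUE when all differences are zero).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p = NA_real_, n = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 12L) {
    # exact: all 2^n sign assignments of the observed (mid)ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_null <- as.vector(signs %*% r)
    p <- mean(abs(v_null - mu) >= abs(v - mu) - 1e-12)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(v - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = v, p = min(p, 1), n = n, method = method,
       degenerate = FALSE)
}

#' Win-versus-loss parameter comparisons
#'
#' For each parameter family (alpha, rho, theta) the win and loss values
#' are averaged over the two conditions within participant and compared by
#' the paired signed-rank test ([wilcoxon_signed_rank()]).
#'
#' @param param_table a [fit_cohort()]-dialect parameter table.
#' @return data.frame `parameter`, `statistic`, `p`, `n`, `method`,
#'   `degenerate`, `median_win`, `median_loss`.
#' @export
wilcoxon_win_vs_loss <- function(param_table) {
  fam <- c("alpha", "rho", "theta")
  rows <- lapply(fam, function(f) {
    w <- tapply(param_table[[paste0(f, "_win")]],
                param_table$participant_id, mean)
    l <- tapply(param_table[[paste0(f, "_loss")]],
                param_table$participant_id, mean)
    l <- l[names(w)]
    t <- wilcoxon_signed_rank(as.numeric(w), as.numeric(l))
    data.frame(parameter = f, statistic = t$statistic, p = t$p, n = t$n,
               method = t$method, degenerate = t$degenerate,
               median_win = stats::median(w), median_loss = stats::median(l),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Assemble the analysis frame for one parameter column: centred AQ,
# non-social reference condition, boundary values nudged off 0/1.
param_model_frame <- function(param_table, aq_table, target,
                              nudge = 1e-6) {
  if (!target %in% names(param_table))
    stop("unknown target parameter '", target, "'", call. = FALSE)
  d <- merge(param_table[, c("participant_id", "condition", target)],
             aq_table, by = "participant_id")
  names(d)[names(d) == target] <- "value"
  lev <- unique(d$condition)
  lev <- c(lev[grepl("^non", lev)], lev[!grepl("^non", lev)])
  d$condition <- factor(d$condition, levels = lev)
  d$aq_c <- d$aq_score - mean(aq_table$aq_score)
  d$participant_id <- factor(d$participant_id)
  at_bound <- d$value <= 0 | d$value >= 1
  if (grepl("^(alpha|rho)", target) && any(at_bound)) {
    message("param_model_frame: nudging ", sum(at_bound),
            " boundary value(s) off 0/1 for the beta likelihood")
    d$value <- pmin(1 - nudge, pmax(nudge, d$value))
  }
  d
}

summarize_beta_fit <- function(fit, simplified) {
  est <- glmmTMB::fixef(fit)$cond
  se <- sqrt(diag(as.matrix(vcov(fit)$cond)))
  phi <- glmmTMB::sigma(fit)  # beta precision
  re <- tryCatch(glmmTMB::VarCorr(fit)$cond$participant_id[1, 1],
                 error = function(e) NA_real_)
  structure(list(fixed = wald_or_table(est, se, names(est)),
                 phi = phi, ranef_var = re,
                 loglik = as.numeric(logLik(fit)), model = fit,
                 simplified = simplified, converged = TRUE),
            class = "beta_mixed_summary")
}

#' Beta-likelihood mixed regression of a bounded parameter on AQ
#'
#' Models a (0,1)-bounded fitted parameter (alpha or rho, win or loss) with
#' a beta likelihood and logit link: intercept + condition + centred AQ
#' (+ AQ-by-condition interaction on request) as fixed effects and a
#' participant random intercept (each participant contributes one value per
#' condition). Fixed effects are reported as odds ratios with Wald CIs.
#' Falls back to a fixed-effects-only beta regression when the mixed fit
#' fails, with a flag in the summary.
#'
#' @param param_table a [fit_cohort()]-dialect parameter table (fitted or
#'   ground-truth values).
#' @param aq_table data.frame `participant_id`, `aq_score`.
#' @param target one of `"alpha_win"`, `"alpha_loss"`, `"rho_win"`,
#'   `"rho_loss"`.
#' @param include_interaction add the AQ-by-condition term?
#' @return a `beta_mixed_summary` list: `fixed`, `phi` (beta precision),
#'   `ranef_var`, `loglik`, `model`, `simplified`, `converged`.
#' @export
fit_beta_mixed <- function(param_table, aq_table,
                           target = c("rho_win", "rho_loss", "alpha_win",
                                      "alpha_loss"),
                           include_interaction = FALSE) {
  target <- match.arg(target)
  d <- param_model_frame(param_table, aq_table, target)
  f <- if (include_interaction)
    value ~ condition * aq_c + (1 | participant_id)
  else value ~ condition + aq_c + (1 | participant_id)
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(f, data = d,
                                      family = glmmTMB::beta_family())),
    error = function(e) NULL)
  bad <- is.null(fit) || !fit$sdr$pdHess ||
    any(!is.finite(sqrt(diag(as.matrix(vcov(fit)$cond)))))
  if (bad) {
    message("fit_beta_mixed: mixed fit failed for ", target,
            "; falling back to fixed effects only")
    f0 <- if (include_interaction) value ~ condition * aq_c
          else value ~ condition + aq_c
    fit <- glmmTMB::glmmTMB(f0, data = d, family = glmmTMB::beta_family())
    out <- summarize_beta_fit(fit, simplified = "fixed_only")
    out$converged <- FALSE
    return(out)
  }
  summarize_beta_fit(fit, simplified = "none")
}

#' Linear mixed model for inverse temperature
#'
#' Theta is unbounded above 1, so it is analysed with a Gaussian linear
#' mixed model: condition + centred AQ fixed effects, participant random
#' intercept. p-values use Satterthwaite degrees of freedom; each fixed
#' effect carries the effect size `r = t / sqrt(t^2 + df)`. Singular random
#' effects trigger a plain linear-model fallback (logged).
#'
#' @param param_table parameter table.
#' @param aq_table AQ table.
#' @param target `"theta_win"` or `"theta_loss"`.
#' @return an `lmm_summary` list with a `fixed` data.frame
#'   (`term`, `estimate`, `se`, `t`, `df`, `p`, `r`), `model`, `simplified`.
#' @export
fit_lmm_theta <- function(param_table, aq_table,
                          target = c("theta_loss", "theta_win")) {
  target <- match.arg(target)
  d <- param_model_frame(param_table, aq_table, target)
  fit <- suppressWarnings(suppressMessages(
    lmerTest::lmer(value ~ condition + aq_c + (1 | participant_id),
                   data = d)))
  if (lme4::isSingular(fit)) {
    message("fit_lmm_theta: singular random intercept for ", target,
            "; falling back to ordinary least squares")
    ols <- stats::lm(value ~ condition + aq_c, data = d)
    cf <- summary(ols)$coefficients
    df <- ols$df.residual
    fixed <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                        t = cf[, 3], df = df, p = cf[, 4],
                        r = cf[, 3] / sqrt(cf[, 3]^2 + df),
                        stringsAsFactors = FALSE, row.names = NULL)
    return(structure(list(fixed = fixed, model = ols, simplified = "ols"),
                     class = "lmm_summary"))
  }
  cf <- summary(fit)$coefficients  # Satterthwaite df from lmerTest
  fixed <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"], t = cf[, "t value"],
                      df = cf[, "df"], p = cf[, "Pr(>|t|)"],
                      r = effect_size_r(cf[, "t value"], cf[, "df"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fixed = fixed, model = fit, simplified = "none"),
            class = "lmm_summary")
}

#' Effect size r from a t statistic
#'
#' `r = t / sqrt(t^2 + df)`, the point-biserial-style effect size used to
#' accompany mixed-model t tests.
#'
#' @param t t statistic.
#' @param df degrees of freedom.
#' @return effect size in (-1, 1).
#' @export
effect_size_r <- function(t, df) t / sqrt(t^2 + df)

#' Per-condition AQ slopes (simple slopes)
#'
#' Re-expresses the AQ effect within each condition by refitting the
#' interaction model with condition-nested AQ terms
#' (`value ~ condition + condition:aq_c + (1 | participant)`), whose
#' coefficients are exactly the per-condition slopes (a linear
#' recombination of the interaction fit's coefficients). Reported as odds
#' ratios with Wald CIs.
#'
#' @param param_table parameter table.
#' @param aq_table AQ table.
#' @param target bounded parameter column.
#' @return data.frame `condition`, `estimate`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
simple_slopes <- function(param_table, aq_table, target = "rho_win") {
  d <- param_model_frame(param_table, aq_table, target)
  fit <- suppressWarnings(glmmTMB::glmmTMB(
    value ~ condition + condition:aq_c + (1 | participant_id),
    data = d, family = glmmTMB::beta_family()))
  est <- glmmTMB::fixef(fit)$cond
  se <- sqrt(diag(as.matrix(vcov(fit)$cond)))
  keep <- grepl(":aq_c$", names(est))
  tab <- wald_or_table(est[keep], se[keep], names(est)[keep])
  tab$condition <- sub(":aq_c$", "", sub("^condition", "", tab$term))
  tab[, c("condition", "estimate", "se", "or", "ci_low", "ci_high", "p")]
}

# AQ coefficient of the chosen beta-regression engine; the statistic
# recomputed inside the resampling loops.
aq_coefficient <- function(d, engine = c("mixed", "fixed")) {
  engine <- match.arg(engine)
  if (engine == "mixed") {
    fit <- suppressWarnings(glmmTMB::glmmTMB(
      value ~ condition + aq_c + (1 | participant_id),
      data = d, family = glmmTMB::beta_family()))
    if (!fit$sdr$pdHess) stop("non-pd Hessian")
    unname(glmmTMB::fixef(fit)$cond["aq_c"])
  } else {
    fit <- mgcv::gam(value ~ condition + aq_c, data = d,
                     family = mgcv::betar())
    unname(coef(fit)["aq_c"])
  }
}

#' Permutation test for the AQ effect
#'
#' AQ scores are shuffled across participants (participant-level
#' exchangeability: both of a participant's condition rows receive the same
#' permuted score) and the AQ coefficient of the beta regression is
#' recomputed for each permutation. The empirical two-sided p-value uses
#' the add-one rule `(1 + #{|b_perm| >= |b_obs|}) / (n_perm + 1)`.
#'
#' @param param_table parameter table.
#' @param aq_table AQ table.
#' @param target bounded parameter column.
#' @param n_perm number of permutations (`>= 19`).
#' @param seed integer seed.
#' @param engine `"mixed"` (participant random intercept, glmmTMB) or
#'   `"fixed"` (fixed-effects beta regression; much faster, used for
#'   large replicate studies).
#' @return list of class `resampling_result`: `observed`, `n_resamples`,
#'   `p`, `n_failed`, `seed`.
#' @export
permutation_test_aq <- function(param_table, aq_table, target = "rho_win",
                                n_perm = 999L, seed = 1L,
                                engine = c("mixed", "fixed")) {
  engine <- match.arg(engine)
  if (n_perm < 19L)
    stop("permutation_test_aq: need at least 19 permutations", call. = FALSE)
  set.seed(seed)
  d <- param_model_frame(param_table, aq_table, target)
  obs <- aq_coefficient(d, engine)
  ids <- levels(d$participant_id)
  aq_by_id <- d$aq_c[match(ids, as.character(d$participant_id))]
  stat <- rep(NA_real_, n_perm)
  for (k in seq_len(n_perm)) {
    perm <- sample(aq_by_id)
    d$aq_c <- perm[match(as.character(d$participant_id), ids)]
    stat[k] <- tryCatch(aq_coefficient(d, engine), error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(stat))
  if (n_failed > 0.1 * n_perm)
    stop("permutation_test_aq: ", n_failed, "/", n_perm,
         " permutation fits failed; run invalidated", call. = FALSE)
  ok <- stat[!is.na(stat)]
  p <- (1 + sum(abs(ok) >= abs(obs))) / (length(ok) + 1)
  structure(list(observed = obs, n_resamples = length(ok), p = p,
                 n_failed = n_failed, seed = seed),
            class = "resampling_result")
}

#' Cluster bootstrap CI for the AQ effect
#'
#' Participants are resampled with replacement, each keeping both condition
#' rows, and the AQ coefficient refit per resample; the 95% percentile
#' interval is reported.
#'
#' @inheritParams permutation_test_aq
#' @param n_boot number of bootstrap resamples (`>= 199`).
#' @return list of class `resampling_result`: `observed`, `n_resamples`,
#'   `ci_low`, `ci_high`, `n_failed`, `seed`.
#' @export
bootstrap_aq <- function(param_table, aq_table, target = "rho_win",
                         n_boot = 999L, seed = 1L,
                         engine = c("mixed", "fixed")) {
  engine <- match.arg(engine)
  if (n_boot < 199L)
    stop("bootstrap_aq: need at least 199 resamples", call. = FALSE)
  set.seed(seed)
  d <- param_model_frame(param_table, aq_table, target)
  obs <- aq_coefficient(d, engine)
  ids <- levels(d$participant_id)
  rows_by_id <- split(seq_len(nrow(d)), as.character(d$participant_id))
  stat <- rep(NA_real_, n_boot)
  for (k in seq_len(n_boot)) {
    take <- sample(ids, replace = TRUE)
    db <- d[unlist(rows_by_id[take]), , drop = FALSE]
    # resampled clusters become distinct participants
    db$participant_id <- factor(rep(seq_along(take),
                                    vapply(rows_by_id[take], length, 1L)))
    stat[k] <- tryCatch(aq_coefficient(db, engine), error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(stat))
  if (n_failed > 0.1 * n_boot)
    stop("bootstrap_aq: ", n_failed, "/", n_boot,
         " bootstrap fits failed; run invalidated", call. = FALSE)
  ci <- quantile(stat[!is.na(stat)], c(0.025, 0.975), names = FALSE)
  structure(list(observed = obs, n_resamples = n_boot - n_failed,
                 ci_low = ci[1], ci_high = ci[2], n_failed = n_failed,
                 seed = seed),
            class = "resampling_result")
}
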