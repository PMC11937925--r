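#' Per-cycle accuracy
#'
#' Proportion of events on which the high-probability option was chosen,
#' per participant, condition and trial cycle.
#'
#' @param trials long-format trial table with `is_correct` filled in.
#' @return data.frame `participant_id`, `condition`, `cycle`, `accuracy`,
#'   `n_events`.
#' @export
aggregate_accuracy <- function(trials) {
  miss <- is.na(trials$choice) | is.na(trials$is_correct)
  if (any(miss)) {
    warning("aggregate_accuracy: excluding ", sum(miss),
            " events with missing choices")
    trials <- trials[!miss, , drop = FALSE]
  }
  agg <- aggregate(cbind(accuracy = as.numeric(trials$is_correct)),
                   by = list(participant_id = trials$participant_id,
                             condition = trials$condition,
                             cycle = trials$cycle),
                   FUN = mean)
  n <- aggregate(list(n_events = trials$is_correct),
                 by = list(participant_id = trials$participant_id,
                           condition = trials$condition,
                           cycle = trials$cycle),
                 FUN = length)
  out <- merge(agg, n)
  out <- out[order(out$participant_id, out$condition, out$cycle), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared fixed-effect summary: log-odds estimate, OR, Wald CI, z p-value
wald_or_table <- function(est, se, terms) {
  z <- est / se
  data.frame(term = terms, estimate = est, se = se, or = exp(est),
             ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
             p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
}

prepare_model_frame <- function(trials, aq_table) {
  d <- merge(trials, aq_table, by = "participant_id")
  if (nrow(d) < nrow(trials))
    stop("fit_learning_model: AQ score missing for some participants",
         call. = FALSE)
  d$correct <- as.integer(d$is_correct)
  # non-social as reference level
  lev <- unique(d$condition)
  lev <- c(lev[grepl("^non", lev)], lev[!grepl("^non", lev)])
  d$condition <- factor(d$condition, levels = lev)
  d$aq_c <- d$aq_score - mean(aq_table$aq_score)  # grand-mean centring
  d$participant_id <- factor(d$participant_id)
  d
}

#' Mixed logistic learning model
#'
#' Event-level binomial-logit mixed model of correctness on the full
#' three-way expansion of condition, trial cycle (continuous 1--12) and
#' grand-mean-centred AQ, with by-participant random intercept and random
#' slopes for condition and cycle:
#' `correct ~ condition * cycle * aq_c + (1 + condition + cycle | participant)`.
#' Fixed effects are reported as odds ratios with Wald 95% CIs. If the full
#' random structure fails to converge the model is refit first without
#' random-effect correlations, then with a random intercept only; every
#' simplification is recorded in the summary.
#'
#' @param trials long-format trial table.
#' @param aq_table data.frame `participant_id`, `aq_score`.
#' @return list of class `glmm_summary`: `fixed` (term/estimate/OR/CI/p
#'   table), `ranef_var`, `loglik`, `model`, `simplified`, `converged`.
#' @export
fit_learning_model <- function(trials, aq_table) {
  d <- prepare_model_frame(trials, aq_table)
  forms <- list(
    full = correct ~ condition * cycle * aq_c +
      (1 + condition + cycle | participant_id),
    nocorr = correct ~ condition * cycle * aq_c +
      (1 + condition + cycle || participant_id),
    intercept = correct ~ condition * cycle * aq_c + (1 | participant_id))
  fit <- NULL; used <- NA_character_
  for (nm in names(forms)) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::glmer(forms[[nm]], data = d, family = stats::binomial()))),
      error = function(e) NULL)
    ok <- !is.null(fit) && length(fit@optinfo$conv$lme4$messages) == 0L
    if (!is.null(fit)) { used <- nm; if (ok || nm == "intercept") break }
  }
  if (is.null(fit))
    stop("fit_learning_model: no random-effect structure converged",
         call. = FALSE)
  if (used != "full")
    message("fit_learning_model: random structure simplified to '", used, "'")
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  structure(list(fixed = wald_or_table(est, se, names(est)),
                 ranef_var = lme4::VarCorr(fit),
                 loglik = as.numeric(logLik(fit)),
                 model = fit, simplified = used,
                 converged = length(fit@optinfo$conv$lme4$messages) == 0L),
            class = "glmm_summary")
}

#' Likelihood-ratio test for random slopes
#'
#' Compares the learning model's full random structure (by-participant
#' intercept plus condition and cycle slopes, unstructured covariance: six
#' variance-covariance parameters) against a random-intercept-only model
#' (one), a 5-df chi-square test of inter-individual variability in
#' learning trajectories.
#'
#' @param trials long-format trial table.
#' @param aq_table data.frame `participant_id`, `aq_score`.
#' @return list of class `lr_test`: `statistic`, `df`, `p`.
#' @export
random_slope_lr_test <- function(trials, aq_table) {
  d <- prepare_model_frame(trials, aq_table)
  full <- suppressWarnings(suppressMessages(lme4::glmer(
    correct ~ condition * cycle * aq_c +
      (1 + condition + cycle | participant_id),
    data = d, family = stats::binomial())))
  reduced <- suppressWarnings(suppressMessages(lme4::glmer(
    correct ~ condition * cycle * aq_c + (1 | participant_id),
    data = d, family = stats::binomial())))
  stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(reduced)))
  if (stat < -1e-6)
    stop("random_slope_lr_test: negative LR statistic (", signif(stat, 3),
         "); nested fits did not both converge", call. = FALSE)
  stat <- max(stat, 0)
  df <- 5L
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lr_test")
}
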