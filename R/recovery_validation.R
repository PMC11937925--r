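#' Parameter-recovery experiment
#'
#' Simulates agents with known parameters on one condition's default
#' schedule (48 events), refits each by [fit_participant_condition()], and
#' quantifies truth-estimate agreement per parameter. True alpha and rho
#' are drawn uniformly over a behaviourally plausible range and theta over
#' the exploratory-to-exploitative span; see the methods vignette for the
#' rationale.
#'
#' @param n_agents number of simulated agents.
#' @param fit_cfg a [fit_config()].
#' @param task a [task_config()].
#' @param coding outcome coding used both to simulate and to fit.
#' @param n_blocks number of blocks of the agent's single condition to
#'   simulate (default `task$n_blocks_per_condition`, i.e. 48 events);
#'   increase to probe consistency with longer data.
#' @param alpha_range,rho_range,theta_range sampling ranges for the truths.
#' @param seed integer seed.
#' @return list of class `recovery_report`: `summary` (per parameter:
#'   `pearson`, `spearman`, `bias`, `rmse`, `n`), `truth`, `estimates`,
#'   `n_failed`.
#' @export
run_recovery <- function(n_agents = 100L, fit_cfg = fit_config(),
                         task = task_config(), coding = "signed",
                         n_blocks = NULL,
                         alpha_range = c(0.1, 0.9), rho_range = c(0.1, 0.9),
                         theta_range = c(1, 20), seed = 1L) {
  set.seed(seed)
  if (!is.null(n_blocks)) task$n_blocks_per_condition <- as.integer(n_blocks)
  pars <- c("alpha_win", "alpha_loss", "rho_win", "rho_loss",
            "theta_win", "theta_loss")
  truth <- data.frame(
    alpha_win = runif(n_agents, alpha_range[1], alpha_range[2]),
    alpha_loss = runif(n_agents, alpha_range[1], alpha_range[2]),
    rho_win = runif(n_agents, rho_range[1], rho_range[2]),
    rho_loss = runif(n_agents, rho_range[1], rho_range[2]),
    theta_win = runif(n_agents, theta_range[1], theta_range[2]),
    theta_loss = runif(n_agents, theta_range[1], theta_range[2]))
  est <- truth; est[] <- NA_real_
  n_failed <- 0L
  cond <- task$conditions[1]
  for (i in seq_len(n_agents)) {
    p <- do.call(rw_params, as.list(truth[i, ]))
    sched <- build_schedule(task, seed = child_seed(seed, 2L * i))
    sched <- sched[sched$condition == cond, , drop = FALSE]
    sim <- simulate_agent(p, sched, task, coding = coding,
                          seed = child_seed(seed, 2L * i + 1L))
    fit <- fit_participant_condition(sim, coding, fit_cfg,
                                     seed = child_seed(seed, 100000L + i))
    if (fit$failed) { n_failed <- n_failed + 1L; next }
    est[i, ] <- as.numeric(fit$params[pars])
  }
  ok <- stats::complete.cases(est)
  summ <- do.call(rbind, lapply(pars, function(pn) {
    tr <- truth[[pn]][ok]; es <- est[[pn]][ok]
    data.frame(parameter = pn,
               pearson = stats::cor(tr, es),
               spearman = stats::cor(tr, es, method = "spearman"),
               bias = mean(es - tr),
               rmse = sqrt(mean((es - tr)^2)),
               n = sum(ok), stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, truth = truth, estimates = est,
                 n_failed = n_failed),
            class = "recovery_report")
}

#' Posterior-predictive learning curves
#'
#' Forward-simulates each fitted participant-by-condition parameter set
#' `n_sims` times on fresh schedules (fresh feedback randomness, not the
#' observed sequence) and averages predicted accuracy per condition and
#' cycle, paired with the observed cohort curve and a Monte-Carlo band.
#'
#' @param trials observed/simulated trial table.
#' @param param_table fitted parameter table ([fit_cohort()] dialect).
#' @param task the [task_config()].
#' @param n_sims forward simulations per participant-condition.
#' @param coding outcome coding.
#' @param seed integer seed.
#' @return data.frame `condition`, `cycle`, `observed`, `predicted`,
#'   `pred_low`, `pred_high` (2.5% and 97.5% Monte-Carlo quantiles of the
#'   per-simulation cohort means).
#' @export
predictive_curves <- function(trials, param_table, task = task_config(),
                              n_sims = 20L, coding = "signed", seed = 1L) {
  set.seed(seed)
  obs <- aggregate_accuracy(trials)
  obs_mean <- aggregate(list(observed = obs$accuracy),
                        by = list(condition = obs$condition,
                                  cycle = obs$cycle), FUN = mean)
  n_cycles <- task$n_blocks_per_condition * task$cycles_per_block
  ids <- unique(param_table$participant_id)
  have <- table(param_table$participant_id)
  miss <- sum(have < 2L)
  if (miss > 0L) message("predictive_curves: skipping ", miss,
                         " participant(s) without fits for both conditions")
  pred <- list()
  for (cond in task$conditions) {
    # sims x cycles matrix of cohort-mean predicted accuracy
    acc <- matrix(NA_real_, n_sims, n_cycles)
    for (s in seq_len(n_sims)) {
      per_part <- matrix(NA_real_, length(ids), n_cycles)
      for (j in seq_along(ids)) {
        row <- param_table[param_table$participant_id == ids[j] &
                             param_table$condition == cond, , drop = FALSE]
        if (nrow(row) != 1L) next
        p <- rw_params(row$alpha_win, row$alpha_loss, row$rho_win,
                       row$rho_loss, row$theta_win, row$theta_loss)
        sched <- build_schedule(task)
        sched <- sched[sched$condition == cond, , drop = FALSE]
        sim <- simulate_agent(p, sched, task, coding = coding)
        per_part[j, ] <- tapply(as.numeric(sim$is_correct), sim$cycle, mean)
      }
      acc[s, ] <- colMeans(per_part, na.rm = TRUE)
    }
    pred[[cond]] <- data.frame(
      condition = cond, cycle = seq_len(n_cycles),
      predicted = colMeans(acc),
      pred_low = apply(acc, 2, quantile, 0.025),
      pred_high = apply(acc, 2, quantile, 0.975),
      stringsAsFactors = FALSE)
  }
  out <- merge(obs_mean, do.call(rbind, pred), by = c("condition", "cycle"))
  out <- out[order(out$condition, out$cycle), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("condition", "cycle", "observed", "predicted", "pred_low",
          "pred_high")]
}

#' Likelihood profile over the loss reward sensitivity
#'
#' Finite-grid profile of the negative log-likelihood over `rho_loss`, all
#' other parameters held fixed. Under literal 0/1 outcome coding a
#' non-reward contributes `-p` to the prediction error regardless of
#' `rho_loss`, so the profile is exactly flat -- the parameter is not
#' identifiable from data coded that way. Under signed coding the loss
#' outcome is scaled by `-rho_loss` and the profile curves.
#'
#' @param params baseline [rw_params()].
#' @param events one participant-by-condition event sequence.
#' @param coding outcome coding.
#' @param grid rho_loss values to profile over.
#' @return list of class `identifiability_probe`: `grid`, `nll`, `range`
#'   (max - min), `flat` (`range < 1e-10`).
#' @export
identifiability_probe <- function(params, events,
                                  coding = c("literal", "signed"),
                                  grid = seq(0.05, 0.95, by = 0.05)) {
  coding <- match.arg(coding)
  nll <- vapply(grid, function(r) {
    p <- params
    p[["rho_loss"]] <- r
    negative_log_likelihood(p, events, coding)
  }, numeric(1))
  rng <- max(nll) - min(nll)
  structure(list(grid = grid, nll = nll, range = rng, flat = rng < 1e-10),
            class = "identifiability_probe")
}
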