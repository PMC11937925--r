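#' Fitting configuration
#'
#' Settings for penalized maximum-likelihood estimation: elastic-net
#' strengths (L1 and L2, both 0.01 by default, acting on the raw
#' logistic-scale alpha/rho components), the number of random restarts of
#' the bounded optimizer, and its convergence tolerance.
#'
#' @param lambda_l1,lambda_l2 penalty strengths, `>= 0`.
#' @param n_restarts random box-uniform starts per fit, `>= 1`.
#' @param tolerance relative convergence tolerance passed to the optimizer.
#' @param seed optional integer seed for the restart draws.
#' @return a `fit_config` list.
#' @export
fit_config <- function(lambda_l1 = 0.01, lambda_l2 = 0.01, n_restarts = 10L,
                       tolerance = 1e-8, seed = NULL) {
  if (lambda_l1 < 0 || lambda_l2 < 0)
    stop("fit_config: penalties must be >= 0", call. = FALSE)
  if (n_restarts < 1L) stop("fit_config: `n_restarts` must be >= 1", call. = FALSE)
  structure(list(lambda_l1 = lambda_l1, lambda_l2 = lambda_l2,
                 n_restarts = as.integer(n_restarts), tolerance = tolerance,
                 seed = seed),
            class = "fit_config")
}

# optimizer boxes: raw alpha/rho in [-10, 10], theta in [1, 50]
raw_lower <- c(rep(-10, 4), 1, 1)
raw_upper <- c(rep(10, 4), 50, 50)
raw_names <- c("raw_alpha_win", "raw_alpha_loss", "raw_rho_win",
               "raw_rho_loss", "theta_win", "theta_loss")

#' Map raw optimizer parameters to the constrained scale
#'
#' Alpha and rho are estimated on an unconstrained logistic scale (box
#' \[-10, 10\]) and mapped into (0,1) by the logistic function; theta is
#' estimated directly on its \[1, 50\] box with no transformation.
#'
#' @param raw numeric vector of length 6: `raw_alpha_win`, `raw_alpha_loss`,
#'   `raw_rho_win`, `raw_rho_loss`, `theta_win`, `theta_loss`.
#' @return an [rw_params()] vector.
#' @export
to_constrained <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) != 6L) stop("to_constrained: expected 6 values", call. = FALSE)
  if (any(raw < raw_lower - 1e-9) || any(raw > raw_upper + 1e-9))
    stop("to_constrained: raw parameters outside their boxes", call. = FALSE)
  rw_params(alpha_win = plogis(raw[1]), alpha_loss = plogis(raw[2]),
            rho_win = plogis(raw[3]), rho_loss = plogis(raw[4]),
            theta_win = raw[5], theta_loss = raw[6])
}

#' Penalized fitting objective
#'
#' Negative log-likelihood at the constrained parameters plus the
#' elastic-net penalty `lambda_l1 * sum|raw| + lambda_l2 * sum raw^2` over
#' the four raw alpha/rho components. Theta is not penalized: it is
#' untransformed and its box excludes zero, so shrinkage toward zero would
#' be ill-posed. Shrinkage therefore pulls alpha and rho toward the neutral
#' midpoint 0.5.
#'
#' @param raw length-6 raw parameter vector (see [to_constrained()]).
#' @param events one participant-by-condition event sequence.
#' @param coding outcome coding.
#' @param config a [fit_config()].
#' @return scalar objective value.
#' @export
penalized_objective <- function(raw, events, coding = "signed",
                                config = fit_config()) {
  ar <- raw[1:4]
  negative_log_likelihood(to_constrained(raw), events, coding) +
    config$lambda_l1 * sum(abs(ar)) + config$lambda_l2 * sum(ar^2)
}

#' Fit one participant-by-condition sequence
#'
#' Penalized maximum likelihood by bounded quasi-Newton minimization
#' (`optim`, L-BFGS-B) from `n_restarts` random box-uniform start points.
#' The best converged restart wins; if every restart errors the function
#' returns a failure record rather than raising, so cohort fitting never
#' aborts.
#'
#' @param events data.frame of events for one participant and condition,
#'   with at least 8 rows.
#' @param coding outcome coding.
#' @param config a [fit_config()].
#' @param seed optional integer seed overriding `config$seed`.
#' @return list of class `rw_fit`: `params` (constrained [rw_params()]),
#'   `raw`, `objective` (penalized), `nll` (unpenalized), `converged`,
#'   `best_restart`, `n_events`, `failed`.
#' @export
fit_participant_condition <- function(events, coding = "signed",
                                      config = fit_config(), seed = NULL) {
  if (nrow(events) < 8L)
    stop("fit_participant_condition: need >= 8 events, got ", nrow(events),
         call. = FALSE)
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  starts <- matrix(runif(6L * config$n_restarts, raw_lower, raw_upper),
                   ncol = config$n_restarts)

  # precompute the integer encoding once; the objective closure is the hot path
  enc <- encode_events(events)
  signed <- identical(coding, "signed")
  l1 <- config$lambda_l1; l2 <- config$lambda_l2
  obj <- function(raw) {
    par <- c(plogis(raw[1:4]), raw[5:6])
    rw_forward_cpp(enc$stim, enc$choice_a, enc$reward, enc$n_stim, par,
                   signed)$nll +
      l1 * sum(abs(raw[1:4])) + l2 * sum(raw[1:4]^2)
  }

  best <- NULL
  best_i <- NA_integer_
  for (i in seq_len(config$n_restarts)) {
    res <- tryCatch(
      optim(starts[, i], obj, method = "L-BFGS-B",
            lower = raw_lower, upper = raw_upper,
            control = list(factr = config$tolerance / .Machine$double.eps,
                           maxit = 500L)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) { best <- res; best_i <- i }
  }
  if (is.null(best))
    return(structure(list(params = NULL, raw = NULL, objective = NA_real_,
                          nll = NA_real_, converged = FALSE,
                          best_restart = NA_integer_, n_events = nrow(events),
                          failed = TRUE),
                     class = "rw_fit"))
  raw <- setNames(best$par, raw_names)
  params <- to_constrained(raw)
  structure(list(params = params, raw = raw, objective = best$value,
                 nll = negative_log_likelihood(params, events, coding),
                 converged = best$convergence == 0L, best_restart = best_i,
                 n_events = nrow(events), failed = FALSE),
            class = "rw_fit")
}

#' Fit every participant-by-condition sequence of a trial dataset
#'
#' Splits the long-format trial table by participant and condition, fits
#' each sequence with [fit_participant_condition()], and assembles the
#' parameter table consumed by the group-level analyses (six constrained
#' parameters per row, two rows per participant). Participants missing a
#' condition are reported and skipped.
#'
#' @param trials long-format trial data.frame (the [generate_dataset()]
#'   dialect): `participant_id`, `condition`, `cycle`, `stimulus_id`,
#'   `choice`, `feedback`.
#' @param coding outcome coding.
#' @param config a [fit_config()].
#' @param seed optional integer seed; each sequence gets a [child_seed()].
#' @return data.frame with columns `participant_id`, `condition`,
#'   `alpha_win`, `alpha_loss`, `rho_win`, `rho_loss`, `theta_win`,
#'   `theta_loss`, `nll`, `penalized_obj`, `converged`, `n_events`.
#' @export
fit_cohort <- function(trials, coding = "signed", config = fit_config(),
                       seed = NULL) {
  cols <- c("participant_id", "condition", "alpha_win", "alpha_loss",
            "rho_win", "rho_loss", "theta_win", "theta_loss", "nll",
            "penalized_obj", "converged", "n_events")
  if (nrow(trials) == 0L) {
    warning("fit_cohort: empty trial table, returning empty parameter table")
    out <- data.frame(participant_id = character(), condition = character(),
                      alpha_win = numeric(), alpha_loss = numeric(),
                      rho_win = numeric(), rho_loss = numeric(),
                      theta_win = numeric(), theta_loss = numeric(),
                      nll = numeric(), penalized_obj = numeric(),
                      converged = logical(), n_events = integer(),
                      stringsAsFactors = FALSE)
    return(out[, cols])
  }
  conds <- unique(trials$condition)
  ids <- unique(trials$participant_id)
  have_both <- vapply(ids, function(id) {
    length(unique(trials$condition[trials$participant_id == id])) ==
      length(conds)
  }, logical(1))
  if (any(!have_both))
    warning("fit_cohort: skipping participants missing a condition: ",
            paste(ids[!have_both], collapse = ", "))
  ids <- ids[have_both]

  rows <- list()
  k <- 0L
  for (id in ids) {
    for (cond in conds) {
      k <- k + 1L
      ev <- trials[trials$participant_id == id & trials$condition == cond, ,
                   drop = FALSE]
      ev <- ev[order(ev$cycle, ev$position), , drop = FALSE]
      fit <- fit_participant_condition(
        ev, coding, config,
        seed = if (!is.null(seed)) child_seed(seed, k) else NULL)
      if (fit$failed) {
        warning("fit_cohort: all restarts failed for participant ", id,
                ", condition ", cond)
        next
      }
      rows[[k]] <- data.frame(
        participant_id = id, condition = cond, as.list(unclass(fit$params)),
        nll = fit$nll, penalized_obj = fit$objective,
        converged = fit$converged, n_events = fit$n_events,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, cols]
}
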