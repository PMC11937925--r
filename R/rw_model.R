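#' Valenced Rescorla-Wagner parameter set
#'
#' Six parameters for one participant-by-condition fit: learning rates
#' `alpha_*` and reward sensitivities `rho_*` in (0,1), softmax inverse
#' temperatures `theta_*` in \[1, 50\]. The `win` set applies on rewarded
#' events, the `loss` set on non-rewarded events of the same choice sequence.
#'
#' @param alpha_win,alpha_loss learning rates in \[0,1\].
#' @param rho_win,rho_loss reward sensitivities in \[0,1\].
#' @param theta_win,theta_loss inverse temperatures in \[1,50\].
#' @return named numeric vector of length 6, class `rw_params`.
#' @export
rw_params <- function(alpha_win, alpha_loss, rho_win, rho_loss,
                      theta_win, theta_loss) {
  p <- c(alpha_win = alpha_win, alpha_loss = alpha_loss,
         rho_win = rho_win, rho_loss = rho_loss,
         theta_win = theta_win, theta_loss = theta_loss)
  if (any(!is.finite(p)))
    stop("rw_params: all six parameters must be finite", call. = FALSE)
  ar <- p[1:4]
  if (any(ar < 0 | ar > 1))
    stop("rw_params: alpha and rho must lie in [0, 1]", call. = FALSE)
  th <- p[5:6]
  if (any(th < 1 | th > 50))
    stop("rw_params: theta must lie in [1, 50]", call. = FALSE)
  structure(p, class = "rw_params")
}

#' Reward prediction error
#'
#' `rho * outcome - p`: the discrepancy between the sensitivity-scaled
#' outcome and the current reward expectation. Under literal 0/1 coding a
#' non-reward contributes `-p` regardless of `rho` -- the root of the
#' `rho_loss` identifiability problem probed by [identifiability_probe()].
#'
#' @param rho reward sensitivity.
#' @param outcome coded outcome (+1 reward; -1 or 0 nonreward by coding).
#' @param p current expected reward probability, in \[0,1\].
#' @return the prediction error.
#' @export
prediction_error <- function(rho, outcome, p) rho * outcome - p

#' Value update
#'
#' Moves the expectation a fraction `alpha` of the prediction error, then
#' clips to \[0,1\] so the value keeps its probability reading under signed
#' outcome coding.
#'
#' @param p current value in \[0,1\].
#' @param alpha learning rate.
#' @param rpe prediction error.
#' @return updated value in \[0,1\].
#' @export
update_value <- function(p, alpha, rpe) pmin(1, pmax(0, p + alpha * rpe))

#' Softmax choice probability
#'
#' Probability of choosing option A given the two values, through a logistic
#' in `theta * (p_a - p_b)`. Overflow-safe for the full `theta` box.
#'
#' @param theta inverse temperature.
#' @param p_a,p_b option values.
#' @return probability of choosing A, in (0,1).
#' @export
choice_probability <- function(theta, p_a, p_b) plogis(theta * (p_a - p_b))

#' Initialize the learner's value state
#'
#' One value per stimulus (expected reward probability of option A,
#' initialized to the chance expectation 0.5; option B's value is its
#' complement), plus the valence of the most recent feedback, which selects
#' the inverse temperature on the next event.
#'
#' @param stimulus_ids vector of stimulus identifiers.
#' @return a `value_state` list.
#' @export
value_state <- function(stimulus_ids) {
  structure(list(p_a = setNames(rep(0.5, length(stimulus_ids)),
                                as.character(stimulus_ids)),
                 last_valence = "none"),
            class = "value_state")
}

#' One learner step (reference implementation)
#'
#' Computes the choice probability for the event, then applies the valenced
#' update to the chosen option's value: `(alpha_win, rho_win)` after
#' rewarding feedback, `(alpha_loss, rho_loss)` after non-rewarding
#' feedback. The inverse temperature is `theta_win` or `theta_loss`
#' according to the most recent feedback valence; the first event of a
#' sequence uses their mean. The compiled forward pass used by
#' [negative_log_likelihood()] and [simulate_agent()] implements the same
#' recursion; this R version is the readable single-step form.
#'
#' @param state a [value_state()].
#' @param params an [rw_params()] vector.
#' @param stimulus_id stimulus shown.
#' @param choice `"A"` or `"B"`.
#' @param feedback `"reward"` or `"nonreward"`.
#' @param coding `"signed"` (nonreward = -1, default) or `"literal"`
#'   (nonreward = 0, the printed-model form).
#' @return list with `p_choice` (probability of the observed choice before
#'   updating) and `state` (updated).
#' @export
rw_step <- function(state, params, stimulus_id, choice, feedback,
                    coding = c("signed", "literal")) {
  coding <- match.arg(coding)
  key <- as.character(stimulus_id)
  if (!key %in% names(state$p_a))
    stop("rw_step: unknown stimulus '", key, "'", call. = FALSE)
  theta <- switch(state$last_valence,
                  win = params[["theta_win"]],
                  loss = params[["theta_loss"]],
                  none = mean(c(params[["theta_win"]], params[["theta_loss"]])))
  p_a <- state$p_a[[key]]
  pr_a <- choice_probability(theta, p_a, 1 - p_a)
  p_choice <- if (choice == "A") pr_a else 1 - pr_a

  win <- feedback == "reward"
  outcome <- if (win) 1 else if (coding == "signed") -1 else 0
  alpha <- if (win) params[["alpha_win"]] else params[["alpha_loss"]]
  rho <- if (win) params[["rho_win"]] else params[["rho_loss"]]
  p_chosen <- if (choice == "A") p_a else 1 - p_a
  p_chosen <- update_value(p_chosen, alpha, prediction_error(rho, outcome, p_chosen))
  state$p_a[[key]] <- if (choice == "A") p_chosen else 1 - p_chosen
  state$last_valence <- if (win) "win" else "loss"
  list(p_choice = p_choice, state = state)
}

# Convert one condition's event rows to the integer encoding of the C++ core.
encode_events <- function(events) {
  stim_levels <- unique(as.character(events$stimulus_id))
  list(stim = match(as.character(events$stimulus_id), stim_levels) - 1L,
       choice_a = as.integer(events$choice == "A"),
       reward = as.integer(events$feedback == "reward"),
       n_stim = length(stim_levels),
       stim_levels = stim_levels)
}

#' Negative log-likelihood of observed choices
#'
#' Sum of `-log P(observed choice)` over a single participant-by-condition
#' event sequence, with values evolved exactly as in [rw_step()].
#' Accumulation uses a numerically stable log-sigmoid, so the result is
#' finite over the whole parameter box.
#'
#' @param params an [rw_params()] vector (or any named numeric with the six
#'   components).
#' @param events data.frame of events in presentation order for one
#'   participant and condition, with columns `stimulus_id`, `choice`,
#'   `feedback` (and `condition`, checked for purity when present).
#' @param coding outcome coding, `"signed"` or `"literal"`.
#' @return scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, events,
                                    coding = c("signed", "literal")) {
  coding <- match.arg(coding)
  if (!is.null(events$condition) && length(unique(events$condition)) > 1L)
    stop("negative_log_likelihood: events mix conditions; fit each ",
         "participant x condition sequence separately", call. = FALSE)
  if (!is.null(events$cycle) && is.unsorted(events$cycle))
    stop("negative_log_likelihood: events are not in presentation order ",
         "(cycle decreases at row ",
         which(diff(events$cycle) < 0)[1] + 1L, ")", call. = FALSE)
  enc <- encode_events(events)
  par <- as.numeric(params[c("alpha_win", "alpha_loss", "rho_win", "rho_loss",
                             "theta_win", "theta_loss")])
  rw_forward_cpp(enc$stim, enc$choice_a, enc$reward, enc$n_stim, par,
                 coding == "signed")$nll
}

#' Per-event model choice probabilities
#'
#' Probability the model assigns to choosing option A at each event, before
#' that event's update (one-step-ahead predictions along the observed
#' sequence).
#'
#' @inheritParams negative_log_likelihood
#' @return numeric vector, one probability per event.
#' @export
choice_probabilities <- function(params, events,
                                 coding = c("signed", "literal")) {
  coding <- match.arg(coding)
  enc <- encode_events(events)
  par <- as.numeric(params[c("alpha_win", "alpha_loss", "rho_win", "rho_loss",
                             "theta_win", "theta_loss")])
  rw_forward_cpp(enc$stim, enc$choice_a, enc$reward, enc$n_stim, par,
                 coding == "signed")$p_choice_a
}

#' Simulate an agent on a schedule
#'
#' Walks a [build_schedule()] layout, sampling choices from the softmax rule
#' and feedback from the mirrored contingency, with the valenced update
#' after every event. Both conditions of the schedule are simulated with the
#' same parameter set unless a per-condition list is given.
#'
#' @param params an [rw_params()] vector, or a named list of one such vector
#'   per condition.
#' @param schedule a [build_schedule()] data.frame.
#' @param config the [task_config()] used for the schedule (for the
#'   contingency).
#' @param coding outcome coding.
#' @param seed optional integer seed.
#' @return the schedule with `choice`, `is_correct`, `feedback` columns.
#' @export
simulate_agent <- function(params, schedule, config = task_config(),
                           coding = c("signed", "literal"), seed = NULL) {
  coding <- match.arg(coding)
  if (!is.null(seed)) set.seed(seed)
  schedule$choice <- NA_character_
  schedule$is_correct <- NA
  schedule$feedback <- NA_character_
  for (cond in unique(schedule$condition)) {
    idx <- which(schedule$condition == cond)
    ev <- schedule[idx, , drop = FALSE]
    stim_levels <- unique(as.character(ev$stimulus_id))
    stim <- match(as.character(ev$stimulus_id), stim_levels) - 1L
    corr <- ev$correct_option[match(stim_levels, as.character(ev$stimulus_id))]
    par_c <- if (is.list(params) && !inherits(params, "rw_params"))
      params[[cond]] else params
    par <- as.numeric(par_c[c("alpha_win", "alpha_loss", "rho_win",
                              "rho_loss", "theta_win", "theta_loss")])
    sim <- rw_simulate_cpp(stim, as.integer(corr == "A"),
                           config$reward_contingency,
                           length(stim_levels), par, coding == "signed")
    schedule$choice[idx] <- ifelse(sim$choice_a == 1L, "A", "B")
    schedule$is_correct[idx] <- sim$is_correct == 1L
    schedule$feedback[idx] <- ifelse(sim$reward == 1L, "reward", "nonreward")
  }
  schedule
}
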