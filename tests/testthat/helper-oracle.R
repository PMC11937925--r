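# Brute-force reference recursion for the valenced learner, written
# independently of the package's forward pass: plain lists, no log-sigmoid
# shortcut, probabilities multiplied out event by event.
oracle_nll <- function(params, events, coding = "signed") {
  vals <- list()
  last <- "none"
  total <- 0
  for (i in seq_len(nrow(events))) {
    s <- as.character(events$stimulus_id[i])
    if (is.null(vals[[s]])) vals[[s]] <- 0.5
    theta <- if (last == "none") {
      (params[["theta_win"]] + params[["theta_loss"]]) / 2
    } else if (last == "win") params[["theta_win"]] else params[["theta_loss"]]
    p_a <- vals[[s]]
    gap <- p_a - (1 - p_a)
    if (events$choice[i] == "B") gap <- -gap
    total <- total + log(1 + exp(-theta * gap))  # = -log P(observed choice)

    won <- events$feedback[i] == "reward"
    outc <- if (won) 1 else if (coding == "signed") -1 else 0
    a <- if (won) params[["alpha_win"]] else params[["alpha_loss"]]
    r <- if (won) params[["rho_win"]] else params[["rho_loss"]]
    pc <- if (events$choice[i] == "A") p_a else 1 - p_a
    pc <- pc + a * (r * outc - pc)
    pc <- min(1, max(0, pc))
    vals[[s]] <- if (events$choice[i] == "A") pc else 1 - pc
    last <- if (won) "win" else "loss"
  }
  total
}

# Assemble a minimal single-condition event table from parallel vectors.
make_events <- function(stimulus, choice, feedback, condition = "social") {
  data.frame(stimulus_id = stimulus, choice = choice, feedback = feedback,
             condition = condition, cycle = seq_along(stimulus),
             stringsAsFactors = FALSE)
}
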