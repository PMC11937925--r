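#' Task configuration
#'
#' Describes the probabilistic categorization task: two interleaved block
#' types (social feedback from point-light faces, non-social feedback from
#' check/cross symbols), each condition contributing two blocks of six trial
#' cycles over four two-digit number stimuli. A "cycle" is one pass over a
#' condition's four stimuli (the task's trial counter, 1--12 across the two
#' blocks of a condition); an "event" is a single stimulus presentation.
#'
#' @param n_blocks_per_condition blocks per condition (default 2).
#' @param cycles_per_block trial cycles per block (default 6).
#' @param stimuli_per_condition unique stimuli per condition (default 4).
#' @param reward_contingency probability that a correct response receives
#'   rewarding feedback (default 0.85). Incorrect responses are rewarded
#'   with the mirrored probability `1 - reward_contingency`.
#' @param conditions labels for the two block types; the first is non-social
#'   by convention (reference level downstream).
#' @param parity named mapping from condition to the parity ("even"/"odd")
#'   of its two-digit stimulus numbers.
#' @return a `task_config` list.
#' @export
task_config <- function(n_blocks_per_condition = 2L,
                        cycles_per_block = 6L,
                        stimuli_per_condition = 4L,
                        reward_contingency = 0.85,
                        conditions = c("nonsocial", "social"),
                        parity = c(social = "even", nonsocial = "odd")) {
  cfg <- list(
    n_blocks_per_condition = as.integer(n_blocks_per_condition),
    cycles_per_block = as.integer(cycles_per_block),
    stimuli_per_condition = as.integer(stimuli_per_condition),
    reward_contingency = reward_contingency,
    conditions = conditions,
    parity = parity
  )
  validate_task_config(cfg)
  structure(cfg, class = "task_config")
}

validate_task_config <- function(cfg) {
  if (!(cfg$reward_contingency > 0.5 && cfg$reward_contingency <= 1))
    stop("task_config: `reward_contingency` must lie in (0.5, 1], got ",
         cfg$reward_contingency, call. = FALSE)
  for (f in c("n_blocks_per_condition", "cycles_per_block",
              "stimuli_per_condition"))
    if (cfg[[f]] < 1L) stop("task_config: `", f, "` must be >= 1", call. = FALSE)
  if (length(cfg$conditions) != 2L || anyDuplicated(cfg$conditions))
    stop("task_config: `conditions` must be two distinct labels", call. = FALSE)
  if (!all(sort(names(cfg$parity)) == sort(cfg$conditions)) ||
      !all(cfg$parity %in% c("even", "odd")))
    stop("task_config: `parity` must map each condition to 'even' or 'odd'",
         call. = FALSE)
  n_avail <- 45L  # two-digit integers 10..99 of each parity
  if (cfg$stimuli_per_condition > n_avail)
    stop("task_config: `stimuli_per_condition` exceeds the ", n_avail,
         " available two-digit numbers per parity class", call. = FALSE)
  invisible(cfg)
}

#' Assign two-digit stimulus numbers to conditions
#'
#' Stimulus numbers are drawn without replacement from the two-digit range
#' 10--99, even numbers going to social blocks and odd numbers to non-social
#' blocks (so number identity cannot carry over between conditions). Each
#' stimulus is randomly assigned a high-probability ("correct") option.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return data.frame with `stimulus_id`, `condition`, `correct_option`.
#' @export
assign_stimuli <- function(config = task_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- list(even = seq(10L, 98L, by = 2L), odd = seq(11L, 99L, by = 2L))
  out <- lapply(config$conditions, function(cond) {
    ids <- sample(pool[[config$parity[[cond]]]], config$stimuli_per_condition)
    data.frame(stimulus_id = ids, condition = cond,
               correct_option = sample(c("A", "B"), length(ids), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build the presentation schedule
#'
#' Lays out the full interleaved schedule: the starting block type is chosen
#' at random and block types alternate thereafter; within every cycle each of
#' that condition's stimuli appears exactly once in random order; the screen
#' side of option A is re-randomized per event. Cycles are numbered
#' continuously across a condition's blocks (1..12 by default). No choices
#' or feedback yet -- those are produced by [simulate_agent()] or a real
#' participant.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed (covers the stimulus assignment too when
#'   `assignments` is not supplied).
#' @param assignments optional stimulus table from [assign_stimuli()].
#' @return data.frame of presentation slots: `condition`, `block`
#'   (1-based within condition), `cycle`, `position` (1..stimuli_per_condition
#'   within the cycle), `stimulus_id`, `left_option`, `right_option`,
#'   `correct_option`.
#' @export
build_schedule <- function(config = task_config(), seed = NULL,
                           assignments = NULL) {
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(assignments)) assignments <- assign_stimuli(config)

  first <- sample(config$conditions, 1L)
  other <- setdiff(config$conditions, first)
  block_types <- rep(c(first, other), config$n_blocks_per_condition)

  block_counter <- setNames(c(0L, 0L), config$conditions)
  rows <- vector("list", length(block_types))
  for (b in seq_along(block_types)) {
    cond <- block_types[b]
    block_counter[cond] <- block_counter[cond] + 1L
    stim <- assignments[assignments$condition == cond, , drop = FALSE]
    per_block <- lapply(seq_len(config$cycles_per_block), function(cy) {
      ord <- sample(nrow(stim))
      cycle <- (block_counter[[cond]] - 1L) * config$cycles_per_block + cy
      a_left <- sample(c(TRUE, FALSE), nrow(stim), replace = TRUE)
      data.frame(condition = cond,
                 block = block_counter[[cond]],
                 cycle = cycle,
                 position = seq_len(nrow(stim)),
                 stimulus_id = stim$stimulus_id[ord],
                 left_option = ifelse(a_left, "A", "B"),
                 right_option = ifelse(a_left, "B", "A"),
                 correct_option = stim$correct_option[ord],
                 stringsAsFactors = FALSE)
    })
    rows[[b]] <- do.call(rbind, per_block)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample probabilistic feedback
#'
#' Correct responses are rewarded with probability `contingency`; incorrect
#' responses with the mirrored probability `1 - contingency`.
#'
#' @param is_correct logical vector.
#' @param contingency reward probability for correct responses, in `[0, 1]`.
#' @return character vector, `"reward"` or `"nonreward"`.
#' @export
sample_feedback <- function(is_correct, contingency = 0.85) {
  if (!is.numeric(contingency) || contingency < 0 || contingency > 1)
    stop("sample_feedback: `contingency` must lie in [0, 1], got ",
         contingency, call. = FALSE)
  p <- ifelse(is_correct, contingency, 1 - contingency)
  ifelse(runif(length(is_correct)) < p, "reward", "nonreward")
}
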