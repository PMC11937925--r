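# Shared fixtures, built once per test run. Kept small so single fits stay
# in the sub-second range and the cohort fit in the tens of seconds.
.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_dataset(cohort_config(n_participants = 16L,
                                                       seed = 2024L))
  .fixtures$cohort
}

small_param_table <- function() {
  if (is.null(.fixtures$params))
    .fixtures$params <- fit_cohort(small_cohort()$trials,
                                   config = fit_config(n_restarts = 5L),
                                   seed = 7L)
  .fixtures$params
}

# Ground-truth parameter table in the fit_cohort dialect, drawn straight
# from the generative model (no trial simulation, no fitting) -- used for
# the statistical operating-characteristic simulations.
truth_param_table <- function(config, seed) {
  aq <- sample_aq(config$n_participants, config$aq,
                  seed = child_seed(seed, 0L))
  aq_c <- aq - mean(aq)
  ids <- sprintf("P%03d", seq_len(config$n_participants))
  rows <- lapply(seq_along(ids), function(i) {
    ps <- sample_parameters(aq_c[i], config, seed = child_seed(seed, i))
    do.call(rbind, lapply(names(ps), function(cond)
      data.frame(participant_id = ids[i], condition = cond,
                 as.list(unclass(ps[[cond]])), stringsAsFactors = FALSE)))
  })
  list(params = do.call(rbind, rows),
       aq = data.frame(participant_id = ids, aq_score = aq,
                       stringsAsFactors = FALSE))
}

default_rw_params <- function() rw_params(0.5, 0.3, 0.8, 0.5, 10, 5)
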