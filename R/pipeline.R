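#' Validate a trial/AQ dataset pair
#'
#' Structural checks on the long-format trial table and the AQ table:
#' required columns, condition and choice labels, cycle range, AQ bounds
#' (0--33), and participant consistency across the two files. Every
#' violation is returned as one row with the offending location.
#'
#' @param trials trial data.frame or path to a trials CSV.
#' @param aq_table AQ data.frame or path to an AQ CSV.
#' @param task the [task_config()] the data should conform to.
#' @return data.frame `row` (row number in the offending file, NA for
#'   file-level problems), `field`, `message`; zero rows when clean.
#' @export
validate_dataset <- function(trials, aq_table, task = task_config()) {
  if (is.character(trials)) trials <- read_csv_utf8(trials)
  if (is.character(aq_table)) aq_table <- read_csv_utf8(aq_table)
  bad <- list()
  flag <- function(row, field, msg)
    bad[[length(bad) + 1L]] <<- data.frame(row = row, field = field,
                                           message = msg,
                                           stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "block", "cycle", "position",
            "stimulus_id", "left_option", "right_option", "choice",
            "is_correct", "feedback")
  for (col in setdiff(need, names(trials)))
    flag(NA_integer_, col, "missing column in trial table")
  if (length(bad) == 0L) {
    n_cycles <- task$n_blocks_per_condition * task$cycles_per_block
    r <- which(!trials$condition %in% task$conditions)
    for (i in head(r, 50)) flag(i, "condition",
                                paste0("unknown label '", trials$condition[i], "'"))
    r <- which(trials$cycle < 1 | trials$cycle > n_cycles)
    for (i in head(r, 50)) flag(i, "cycle",
                                paste0("cycle ", trials$cycle[i],
                                       " outside 1..", n_cycles))
    r <- which(!trials$choice %in% c("A", "B"))
    for (i in head(r, 50)) flag(i, "choice",
                                paste0("choice '", trials$choice[i],
                                       "' not in {A, B}"))
    r <- which(!trials$feedback %in% c("reward", "nonreward"))
    for (i in head(r, 50)) flag(i, "feedback", "unknown feedback label")
  }
  for (col in setdiff(c("participant_id", "aq_score"), names(aq_table)))
    flag(NA_integer_, col, "missing column in AQ table")
  if ("aq_score" %in% names(aq_table)) {
    r <- which(aq_table$aq_score < 0 | aq_table$aq_score > 33)
    for (i in r) flag(i, "aq_score",
                      paste0("AQ ", aq_table$aq_score[i], " outside 0..33",
                             " (participant ", aq_table$participant_id[i], ")"))
  }
  if ("participant_id" %in% names(trials) &&
      "participant_id" %in% names(aq_table)) {
    orphans <- setdiff(unique(trials$participant_id), aq_table$participant_id)
    for (id in orphans) flag(NA_integer_, "participant_id",
                             paste0("participant ", id, " has trials but no AQ"))
  }
  if (length(bad) == 0L)
    return(data.frame(row = integer(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulation, model fitting, behavioural analysis, parameter-level
#' analysis and predictive validation, end to end, writing every table plus
#' a machine-readable run manifest under `out_dir`. Stages fan their
#' randomness out from the single global seed via [child_seed()]. Intended
#' as the programmatic equivalent of running the `analysis/` scripts in
#' order (at configurable scale).
#'
#' @param config a [cohort_config()] (its `seed` is the global seed).
#' @param out_dir output directory.
#' @param fit_cfg a [fit_config()].
#' @param n_perm,n_boot resampling sizes for the robustness checks.
#' @param resampling_engine `"mixed"` or `"fixed"` (see
#'   [permutation_test_aq()]).
#' @param stages character subset of
#'   `c("simulate", "fit", "behavior", "parameters", "validate")`.
#' @return (invisibly) a list with every stage's result plus `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = "results",
                         fit_cfg = fit_config(),
                         n_perm = 199L, n_boot = 199L,
                         resampling_engine = "fixed",
                         stages = c("simulate", "fit", "behavior",
                                    "parameters", "validate")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if ("simulate" %in% stages) {
    res$data <- stage("simulate", generate_dataset(config, dir = out_dir))
    stopifnot(nrow(validate_dataset(res$data$trials, res$data$aq,
                                    config$task)) == 0L)
  }
  if ("fit" %in% stages) {
    res$params <- stage("fit", fit_cohort(res$data$trials,
                                          config = fit_cfg,
                                          seed = child_seed(config$seed, 1000L)))
    write_csv_utf8(res$params, file.path(out_dir, "parameters.csv"))
  }
  if ("behavior" %in% stages) {
    res$accuracy <- stage("behavior",
                          aggregate_accuracy(res$data$trials))
    res$glmm <- stage("behavior",
                      fit_learning_model(res$data$trials, res$data$aq))
    res$lr_test <- stage("behavior",
                         random_slope_lr_test(res$data$trials, res$data$aq))
    write_csv_utf8(res$accuracy, file.path(out_dir, "accuracy.csv"))
    write_csv_utf8(res$glmm$fixed, file.path(out_dir, "glmm_fixed.csv"))
  }
  if ("parameters" %in% stages) {
    res$wilcoxon <- stage("parameters", wilcoxon_win_vs_loss(res$params))
    res$beta_rho_win <- stage("parameters",
                              fit_beta_mixed(res$params, res$data$aq, "rho_win"))
    res$lmm_theta_loss <- stage("parameters",
                                fit_lmm_theta(res$params, res$data$aq,
                                              "theta_loss"))
    res$slopes_rho_win <- stage("parameters",
                                simple_slopes(res$params, res$data$aq,
                                              "rho_win"))
    res$perm_rho_win <- stage("parameters",
                              permutation_test_aq(res$params, res$data$aq,
                                                  "rho_win", n_perm = n_perm,
                                                  seed = child_seed(config$seed, 2000L),
                                                  engine = resampling_engine))
    res$boot_rho_win <- stage("parameters",
                              bootstrap_aq(res$params, res$data$aq, "rho_win",
                                           n_boot = n_boot,
                                           seed = child_seed(config$seed, 3000L),
                                           engine = resampling_engine))
    write_csv_utf8(res$wilcoxon, file.path(out_dir, "wilcoxon.csv"))
    write_csv_utf8(res$beta_rho_win$fixed,
                   file.path(out_dir, "beta_rho_win.csv"))
    write_csv_utf8(res$lmm_theta_loss$fixed,
                   file.path(out_dir, "lmm_theta_loss.csv"))
  }
  if ("validate" %in% stages) {
    res$curves <- stage("validate",
                        predictive_curves(res$data$trials, res$params,
                                          config$task,
                                          seed = child_seed(config$seed, 4000L)))
    write_csv_utf8(res$curves, file.path(out_dir, "predictive_curves.csv"))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("rwvalence")),
                   seed = config$seed, n_participants = config$n_participants,
                   stages = stages, timestamp = format(Sys.time(), tz = "UTC"))
  res$manifest <- manifest
  writeLines(paste(names(manifest),
                   vapply(manifest, function(x) paste(x, collapse = ","), ""),
                   sep = ": "),
             file.path(out_dir, "manifest.txt"))
  invisible(res)
}
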