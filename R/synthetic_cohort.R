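#' AQ score generator settings
#'
#' The autism-spectrum-quotient short form used here has 33 binary-scored
#' items (score range 0--33). Synthetic scores are drawn from a
#' beta-binomial whose two shape parameters are solved by moment matching
#' to the target mean and standard deviation; the right skew of the
#' empirical distribution then emerges from the mean sitting well below the
#' scale midpoint (it is reported, not forced).
#'
#' @param n_items number of items (default 33).
#' @param mean,sd target moments (defaults 9.45 and 4.88, the calibration
#'   sample's descriptives).
#' @return an `aq_model` list with the solved shapes `a`, `b`.
#' @export
aq_model <- function(n_items = 33L, mean = 9.45, sd = 4.88) {
  n <- as.integer(n_items)
  if (mean <= 0 || mean >= n)
    stop("aq_model: target mean must lie strictly inside (0, n_items)",
         call. = FALSE)
  p <- mean / n
  v_binom <- n * p * (1 - p)
  if (sd^2 <= v_binom)
    stop("aq_model: target sd implies underdispersion relative to a ",
         "binomial; a beta-binomial cannot match it", call. = FALSE)
  icc <- (sd^2 / v_binom - 1) / (n - 1)
  if (icc >= 1)
    stop("aq_model: target sd too large for a 0-", n, " score", call. = FALSE)
  s <- 1 / icc - 1  # a + b
  structure(list(n_items = n, mean = mean, sd = sd, a = p * s, b = (1 - p) * s),
            class = "aq_model")
}

#' Draw synthetic AQ scores
#'
#' Beta-binomial sampling: an item-endorsement propensity per participant
#' from the moment-matched beta, then 33 binary items. `sd = 0` is allowed
#' as a degenerate case (every score equals the rounded mean).
#'
#' @param n number of scores.
#' @param model an [aq_model()] (or a list with `sd = 0` plus `mean`,
#'   `n_items` for the degenerate case).
#' @param seed optional integer seed.
#' @return integer vector of scores in `[0, n_items]`.
#' @export
sample_aq <- function(n, model = aq_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(model$sd) && model$sd == 0)
    return(rep(as.integer(round(model$mean)), n))
  theta <- rbeta(n, model$a, model$b)
  rbinom(n, model$n_items, theta)
}

#' Cohort generator settings
#'
#' Population-level generative model for a synthetic study cohort. Raw-scale
#' (logistic) alpha/rho locations and spreads, theta locations and spreads
#' on the natural scale (truncated to \[1, 50\]), and the AQ linkage: a
#' slope of grand-mean-centred AQ on raw `rho_win` (negative by default:
#' higher autistic traits, lower win reward sensitivity) and on `theta_loss`
#' (positive by default: higher traits, more deterministic behaviour after
#' losses). `condition_sd`/`condition_sd_theta` add a small per-condition
#' jitter around each participant's parameter location so the two condition
#' rows per participant differ, as fitted parameter tables do; no
#' condition-specific AQ slopes exist by default (no AQ-by-condition
#' interaction in truth). `condition_offset` shifts the raw location of the
#' second (social) condition for power experiments.
#'
#' @param n_participants cohort size (default 63, the calibration sample).
#' @param aq an [aq_model()].
#' @param task a [task_config()].
#' @param location,spread named numeric: raw-scale population location and
#'   between-participant sd per parameter (theta entries on the theta
#'   scale).
#' @param condition_sd,condition_sd_theta within-participant, between-
#'   condition sd on the raw / theta scales.
#' @param slope_rho_win AQ slope (per centred AQ point) on raw `rho_win`.
#' @param slope_theta_loss AQ slope (per centred AQ point) on `theta_loss`.
#' @param condition_offset raw-scale additive shift for the social
#'   condition's alpha/rho (default 0).
#' @param seed integer seed for [generate_dataset()].
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 63L,
                          aq = aq_model(),
                          task = task_config(),
                          location = c(alpha_win = -0.5, alpha_loss = -1.0,
                                       rho_win = 1.0, rho_loss = 0.0,
                                       theta_win = 7, theta_loss = 5),
                          spread = c(alpha_win = 0.8, alpha_loss = 0.8,
                                     rho_win = 0.8, rho_loss = 0.8,
                                     theta_win = 3, theta_loss = 3),
                          condition_sd = 0.3,
                          condition_sd_theta = 1,
                          slope_rho_win = -0.08,
                          slope_theta_loss = 0.15,
                          condition_offset = 0,
                          seed = 1L) {
  if (n_participants < 2L)
    stop("cohort_config: need at least 2 participants", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants), aq = aq,
                 task = task, location = location, spread = spread,
                 condition_sd = condition_sd,
                 condition_sd_theta = condition_sd_theta,
                 slope_rho_win = slope_rho_win,
                 slope_theta_loss = slope_theta_loss,
                 condition_offset = condition_offset, seed = seed),
            class = "cohort_config")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  pmin(upper, pmax(lower, rnorm(n, mean, sd)))
}

#' Draw a participant's ground-truth parameters, per condition
#'
#' Raw alpha/rho: population location plus the AQ effect (for `rho_win`)
#' plus a participant-level normal deviate, with an independent
#' per-condition jitter; mapped through the logistic. Theta: the same
#' hierarchy on the natural scale, truncated to \[1, 50\], with the AQ
#' effect on `theta_loss`.
#'
#' @param aq_centred the participant's grand-mean-centred AQ score.
#' @param config a [cohort_config()].
#' @param seed optional integer seed.
#' @return named list of one [rw_params()] per condition.
#' @export
sample_parameters <- function(aq_centred, config = cohort_config(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loc <- config$location
  loc["rho_win"] <- loc["rho_win"] + config$slope_rho_win * aq_centred
  loc["theta_loss"] <- loc["theta_loss"] + config$slope_theta_loss * aq_centred
  ar <- c("alpha_win", "alpha_loss", "rho_win", "rho_loss")
  th <- c("theta_win", "theta_loss")
  person_ar <- loc[ar] + rnorm(4, 0, config$spread[ar])
  person_th <- loc[th] + rnorm(2, 0, config$spread[th])
  out <- lapply(seq_along(config$task$conditions), function(i) {
    raw_ar <- person_ar + rnorm(4, 0, config$condition_sd) +
      if (i == 2L) config$condition_offset else 0
    raw_ar <- pmin(10, pmax(-10, raw_ar))
    theta <- rtrunc_norm(2, person_th, config$condition_sd_theta, 1, 50)
    rw_params(alpha_win = plogis(raw_ar[[1]]), alpha_loss = plogis(raw_ar[[2]]),
              rho_win = plogis(raw_ar[[3]]), rho_loss = plogis(raw_ar[[4]]),
              theta_win = theta[[1]], theta_loss = theta[[2]])
  })
  setNames(out, config$task$conditions)
}

#' Generate a full synthetic cohort dataset
#'
#' For each participant: an AQ score, ground-truth valenced parameters with
#' the configured AQ linkage, a fresh task schedule, and simulated choices
#' with probabilistic feedback. Everything is reproducible from
#' `config$seed` via per-participant child seeds.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory; when given, writes `trials.csv`,
#'   `aq.csv` and `truth.csv` there.
#' @param coding outcome coding for the simulated learners.
#' @return list with `trials` (long-format event table), `aq`
#'   (`participant_id`, `aq_score`), `truth` (one row per participant by
#'   condition, `true_`-prefixed parameters), and `config`.
#' @export
generate_dataset <- function(config = cohort_config(), dir = NULL,
                             coding = "signed") {
  n <- config$n_participants
  aq_scores <- sample_aq(n, config$aq, seed = child_seed(config$seed, 0L))
  aq_centred <- aq_scores - mean(aq_scores)
  ids <- sprintf("P%03d", seq_len(n))

  trials <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    params <- sample_parameters(aq_centred[i], config,
                                seed = child_seed(config$seed, 3L * i - 2L))
    sched <- build_schedule(config$task,
                            seed = child_seed(config$seed, 3L * i - 1L))
    sim <- simulate_agent(params, sched, config$task, coding = coding,
                          seed = child_seed(config$seed, 3L * i))
    sim <- cbind(participant_id = ids[i], sim, stringsAsFactors = FALSE)
    trials[[i]] <- sim
    truth[[i]] <- do.call(rbind, lapply(names(params), function(cond) {
      p <- params[[cond]]
      data.frame(participant_id = ids[i], condition = cond,
                 true_alpha_win = p[["alpha_win"]],
                 true_alpha_loss = p[["alpha_loss"]],
                 true_rho_win = p[["rho_win"]],
                 true_rho_loss = p[["rho_loss"]],
                 true_theta_win = p[["theta_win"]],
                 true_theta_loss = p[["theta_loss"]],
                 stringsAsFactors = FALSE)
    }))
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  aq <- data.frame(participant_id = ids, aq_score = aq_scores,
                   stringsAsFactors = FALSE)
  out <- list(trials = trials, aq = aq, truth = truth, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_csv_utf8(trials, file.path(dir, "trials.csv"))
    write_csv_utf8(aq, file.path(dir, "aq.csv"))
    write_csv_utf8(truth, file.path(dir, "truth.csv"))
  }
  out
}

# fixed CSV dialect: UTF-8, comma, header, "." decimal, no row names
write_csv_utf8 <- function(x, path) {
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e)
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

read_csv_utf8 <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
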