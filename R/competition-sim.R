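# Simulation of deadline-bound point-scoring competitions: a factorial
# episode design (4 deadlines x 13 starting score differences), a calibrated
# LBA opponent, and a participant whose trial-level threshold and correct
# drift follow the regression model in hier-model.R.

FEEDBACK_S <- 1.0  # progress screen shown after every decision

#' Reference covariate scaling used at generation time
#'
#' The generator standardizes the trial-level covariates with fixed
#' reference constants, so that the regression coefficients it uses are on a
#' known scale that recovery analyses can reproduce exactly (the inference
#' side can either re-estimate constants from data or reuse these; see
#' [standardize_covariates()]). The constants approximate the pooled mean
#' and sd of the covariates under the study design: score differences
#' random-walk around the −6..+6 starting grid, and time remaining is swept
#' roughly uniformly within episodes of 5–40 s, with longer episodes
#' contributing more decisions.
#'
#' @return A list with `score_diff` and `time_remaining` entries, each
#'   holding `mean` and `sd`.
#' @export
default_scaling <- function() {
  list(score_diff = list(mean = 0, sd = 4),
       time_remaining = list(mean = 14, sd = 11))
}

.standardize_with <- function(x, const) (x - const$mean) / const$sd

#' Map a participant parameter vector to a trial-parameter process
#'
#' Returns the function that the episode simulator calls at each stimulus
#' onset: given the raw covariates it standardizes them with `scaling`,
#' evaluates the threshold and correct-drift regressions, and returns the
#' trial's accumulator parameters. Threshold offsets that the regression
#' drives to zero or below are floored at `B_floor` (rare under the default
#' population; see the vignette).
#'
#' @param theta participant parameter vector ([participant_vector()]).
#' @param scaling covariate scaling constants ([default_scaling()]).
#' @param sv drift-rate sd (1 in this study).
#' @param B_floor lower clamp for the trial threshold offset.
#' @return `function(score_diff, time_remaining)` returning a list with
#'   `A`, `B`, `t0`, `v_correct`, `v_incorrect`, `sv`.
#' @export
make_participant_process <- function(theta, scaling = default_scaling(),
                                     sv = 1, B_floor = 1e-3) {
  force(theta); force(scaling)
  function(score_diff, time_remaining) {
    sdz <- .standardize_with(score_diff, scaling$score_diff)
    trz <- .standardize_with(time_remaining, scaling$time_remaining)
    lp <- linear_predictor(theta, sdz, trz)
    list(A = theta[["A"]], B = max(lp$B, B_floor), t0 = theta[["t0"]],
         v_correct = lp$v_correct, v_incorrect = theta[["v_incorrect"]],
         sv = sv)
  }
}

#' Enumerate the factorial episode design
#'
#' Full crossing of the four deadline levels (5, 10, 20, 40 s) with the 13
#' starting score differences (−6 … +6), each pair exactly once: 52
#' episodes. Start scores are assigned separately by
#' [assign_start_scores()]; episode order is randomized downstream.
#'
#' @return data.frame with columns `deadline_s` and `start_diff`.
#' @export
generate_design <- function() {
  d <- expand.grid(deadline_s = c(5, 10, 20, 40), start_diff = -6:6,
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[order(d$deadline_s, d$start_diff), c("deadline_s", "start_diff")]
  rownames(d) <- NULL
  d
}

#' Assign start scores to a design
#'
#' The participant's starting score is a uniform integer on 7..13; the
#' opponent's is derived exactly as `participant_start - start_diff`.
#'
#' @param design data.frame from [generate_design()].
#' @return The design with `participant_start` and `opponent_start` added.
#' @export
assign_start_scores <- function(design) {
  design$participant_start <- sample(7:13, nrow(design), replace = TRUE)
  design$opponent_start <- design$participant_start - design$start_diff
  design
}

#' Construct an opponent model
#'
#' The computerized opponent makes its own perceptual decisions from a fixed
#' LBA parameter set; its correct-response accumulator receives `v_correct`,
#' the other `v_incorrect`. The implied accuracy (probability that a made
#' response is correct) is computed from the analytic choice probabilities
#' and stored.
#'
#' @param v_correct,v_incorrect mean drift rates.
#' @param A,B,t0,sv remaining accumulator parameters.
#' @return An `opponent_model` object: list with `params`
#'   ([lba_params()], accumulator 1 = correct) and `accuracy`.
#' @export
opponent_model <- function(v_correct, v_incorrect = 0.5, A = 0.5, B = 1.0,
                           t0 = 0.25, sv = 1) {
  params <- lba_params(A = A, B = B, t0 = t0,
                       v = c(v_correct, v_incorrect), sv = sv)
  p1 <- lba_choice_probability(params, 1)
  p2 <- lba_choice_probability(params, 2)
  structure(list(params = params, accuracy = p1 / (p1 + p2)),
            class = "opponent_model")
}

#' @export
print.opponent_model <- function(x, ...) {
  cat(sprintf("LBA opponent: implied accuracy %.3f\n", x$accuracy))
  print(x$params)
  invisible(x)
}

# Calibrated so the mean net score over 20-s solo episodes is 8 points
# (see calibrate_opponent and the package tests, which revalidate this by
# fresh simulation).
.OPPONENT_V_CORRECT_DEFAULT <- 2.243945

#' The package's default opponent
#'
#' An opponent whose correct drift was calibrated by [calibrate_opponent()]
#' so that its mean net score over 20-second solo episodes is 8 points, the
#' level a typical human shows on this task.
#'
#' @return An [opponent_model()].
#' @export
default_opponent <- function() {
  opponent_model(v_correct = .OPPONENT_V_CORRECT_DEFAULT)
}

#' Simulate solo net scores for a fixed LBA decision maker
#'
#' Runs `n_episodes` independent episodes of length `horizon_s` in which the
#' decision maker repeatedly decides (gaining +1 for correct, −1 for
#' incorrect) with a 1-s feedback screen after each decision; a decision
#' still accumulating at the horizon is discarded. Vectorized across
#' episodes.
#'
#' @param opponent an [opponent_model()] (any fixed LBA decision maker).
#' @param horizon_s episode length in seconds.
#' @param n_episodes number of episodes.
#' @return Integer vector of net scores (final minus starting score).
#' @export
simulate_solo_scores <- function(opponent, horizon_s, n_episodes) {
  stopifnot(inherits(opponent, "opponent_model"), horizon_s > 0)
  p <- opponent$params
  clock <- numeric(n_episodes)
  score <- integer(n_episodes)
  active <- rep(TRUE, n_episodes)
  while (any(active)) {
    idx <- which(active)
    tr <- simulate_lba_trials(p, length(idx))
    done_time <- clock[idx] + tr$rt
    completed <- done_time <= horizon_s
    # accumulator 1 is the correct response by construction
    delta <- ifelse(tr$response == 1L, 1L, -1L)
    score[idx[completed]] <- score[idx[completed]] + delta[completed]
    clock[idx] <- done_time + FEEDBACK_S
    active[idx] <- completed & clock[idx] < horizon_s
  }
  score
}

#' Calibrate the opponent's correct drift to a target scoring rate
#'
#' Bisection on the correct-response mean drift (all other parameters held
#' at the [opponent_model()] defaults) until the simulated mean net score
#' over solo episodes of length `horizon_s` is within `tol` of
#' `target_score`. Common random numbers across bisection evaluations keep
#' the objective monotone; a fresh validation run at the returned drift is
#' reported in the result.
#'
#' @param target_score desired mean net score (points).
#' @param horizon_s episode length in seconds.
#' @param n_episodes episodes per bisection evaluation (validation uses at
#'   least 10,000).
#' @param tol calibration tolerance in points.
#' @param bracket initial bracket on the correct drift.
#' @return An [opponent_model()] with attributes `calibration` (list with
#'   `v_correct`, `mean_score`, `target`, `iterations`).
#' @export
calibrate_opponent <- function(target_score, horizon_s,
                               n_episodes = 4000L, tol = 0.1,
                               bracket = c(0.05, 12)) {
  t0 <- 0.25
  max_rate <- horizon_s / (t0 + FEEDBACK_S)  # perfect, instant decider
  if (target_score > max_rate) {
    stop(sprintf(
      "target %.1f points unachievable in %.0f s (ceiling %.1f with rt floor %.2f s + %.0f s feedback)",
      target_score, horizon_s, max_rate, t0, FEEDBACK_S), call. = FALSE)
  }
  crn_seed <- sample.int(2^31 - 1, 1L)
  mean_score <- function(v) {
    op <- opponent_model(v_correct = v)
    saved <- get0(".Random.seed", envir = .GlobalEnv)
    set.seed(crn_seed)
    m <- mean(simulate_solo_scores(op, horizon_s, n_episodes))
    if (!is.null(saved)) assign(".Random.seed", saved, envir = .GlobalEnv)
    m
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- mean_score(lo); f_hi <- mean_score(hi)
  if (!(f_lo <= target_score && f_hi >= target_score)) {
    stop(sprintf(
      "calibration target %.2f outside achievable range [%.2f, %.2f] for drift bracket [%.2f, %.2f]",
      target_score, f_lo, f_hi, lo, hi), call. = FALSE)
  }
  iterations <- 0L
  mid <- (lo + hi) / 2; f_mid <- mean_score(mid)
  while (abs(f_mid - target_score) > tol / 2 && (hi - lo) > 1e-4 &&
         iterations < 60L) {
    if (f_mid < target_score) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    f_mid <- mean_score(mid)
    iterations <- iterations + 1L
  }
  op <- opponent_model(v_correct = mid)
  valid <- mean(simulate_solo_scores(op, horizon_s, max(n_episodes, 10000L)))
  if (abs(valid - target_score) > max(tol, 0.5)) {
    stop(sprintf("calibration validation failed: mean %.2f vs target %.2f",
                 valid, target_score), call. = FALSE)
  }
  attr(op, "calibration") <- list(v_correct = mid, mean_score = valid,
                                  target = target_score,
                                  iterations = iterations)
  op
}

# simulate one decision for a stream given its trial parameters
.stream_trial <- function(par_list) {
  params <- lba_params(A = par_list$A, B = par_list$B, t0 = par_list$t0,
                       v = c(par_list$v_correct, par_list$v_incorrect),
                       sv = par_list$sv)
  stimulus <- sample(1:2, 1L)  # fair coin: 1 = left, 2 = right
  # accumulator order is (correct, incorrect); map back to L/R via stimulus
  tr <- simulate_lba_trials(params, 1L)
  response <- if (tr$response[1] == 1L) stimulus else 3L - stimulus
  list(stimulus = stimulus, response = response, rt = tr$rt[1],
       correct = tr$response[1] == 1L)
}

#' Simulate one competitive episode
#'
#' The participant and the opponent run as independent decision streams on a
#' shared episode clock: each stream repeats stimulus onset -> LBA decision
#' -> 1-s feedback screen until the deadline. A decision whose threshold
#' crossing would land after the deadline is discarded without score change;
#' the end-of-episode feedback screen is truncated by the deadline. The
#' participant's covariates (score difference, time remaining) are recorded
#' at stimulus onset, with score changes from either stream applied at the
#' moment the corresponding decision completes.
#'
#' @param participant_process function from [make_participant_process()].
#' @param opponent an [opponent_model()].
#' @param design one-row data.frame with `deadline_s`, `start_diff`,
#'   `participant_start`, `opponent_start`.
#' @return A list with `decisions` (participant trials), `opponent_decisions`,
#'   `final_participant_score`, `final_opponent_score`, `outcome`.
#' @export
simulate_episode <- function(participant_process, opponent, design) {
  deadline <- design$deadline_s[1]
  if (!is.finite(deadline) || deadline <= 0) {
    stop("episode deadline must be positive", call. = FALSE)
  }
  p_score <- design$participant_start[1]
  o_score <- design$opponent_start[1]
  # pending score deltas: completion time, stream, delta
  pending <- list()
  apply_pending <- function(upto) {
    if (!length(pending)) return(invisible())
    times <- vapply(pending, `[[`, numeric(1), "time")
    due <- times <= upto
    for (ev in pending[due]) {
      if (ev$who == "p") p_score <<- p_score + ev$delta
      else o_score <<- o_score + ev$delta
    }
    pending <<- pending[!due]
    invisible()
  }

  onset <- c(p = 0, o = 0)
  done <- c(p = FALSE, o = FALSE)
  p_rows <- list(); o_rows <- list()
  trial_no <- c(p = 0L, o = 0L)

  while (!all(done)) {
    who <- if (done["p"]) "o" else if (done["o"]) "p" else
      names(which.min(onset[!done]))
    t_on <- onset[[who]]
    if (t_on >= deadline) { done[who] <- TRUE; next }
    apply_pending(t_on)
    if (who == "p") {
      sd_now <- p_score - o_score
      par_list <- participant_process(sd_now, deadline - t_on)
    } else {
      par_list <- list(A = opponent$params$A, B = opponent$params$B,
                       t0 = opponent$params$t0,
                       v_correct = opponent$params$v[1],
                       v_incorrect = opponent$params$v[2],
                       sv = opponent$params$sv)
    }
    tr <- .stream_trial(par_list)
    t_done <- t_on + tr$rt
    if (t_done > deadline) { done[who] <- TRUE; next }  # dies at the deadline
    trial_no[who] <- trial_no[who] + 1L
    row <- data.frame(
      trial_index = trial_no[[who]], t_onset_s = t_on,
      time_remaining_s = deadline - t_on,
      score_diff = p_score - o_score,
      stimulus = c("L", "R")[tr$stimulus],
      response = c("L", "R")[tr$response],
      rt_s = tr$rt, correct = as.integer(tr$correct),
      stringsAsFactors = FALSE)
    if (who == "p") p_rows[[length(p_rows) + 1L]] <- row
    else o_rows[[length(o_rows) + 1L]] <- row
    pending[[length(pending) + 1L]] <- list(
      time = t_done, who = who, delta = if (tr$correct) 1L else -1L)
    onset[who] <- t_done + FEEDBACK_S
    if (onset[[who]] >= deadline) done[who] <- TRUE
  }
  apply_pending(deadline)
  outcome <- if (p_score > o_score) "win" else if (p_score < o_score) "loss" else "tie"
  list(
    decisions = if (length(p_rows)) do.call(rbind, p_rows) else NULL,
    opponent_decisions = if (length(o_rows)) do.call(rbind, o_rows) else NULL,
    final_participant_score = p_score,
    final_opponent_score = o_score,
    outcome = outcome
  )
}

#' Simulate a full synthetic dataset
#'
#' Draws each participant's 11-parameter vector from the population model,
#' simulates all 52 factorial episodes per participant in randomized order
#' against the opponent, and returns the decisions table, episodes table,
#' and a ground-truth sidecar for recovery analyses. Fully reproducible from
#' `seed`.
#'
#' @param n_participants number of simulated participants.
#' @param true_population generating [population_model()].
#' @param opponent an [opponent_model()].
#' @param scaling covariate scaling constants used by the generator.
#' @param seed integer seed.
#' @param practice if `TRUE`, each participant additionally plays one
#'   practice episode (20 s, zero starting difference) flagged
#'   `is_practice = 1`, mirroring the study procedure.
#' @return A list with data.frames `decisions` and `episodes`, and `truth`
#'   (list: `population`, `participants` matrix, `scaling`).
#' @export
simulate_dataset <- function(n_participants,
                             true_population = default_population(),
                             opponent = default_opponent(),
                             scaling = default_scaling(),
                             seed = 1L,
                             practice = FALSE) {
  set.seed(seed)
  theta_mat <- draw_participants(true_population, n_participants)
  base_design <- generate_design()
  dec_rows <- list(); ep_rows <- list()
  for (i in seq_len(n_participants)) {
    theta <- theta_mat[i, ]
    proc <- make_participant_process(theta, scaling)
    design <- base_design[sample.int(nrow(base_design)), , drop = FALSE]
    if (practice) {
      design <- rbind(data.frame(deadline_s = 20, start_diff = 0), design)
    }
    design <- assign_start_scores(design)
    design$is_practice <- 0L
    if (practice) design$is_practice[1] <- 1L
    for (e in seq_len(nrow(design))) {
      ep <- simulate_episode(proc, opponent, design[e, , drop = FALSE])
      ep_rows[[length(ep_rows) + 1L]] <- data.frame(
        participant_id = i, episode_id = e,
        deadline_condition_s = design$deadline_s[e],
        start_diff = design$start_diff[e],
        final_participant_score = ep$final_participant_score,
        final_opponent_score = ep$final_opponent_score,
        outcome = ep$outcome, is_practice = design$is_practice[e],
        stringsAsFactors = FALSE)
      if (!is.null(ep$decisions)) {
        d <- ep$decisions
        d$participant_id <- i
        d$episode_id <- e
        d$deadline_condition_s <- design$deadline_s[e]
        d$start_diff <- design$start_diff[e]
        d$participant_start <- design$participant_start[e]
        d$opponent_start <- design$opponent_start[e]
        d$is_practice <- design$is_practice[e]
        dec_rows[[length(dec_rows) + 1L]] <- d
      }
    }
  }
  decisions <- do.call(rbind, dec_rows)
  cols <- c("participant_id", "episode_id", "deadline_condition_s",
            "start_diff", "participant_start", "opponent_start",
            "trial_index", "t_onset_s", "time_remaining_s", "score_diff",
            "stimulus", "response", "rt_s", "correct", "is_practice")
  decisions <- decisions[, cols]
  rownames(decisions) <- NULL
  episodes <- do.call(rbind, ep_rows)
  rownames(episodes) <- NULL
  list(
    decisions = decisions,
    episodes = episodes,
    truth = list(population = true_population,
                 participants = theta_mat,
                 scaling = scaling,
                 seed = seed)
  )
}

#' Write a simulated dataset to disk
#'
#' Writes `decisions.csv`, `episodes.csv` and a `truth.json` sidecar
#' (per-participant 11-vectors, population values, scaling constants, seed).
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    decisions = file.path(dir, "decisions.csv"),
    episodes = file.path(dir, "episodes.csv"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(dataset$decisions, paths["decisions"], row.names = FALSE)
  utils::write.csv(dataset$episodes, paths["episodes"], row.names = FALSE)
  truth <- dataset$truth
  jsonlite::write_json(
    list(population = truth$population,
         participants = as.data.frame(truth$participants),
         scaling = truth$scaling, seed = truth$seed),
    paths["truth"], dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
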