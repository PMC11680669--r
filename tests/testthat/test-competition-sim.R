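# Factorial design, opponent calibration, and episode/dataset simulation.

test_that("the factorial design crosses 4 deadlines with 13 starting differences exactly once", {
  d <- generate_design()
  expect_equal(nrow(d), 52L)
  expect_setequal(unique(d$deadline_s), c(5, 10, 20, 40))
  expect_setequal(unique(d$start_diff), -6:6)
  expect_equal(nrow(unique(d[, c("deadline_s", "start_diff")])), 52L)
})

test_that("start scores are uniform on 7..13 with the opponent derived exactly", {
  set.seed(11)
  d <- generate_design()
  big <- do.call(rbind, replicate(200, assign_start_scores(d),
                                  simplify = FALSE))
  expect_true(all(big$participant_start %in% 7:13))
  expect_true(all(big$opponent_start == big$participant_start - big$start_diff))
  tied <- big[big$start_diff == 0, ]
  expect_true(all(tied$participant_start == tied$opponent_start))
  one <- assign_start_scores(data.frame(deadline_s = 5, start_diff = 6))
  expect_equal(one$opponent_start, one$participant_start - 6)
})

test_that("episode simulation respects the clock, the deadline, and the covariate log", {
  set.seed(12)
  theta <- test_theta()
  theta[["t0"]] <- 0.3  # rt floor above 0.25 s
  proc <- make_participant_process(theta)
  op <- default_opponent()
  des <- assign_start_scores(data.frame(deadline_s = 5, start_diff = 0))
  for (r in 1:20) {
    ep <- simulate_episode(proc, op, des)
    if (is.null(ep$decisions)) next
    d <- ep$decisions
    # rt > 0.25 s and 1-s feedback bound completed decisions by floor(5/1.25)
    expect_lte(nrow(d), 4L)
    expect_true(all(d$time_remaining_s > 0 & d$time_remaining_s <= 5))
    expect_true(all(d$t_onset_s + d$rt_s <= 5 + 1e-12))
  }
  # score-difference covariate is recomputable from both decision streams
  des40 <- assign_start_scores(data.frame(deadline_s = 40, start_diff = -3))
  ep <- simulate_episode(proc, op, des40)
  all_dec <- rbind(
    cbind(ep$decisions, who = "p"),
    cbind(ep$opponent_decisions, who = "o"))
  all_dec$t_done <- all_dec$t_onset_s + all_dec$rt_s
  for (j in seq_len(nrow(ep$decisions))) {
    onset <- ep$decisions$t_onset_s[j]
    done <- all_dec[all_dec$t_done <= onset, ]
    delta <- sum(ifelse(done$who == "p", 1, -1) *
                   ifelse(done$correct == 1, 1, -1))
    expect_equal(ep$decisions$score_diff[j], -3 + delta)
  }
  # final scores follow the same bookkeeping
  net_p <- sum(ifelse(ep$decisions$correct == 1, 1, -1))
  expect_equal(ep$final_participant_score,
               des40$participant_start + net_p)
  expect_error(simulate_episode(proc, op,
                                data.frame(deadline_s = 0, start_diff = 0,
                                           participant_start = 8,
                                           opponent_start = 8)),
               "deadline")
})

test_that("a dominant-drift opponent never loses points", {
  set.seed(13)
  op <- opponent_model(v_correct = 10, v_incorrect = -10, sv = 0.01)
  theta <- test_theta()
  proc <- make_participant_process(theta)
  des <- assign_start_scores(data.frame(deadline_s = 10, start_diff = 0))
  ep <- simulate_episode(proc, op, des)
  expect_true(all(ep$opponent_decisions$correct == 1))
  expect_gte(ep$final_opponent_score, des$opponent_start)
})

test_that("opponent calibration is monotone in the target and symmetric at zero", {
  set.seed(14)
  op0 <- calibrate_opponent(0, 20, n_episodes = 1500L, tol = 0.3)
  cal0 <- attr(op0, "calibration")
  expect_lt(abs(cal0$mean_score), 0.6)
  # symmetric target: correct drift near the incorrect drift default
  expect_lt(abs(op0$params$v[1] - op0$params$v[2]), 0.35)
  op6 <- calibrate_opponent(6, 20, n_episodes = 1500L, tol = 0.3)
  op10 <- calibrate_opponent(10, 20, n_episodes = 1500L, tol = 0.3)
  expect_gt(attr(op10, "calibration")$v_correct,
            attr(op6, "calibration")$v_correct)
  expect_error(calibrate_opponent(40, 20, n_episodes = 500L), "unachievable")
})

test_that("dataset simulation is reproducible, complete, and internally consistent", {
  ds1 <- simulate_dataset(2, seed = 15)
  ds2 <- simulate_dataset(2, seed = 15)
  expect_identical(ds1, ds2)
  expect_equal(as.vector(table(ds1$episodes$participant_id)), c(52L, 52L))
  # win/loss/tie partition the episodes
  expect_equal(sum(table(ds1$episodes$outcome)), nrow(ds1$episodes))
  expect_true(all(ds1$decisions$rt_s > 0))
  expect_true(all(ds1$decisions$time_remaining_s > 0))
  # each participant's truth vector respects the individual-level support
  th <- ds1$truth$participants
  expect_true(all(th[, "A"] >= 0 & th[, "b0"] >= 0))
  expect_true(all(th[, "t0"] >= 0.1 & th[, "t0"] <= 1))
})

test_that("win rate responds directionally to participant strength", {
  set.seed(16)
  strong <- test_theta(); strong[["b4"]] <- 4; strong[["v_incorrect"]] <- -1
  weak <- test_theta(); weak[["b4"]] <- 0.6; weak[["v_incorrect"]] <- 0.5
  op <- default_opponent()
  play <- function(theta) {
    proc <- make_participant_process(theta)
    wins <- 0L
    for (r in 1:30) {
      des <- assign_start_scores(data.frame(deadline_s = 20, start_diff = 0))
      ep <- simulate_episode(proc, op, des)
      wins <- wins + (ep$outcome == "win")
    }
    wins / 30
  }
  expect_gt(play(strong), play(weak))
})

test_that("null regression slopes leave response time unrelated to time remaining", {
  pop <- default_population()
  pop$mu[pop$parameter %in% c("b1", "b2", "b3", "b5", "b6", "b7")] <- 0
  pop$sigma[] <- 1e-6
  ds <- simulate_dataset(22, true_population = pop, seed = 17)
  expect_gt(nrow(ds$decisions), 1e4)
  rho <- stats::cor(ds$decisions$rt_s, ds$decisions$time_remaining_s,
                    method = "spearman")
  expect_lt(abs(rho), 0.05)
})

test_that("dataset files round-trip through the on-disk format", {
  ds <- simulate_dataset(1, seed = 18)
  dir <- tempfile("lbarena-ds-")
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths["decisions"])
  expect_equal(nrow(back), nrow(ds$decisions))
  expect_equal(back$rt_s, ds$decisions$rt_s, tolerance = 1e-8)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$seed, 18)
  unlink(dir, recursive = TRUE)
})
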