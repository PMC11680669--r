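# Shared fixtures, built in code at test time.

# canonical participant vector used across tests (the generating-population
# locations)
test_theta <- function() {
  participant_vector(A = 0.7, t0 = 0.3, v_incorrect = 0.7,
                     b0 = 0.8, b1 = 0.04, b2 = 0.05, b3 = -0.02,
                     b4 = 1.8, b5 = 0.13, b6 = -0.03, b7 = 0.03)
}

# simulate n regression-LBA trials for one participant with standard-normal
# covariates (no deadline censoring; likelihood conditioning "response")
simulate_regression_trials <- function(theta, n, seed = 1) {
  set.seed(seed)
  sdz <- stats::rnorm(n)
  trz <- stats::rnorm(n)
  lp <- linear_predictor(theta, sdz, trz)
  rt <- numeric(n); corr <- logical(n)
  for (i in seq_len(n)) {
    p <- lba_params(A = theta[["A"]], B = max(lp$B[i], 1e-3),
                    t0 = theta[["t0"]],
                    v = c(lp$v_correct[i], theta[["v_incorrect"]]))
    d <- simulate_lba_trials(p, 1L)
    rt[i] <- d$rt; corr[i] <- d$response == 1L
  }
  data.frame(rt_s = rt, correct = corr, score_diff_z = sdz,
             time_remaining_z = trz, interaction_z = sdz * trz)
}
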