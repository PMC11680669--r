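# Trial-level regression structure, likelihood assembly, and the
# hierarchical prior layer.

test_that("the model exposes exactly 11 free parameters per participant", {
  expect_equal(n_free_parameters(), 11L)
  expect_length(participant_parameter_names(), 11L)
  theta <- test_theta()
  expect_length(theta, n_free_parameters())
})

test_that("participant vectors are validated against their support", {
  expect_error(participant_vector(A = -0.1, t0 = 0.3, v_incorrect = 0.5,
                                  b0 = 1, b1 = 0, b2 = 0, b3 = 0,
                                  b4 = 2, b5 = 0, b6 = 0, b7 = 0))
  expect_error(participant_vector(A = 0.5, t0 = 0.05, v_incorrect = 0.5,
                                  b0 = 1, b1 = 0, b2 = 0, b3 = 0,
                                  b4 = 2, b5 = 0, b6 = 0, b7 = 0))
  expect_error(participant_vector(A = 0.5, t0 = 0.3, v_incorrect = 0.5,
                                  b0 = -1, b1 = 0, b2 = 0, b3 = 0,
                                  b4 = 2, b5 = 0, b6 = 0, b7 = 0))
})

test_that("linear predictors follow the regression equations", {
  theta <- participant_vector(A = 0.5, t0 = 0.3, v_incorrect = 0.5,
                              b0 = 1.0, b1 = 0.04, b2 = 0.05, b3 = -0.02,
                              b4 = 2.0, b5 = 0.1, b6 = -0.05, b7 = 0.02)
  # direct arithmetic: 1.0 + 0.04*1.2 + 0.05*(-0.5) + (-0.02)*(-0.6) = 1.035
  lp <- linear_predictor(theta, 1.2, -0.5, -0.6)
  expect_equal(lp$B, 1.035)
  # intercept-only at covariate zero (and with all slopes zero)
  lp0 <- linear_predictor(theta, 0, 0, 0)
  expect_equal(lp0$B, 1.0)
  expect_equal(lp0$v_correct, 2.0)
  flat <- theta
  flat[c("b1", "b2", "b3", "b5", "b6", "b7")] <- 0
  lpf <- linear_predictor(flat, 2.7, -1.9)
  expect_equal(lpf$B, 1.0)
  expect_equal(lpf$v_correct, 2.0)
})

test_that("participant log-likelihood is additive, empty-safe, and matches the core density", {
  theta <- test_theta()
  trials <- simulate_regression_trials(theta, 10, seed = 41)
  expect_equal(participant_loglik(theta, trials[0, ]), 0)
  # additivity over disjoint trial sets
  l_all <- participant_loglik(theta, trials, conditioning = "none")
  l_split <- participant_loglik(theta, trials[1:4, ], conditioning = "none") +
    participant_loglik(theta, trials[5:10, ], conditioning = "none")
  expect_equal(l_all, l_split)
  # per-trial oracle from the lba_core defective density
  lp <- linear_predictor(theta, trials$score_diff_z, trials$time_remaining_z,
                         trials$interaction_z)
  oracle <- sum(vapply(seq_len(10), function(i) {
    p <- lba_params(A = theta[["A"]], B = lp$B[i], t0 = theta[["t0"]],
                    v = c(lp$v_correct[i], theta[["v_incorrect"]]))
    winner <- if (trials$correct[i]) 1L else 2L
    lba_trial_loglik(trials$rt_s[i], winner, p)
  }, numeric(1)))
  expect_equal(l_all, oracle)
  # response conditioning subtracts the no-response mass per trial
  l_resp <- participant_loglik(theta, trials, conditioning = "response")
  p_none <- pnorm(-lp$v_correct) * pnorm(-theta[["v_incorrect"]])
  expect_equal(l_resp, l_all - sum(log1p(-p_none)))
  # deadline conditioning uses the closed-form race completion cdf
  trials$time_remaining_s <- trials$rt_s + runif(10, 0.1, 4)
  l_dead <- participant_loglik(theta, trials)
  z <- vapply(seq_len(10), function(i) {
    p <- lba_params(A = theta[["A"]], B = lp$B[i], t0 = theta[["t0"]],
                    v = c(lp$v_correct[i], theta[["v_incorrect"]]))
    tau <- trials$time_remaining_s[i] - theta[["t0"]]
    F1 <- lba_fp_cdf(tau, p$A, p$b, p$v[1], p$sv)
    F2 <- lba_fp_cdf(tau, p$A, p$b, p$v[2], p$sv)
    1 - (1 - F1) * (1 - F2)
  }, numeric(1))
  expect_equal(l_dead, l_all - sum(log(z)))
})

test_that("parameter points outside the support are rejected with -Inf", {
  theta <- test_theta()
  trials <- simulate_regression_trials(theta, 5, seed = 42)
  bad <- theta; bad[["b0"]] <- 0.01; bad[["b1"]] <- 2
  # large slope drives some trial's B_ij negative
  expect_identical(participant_loglik(bad, trials), -Inf)
  late <- theta; late[["t0"]] <- min(trials$rt_s) + 0.01
  late[["t0"]] <- min(late[["t0"]], 1)
  expect_identical(participant_loglik(late, trials), -Inf)
})

test_that("with zero slopes the likelihood is invariant to permuting covariates", {
  theta <- test_theta()
  theta[c("b1", "b2", "b3", "b5", "b6", "b7")] <- 0
  trials <- simulate_regression_trials(theta, 30, seed = 43)
  perm <- trials
  idx <- sample.int(30)
  perm$score_diff_z <- trials$score_diff_z[idx]
  perm$time_remaining_z <- trials$time_remaining_z[idx]
  perm$interaction_z <- trials$interaction_z[idx]
  expect_equal(participant_loglik(theta, perm, conditioning = "response"),
               participant_loglik(theta, trials, conditioning = "response"))
})

test_that("population priors: truncation sentinels, closed forms, and the quadrature oracle", {
  pop <- default_population()
  theta <- test_theta()
  bad_t0 <- theta; bad_t0[["t0"]] <- 0.3
  bad <- unclass(bad_t0); bad["t0"] <- 0.05  # below the 0.1 bound
  expect_identical(log_prior(bad, pop), -Inf)
  # untruncated parameter at its location: -log(sigma * sqrt(2*pi))
  single <- population_model(
    mu = c(A = 1, t0 = 0.3, v_incorrect = 0.5, b0 = 1, b1 = 0, b2 = 0,
           b3 = 0, b4 = 2, b5 = 0, b6 = 0, b7 = 0),
    sigma = c(A = 1, t0 = 0.1, v_incorrect = 2, b0 = 1, b1 = 1, b2 = 1,
              b3 = 1, b4 = 1, b5 = 1, b6 = 1, b7 = 1))
  at_mu <- c(A = 1, t0 = 0.3, v_incorrect = 0.5, b0 = 1, b1 = 0, b2 = 0,
             b3 = 0, b4 = 2, b5 = 0, b6 = 0, b7 = 0)
  lp <- log_prior(at_mu, single)
  # isolate the v_incorrect term by shifting it off its location
  shifted <- at_mu; shifted["v_incorrect"] <- 2.5
  expect_equal(lp - log_prior(shifted, single),
               dnorm(0.5, 0.5, 2, log = TRUE) - dnorm(2.5, 0.5, 2, log = TRUE))
  # truncated-normal density for A = 0.5 under mu = 1, sigma = 1, [0, Inf):
  # closed form vs numeric renormalization
  dens_closed <- dnorm(0.5, 1, 1) / (1 - pnorm(0, 1, 1))
  Zq <- stats::integrate(function(x) dnorm(x, 1, 1), 0, Inf)$value
  expect_equal(dens_closed, dnorm(0.5, 1, 1) / Zq, tolerance = 1e-7)
  at_A <- at_mu; at_A["A"] <- 0.5
  expect_equal(log_prior(at_A, single) - lp,
               log(dens_closed) - log(dnorm(1, 1, 1) / (1 - pnorm(0, 1, 1))))
})

test_that("hyperprior density is finite inside the support and -Inf outside", {
  pop <- default_population()
  expect_true(is.finite(hyper_log_prior(pop)))
  bad <- pop; bad$sigma[1] <- -1
  expect_identical(hyper_log_prior(bad), -Inf)
  out_of_support <- pop; out_of_support$mu[out_of_support$parameter == "t0"] <- -2
  expect_identical(hyper_log_prior(out_of_support), -Inf)
})

test_that("population draws respect bounds and error when the cap is exhausted", {
  pop <- default_population()
  set.seed(44)
  th <- draw_participants(pop, 200)
  expect_true(all(th[, "A"] >= 0))
  expect_true(all(th[, "t0"] >= 0.1 & th[, "t0"] <= 1))
  hopeless <- pop
  hopeless$mu[hopeless$parameter == "t0"] <- 0.1
  hopeless$sigma[hopeless$parameter == "t0"] <- 1e-12
  hopeless$mu[hopeless$parameter == "t0"] <- -5  # essentially never in [0.1, 1]
  expect_error(draw_participants(hopeless, 5, max_redraws = 3),
               "redraws")
})
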