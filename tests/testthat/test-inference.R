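# Sampler calibration on conjugate targets, convergence diagnostics,
# Savage-Dickey machinery, and the maximum-likelihood recovery path.

# conjugate normal-normal toy: y_i ~ N(theta, sd_y^2), theta ~ N(0, sd0^2)
conjugate_posterior <- function(y, sd_y, sd0) {
  n <- length(y)
  prec <- n / sd_y^2 + 1 / sd0^2
  list(mean = sum(y) / sd_y^2 / prec, sd = sqrt(1 / prec))
}

test_that("DE-MC recovers the conjugate normal posterior and is seed-reproducible", {
  set.seed(51)
  y <- rnorm(40, 1.2, 1)
  post <- conjugate_posterior(y, 1, 2)
  lp <- function(th) sum(dnorm(y, th, 1, log = TRUE)) + dnorm(th, 0, 2, log = TRUE)
  init <- matrix(rnorm(8, post$mean, 0.3), 8, 1)
  fit <- de_mcmc(lp, init, iterations = 1500, warmup = 500, seed = 52)
  draws <- as.numeric(fit$draws)
  mcse <- sd(draws) / sqrt(length(draws) / 20)  # generous autocorrelation allowance
  expect_lt(abs(mean(draws) - post$mean), 3 * mcse)
  expect_equal(sd(draws), post$sd, tolerance = 0.15)
  fit2 <- de_mcmc(lp, init, iterations = 1500, warmup = 500, seed = 52)
  expect_identical(fit$draws, fit2$draws)
  expect_error(de_mcmc(function(th) -Inf, matrix(0, 8, 1), 10, 10), "-Inf")
  expect_error(de_mcmc(lp, init[1:3, , drop = FALSE], 10, 10), "chains")
})

test_that("95% interval coverage on replicated conjugate fits is calibrated", {
  set.seed(53)
  hits <- 0L
  n_rep <- 150L
  for (r in seq_len(n_rep)) {
    theta_true <- rnorm(1, 0, 2)
    y <- rnorm(15, theta_true, 1)
    lp <- function(th) sum(dnorm(y, th, 1, log = TRUE)) +
      dnorm(th, 0, 2, log = TRUE)
    post <- conjugate_posterior(y, 1, 2)
    init <- matrix(rnorm(6, post$mean, post$sd), 6, 1)
    fit <- de_mcmc(lp, init, iterations = 250, warmup = 150)
    ci <- credible_interval(as.numeric(fit$draws))
    hits <- hits + (theta_true >= ci["lower"] && theta_true <= ci["upper"])
  }
  cover <- hits / n_rep
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})

test_that("split R-hat separates converged, divergent, and degenerate chains", {
  set.seed(54)
  same <- matrix(rnorm(2e4), ncol = 2)
  expect_lt(split_rhat(same), 1.01)
  offset <- cbind(rnorm(1e4), rnorm(1e4, 5))
  expect_gt(split_rhat(offset), 1.5)
  expect_equal(split_rhat(matrix(1.7, 100, 3)), 1)
  expect_error(split_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(split_rhat(matrix(rnorm(4), 2, 2)), "4 draws")
})

test_that("Savage-Dickey: prior-equal-posterior gives 1, conjugate case matches closed form", {
  set.seed(55)
  # prior = posterior
  draws <- rnorm(1e5, 0, 2)
  bf <- savage_dickey_bf(draws, function(x) dnorm(x, 0, 2))
  expect_equal(as.numeric(bf), 1, tolerance = 0.1)
  # conjugate normal-normal: analytic BF10 in closed form
  y <- rnorm(30, 0.5, 1)
  post <- conjugate_posterior(y, 1, 2)
  analytic <- dnorm(0, 0, 2) / dnorm(0, post$mean, post$sd)
  bf2 <- savage_dickey_bf(rnorm(2e5, post$mean, post$sd),
                          function(x) dnorm(x, 0, 2))
  expect_equal(as.numeric(bf2), analytic, tolerance = 0.1)
  # posterior far from zero: overwhelming evidence
  far <- rnorm(2e4, 12, 1)  # 6 prior sds from 0
  bf3 <- savage_dickey_bf(far, function(x) dnorm(x, 0, 2))
  expect_gt(as.numeric(bf3), 100)
  # unresolvable mass at zero is capped and flagged, never infinite
  bf4 <- savage_dickey_bf(rnorm(1e4, 1000, 0.5), function(x) dnorm(x, 0, 2))
  expect_true(attr(bf4, "capped"))
  expect_equal(as.numeric(bf4), 1e6)
  expect_error(savage_dickey_bf(draws, 0), "positive")
})

test_that("Bayes factors grow monotonically with simulated effect size", {
  set.seed(56)
  bfs <- vapply(c(0, 1, 2.5, 4), function(shift) {
    as.numeric(savage_dickey_bf(rnorm(2e4, shift, 1),
                                function(x) dnorm(x, 0, 2)))
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("evidence labels follow the conventional bins", {
  expect_equal(as.character(classify_evidence(3.44)), "moderate")
  expect_equal(as.character(classify_evidence(11.91)), "strong")
  expect_equal(as.character(classify_evidence(4976)), "extreme")
  expect_equal(as.character(classify_evidence(50)), "very strong")
  expect_equal(as.character(classify_evidence(1.5)), "anecdotal")
  weak <- classify_evidence(1 / 5)
  expect_equal(as.character(weak), "moderate")
  expect_equal(attr(weak, "direction"), "absence")
  expect_error(classify_evidence(0), "positive")
  expect_error(classify_evidence(-2), "positive")
})

test_that("credible intervals hit known quantiles", {
  set.seed(57)
  z <- rnorm(1e6)
  ci <- credible_interval(z)
  expect_equal(unname(ci["lower"]), -1.96, tolerance = 0.01 / 1.96)
  expect_equal(unname(ci["upper"]), 1.96, tolerance = 0.01 / 1.96)
  expect_equal(unname(credible_interval(rep(3.2, 500))), c(3.2, 3.2))
  u <- runif(1e6)
  ci50 <- credible_interval(u, level = 0.5)
  expect_equal(unname(ci50), c(0.25, 0.75), tolerance = 0.05)
})

test_that("the MLE path recovers a known vector and does not undercut the generating point", {
  theta <- test_theta()
  trials <- simulate_regression_trials(theta, 2000, seed = 58)
  fit <- mle_fit(trials, n_starts = 3)
  expect_true(fit$converged)
  # recovery within 20% of truth, allowing for the estimator's own sampling
  # uncertainty along the flat A/b0 ridge (observed-information SEs)
  nm <- participant_parameter_names()
  nll <- function(par) {
    names(par) <- nm
    -participant_loglik(par, trials, conditioning = "response")
  }
  se <- sqrt(diag(solve(stats::optimHess(fit$theta, nll))))
  names(se) <- nm
  for (k in c("A", "b0", "b4")) {
    expect_lt(abs(fit$theta[[k]] - theta[[k]]),
              max(0.2 * abs(theta[[k]]), 3 * se[[k]]))
  }
  # sample optimality: the fit cannot be worse than the generating truth
  expect_gte(fit$loglik,
             participant_loglik(theta, trials, conditioning = "response") - 1e-6)
})

test_that("a small hierarchical fit emits a complete, internally consistent evidence report", {
  ds <- simulate_dataset(2, seed = 91)
  prep <- prepare_decisions(ds$decisions, scaling = ds$truth$scaling)
  trials <- lapply(unique(prep$participant_id),
                   function(i) participant_trials(prep, i))
  # a participant screened out by the accuracy rule is rejected explicitly
  expect_error(sample_posterior(trials, settings = list(iterations = 2,
                                                        warmup = 2)),
               "no retained trials")
  trials <- trials[vapply(trials, nrow, integer(1)) > 0L]
  fit <- sample_posterior(trials,
                          settings = list(chains = 12, iterations = 40,
                                          warmup = 40, seed = 92,
                                          init = "heuristic"))
  expect_s3_class(fit, "lba_posterior")
  expect_output(print(fit), "12 chains")
  rep <- evidence_report(fit)
  expect_equal(rep$effect, c("b1", "b2", "b3", "b5", "b6", "b7"))
  expect_true(all(is.finite(rep$bf10) & rep$bf10 > 0))
  expect_true(all(rep$ci_lower <= rep$ci_upper))
  # labels are reproduced by classifying the reported Bayes factors
  expect_equal(rep$label,
               vapply(rep$bf10,
                      function(b) as.character(classify_evidence(b)),
                      character(1)))
  summ <- population_summary(fit)
  expect_equal(nrow(summ), 11L)
  expect_true(all(summ$rhat >= 1))
  # same seed reproduces the draws exactly
  fit2 <- sample_posterior(trials,
                           settings = list(chains = 12, iterations = 40,
                                           warmup = 40, seed = 92,
                                           init = "heuristic"))
  expect_identical(fit$mu, fit2$mu)
})

test_that("null slopes are estimated within curvature-based uncertainty", {
  theta <- test_theta()
  theta[c("b1", "b2", "b3", "b5", "b6", "b7")] <- 0
  trials <- simulate_regression_trials(theta, 1500, seed = 59)
  fit <- mle_fit(trials, n_starts = 3)
  # observed-information standard errors via a numeric Hessian
  nm <- participant_parameter_names()
  nll <- function(par) {
    names(par) <- nm
    -participant_loglik(par, trials, conditioning = "response")
  }
  H <- stats::optimHess(fit$theta, nll)
  se <- sqrt(diag(solve(H)))
  names(se) <- nm
  for (k in c("b1", "b2", "b3", "b5", "b6", "b7")) {
    expect_lt(abs(fit$theta[[k]]), 3 * se[[k]])
  }
})
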