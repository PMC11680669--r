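# Descriptive behavioral models: Bayesian mixed-effects polynomial
# regressions of accuracy (logit link) and response time (log scale,
# milliseconds) on score difference, time remaining, their squares, and
# their interaction, with participant random intercepts. Fitted with the
# same blocked DE-MC machinery as the LBA, so Savage-Dickey Bayes factors
# come straight off the posterior draws.

.GLMM_EFFECTS <- c("intercept", "score_diff_z", "score_diff_z_sq",
                   "time_remaining_z", "time_remaining_z_sq", "interaction")

#' Specify a behavioral mixed-effects model
#'
#' @param outcome `"accuracy"` (Bernoulli, logit link) or `"rt"`
#'   (log-normal on milliseconds).
#' @param priors list with `fixed_sd` (sd of the zero-centered normal prior
#'   on the five non-intercept coefficients; the Savage-Dickey prior
#'   ordinate at 0 is taken from this), `intercept_sd`, `tau_sd`
#'   (half-normal sd for the random-intercept scale) and `sigma_sd`
#'   (half-normal sd for the residual sd of the log-RT model).
#' @return A `behavioral_spec` object.
#' @export
behavioral_spec <- function(outcome = c("accuracy", "rt"),
                            priors = list()) {
  outcome <- match.arg(outcome)
  priors <- utils::modifyList(
    list(fixed_sd = 1, intercept_sd = 5, tau_sd = 1, sigma_sd = 1), priors)
  structure(list(outcome = outcome, priors = priors,
                 effects = .GLMM_EFFECTS),
            class = "behavioral_spec")
}

# fixed-effect design matrix from prepared decisions
.glmm_design <- function(records) {
  stopifnot(all(c("score_diff_z", "time_remaining_z") %in% names(records)))
  cbind(intercept = 1,
        score_diff_z = records$score_diff_z,
        score_diff_z_sq = records$score_diff_z^2,
        time_remaining_z = records$time_remaining_z,
        time_remaining_z_sq = records$time_remaining_z^2,
        interaction = records$score_diff_z * records$time_remaining_z)
}

#' Fit a behavioral mixed-effects model by blocked DE-MC
#'
#' Posterior sampling for the six fixed effects, the per-participant random
#' intercepts, the random-intercept scale tau, and (for the RT model) the
#' residual sd. Random intercepts are updated in a vectorized
#' participant-wise Metropolis pass (their full conditionals factor by
#' participant); fixed effects and variance parameters get DE proposals.
#'
#' @param spec a [behavioral_spec()].
#' @param records prepared decisions ([prepare_decisions()]); excluded rows
#'   are dropped here. Accuracy uses the 0/1 `correct` column; RT uses
#'   `rt_s` converted to milliseconds.
#' @param settings list: `chains` (default 16), `iterations` (default 500),
#'   `warmup` (default 500), `seed`, `eps`.
#' @return A `behavioral_fit` object: draws for fixed effects
#'   (`iterations x chains x 6`), `tau`, `sigma` (RT only), random
#'   intercepts at the final iteration, spec and settings.
#' @export
fit_behavioral_model <- function(spec, records, settings = list()) {
  stopifnot(inherits(spec, "behavioral_spec"))
  s <- utils::modifyList(list(chains = 16L, iterations = 500L,
                              warmup = 500L, seed = 1L, eps = 1e-4),
                         settings)
  set.seed(s$seed)
  keep <- if ("excluded" %in% names(records)) !records$excluded else
    rep(TRUE, nrow(records))
  d <- records[keep, , drop = FALSE]
  if (!nrow(d)) stop("no retained decisions to fit", call. = FALSE)
  X <- .glmm_design(d)
  pid <- match(d$participant_id, unique(d$participant_id))
  n_p <- max(pid)
  if (spec$outcome == "accuracy") {
    y <- as.numeric(d$correct)
    if (!all(y %in% c(0, 1))) {
      stop("accuracy outcome must be binary 0/1", call. = FALSE)
    }
  } else {
    if (!"rt_s" %in% names(d)) stop("rt_s column required", call. = FALSE)
    y <- log(d$rt_s * 1000)  # log milliseconds
  }
  pr <- spec$priors
  fixed_prior_sd <- c(pr$intercept_sd, rep(pr$fixed_sd, 5L))

  # per-participant log likelihood given linear predictor pieces
  loglik_by_p <- function(beta, u, sigma) {
    eta <- drop(X %*% beta) + u[pid]
    if (spec$outcome == "accuracy") {
      ll <- y * eta - log1p(exp(eta))
    } else {
      ll <- stats::dnorm(y, eta, sigma, log = TRUE)
    }
    rowsum(ll, pid)[, 1]
  }

  K <- 6L
  # initialization: crude GLM-ish start plus jitter
  beta0 <- if (spec$outcome == "accuracy") {
    c(stats::qlogis(min(max(mean(y), 0.05), 0.95)), rep(0, 5))
  } else c(mean(y), rep(0, 5))
  beta <- matrix(rep(beta0, each = s$chains), s$chains, K,
                 dimnames = list(NULL, spec$effects)) +
    matrix(stats::rnorm(s$chains * K, 0, 0.05), s$chains, K)
  u <- matrix(stats::rnorm(s$chains * n_p, 0, 0.1), s$chains, n_p)
  tau <- abs(stats::rnorm(s$chains, 0.3, 0.05))
  sigma <- if (spec$outcome == "rt") {
    abs(stats::rnorm(s$chains, stats::sd(y), 0.02))
  } else rep(NA_real_, s$chains)

  llp <- matrix(NA_real_, s$chains, n_p)  # per-participant loglik cache
  for (ch in seq_len(s$chains)) {
    llp[ch, ] <- loglik_by_p(beta[ch, ], u[ch, ], sigma[ch])
  }

  total <- s$warmup + s$iterations
  out_beta <- array(NA_real_, c(s$iterations, s$chains, K),
                    dimnames = list(NULL, NULL, spec$effects))
  out_tau <- matrix(NA_real_, s$iterations, s$chains)
  out_sigma <- matrix(NA_real_, s$iterations, s$chains)
  acc_beta <- 0L

  for (it in seq_len(total)) {
    # fixed effects: DE proposal on the 6-vector (subset half the time)
    for (ch in seq_len(s$chains)) {
      if (stats::runif(1) < 0.5) {
        idx <- sample.int(K, 2L)
        prop <- beta[ch, ]
        prop[idx] <- .de_proposal(beta, ch, idx, s$eps)
      } else {
        prop <- .de_proposal(beta, ch, seq_len(K), s$eps)
      }
      ll_prop <- loglik_by_p(prop, u[ch, ], sigma[ch])
      lr <- sum(ll_prop) - sum(llp[ch, ]) +
        sum(stats::dnorm(prop, 0, fixed_prior_sd, log = TRUE)) -
        sum(stats::dnorm(beta[ch, ], 0, fixed_prior_sd, log = TRUE))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        beta[ch, ] <- prop
        llp[ch, ] <- ll_prop
        acc_beta <- acc_beta + 1L
      }
    }
    # random intercepts: vectorized per-participant random-walk Metropolis
    for (ch in seq_len(s$chains)) {
      step <- stats::rnorm(n_p, 0, 0.5 * tau[ch] + 0.02)
      u_prop <- u[ch, ] + step
      ll_prop <- loglik_by_p(beta[ch, ], u_prop, sigma[ch])
      lr <- ll_prop - llp[ch, ] +
        stats::dnorm(u_prop, 0, tau[ch], log = TRUE) -
        stats::dnorm(u[ch, ], 0, tau[ch], log = TRUE)
      acc <- log(stats::runif(n_p)) < lr
      u[ch, acc] <- u_prop[acc]
      llp[ch, acc] <- ll_prop[acc]
    }
    # tau (and sigma for RT): random-walk on the positive half-line
    for (ch in seq_len(s$chains)) {
      prop <- tau[ch] * exp(stats::rnorm(1, 0, 0.15))
      lr <- sum(stats::dnorm(u[ch, ], 0, prop, log = TRUE)) -
        sum(stats::dnorm(u[ch, ], 0, tau[ch], log = TRUE)) +
        stats::dnorm(prop, 0, pr$tau_sd, log = TRUE) -
        stats::dnorm(tau[ch], 0, pr$tau_sd, log = TRUE) +
        log(prop) - log(tau[ch])  # log-scale proposal Jacobian
      if (is.finite(lr) && log(stats::runif(1)) < lr) tau[ch] <- prop
      if (spec$outcome == "rt") {
        sp <- sigma[ch] * exp(stats::rnorm(1, 0, 0.05))
        ll_prop <- loglik_by_p(beta[ch, ], u[ch, ], sp)
        lr <- sum(ll_prop) - sum(llp[ch, ]) +
          stats::dnorm(sp, 0, pr$sigma_sd, log = TRUE) -
          stats::dnorm(sigma[ch], 0, pr$sigma_sd, log = TRUE) +
          log(sp) - log(sigma[ch])
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          sigma[ch] <- sp
          llp[ch, ] <- ll_prop
        }
      }
    }
    # ensemble migration (symmetric state permutation)
    if (stats::runif(1) < 0.1) {
      sel <- sample.int(s$chains, 3L)
      perm <- c(sel[-1], sel[1])
      beta[sel, ] <- beta[perm, , drop = FALSE]
      u[sel, ] <- u[perm, , drop = FALSE]
      tau[sel] <- tau[perm]
      sigma[sel] <- sigma[perm]
      llp[sel, ] <- llp[perm, , drop = FALSE]
    }
    if (it > s$warmup) {
      i <- it - s$warmup
      out_beta[i, , ] <- beta
      out_tau[i, ] <- tau
      out_sigma[i, ] <- sigma
    }
  }
  structure(list(
    beta = out_beta, tau = out_tau,
    sigma = if (spec$outcome == "rt") out_sigma else NULL,
    u_final = u, spec = spec, settings = s,
    accept_beta = acc_beta / (total * s$chains)
  ), class = "behavioral_fit")
}

#' Evidence table for a behavioral fit
#'
#' One row per fixed effect: posterior mean, sd (reported as SE), 95%
#' credible interval, split R-hat, Savage-Dickey BF10 against zero for the
#' five non-intercept effects (the intercept has no point-null hypothesis
#' and gets `NA`), and the conventional evidence label.
#'
#' @param fit a `behavioral_fit`.
#' @return data.frame mirroring the coefficient-table layout of the study's
#'   behavioral analyses.
#' @export
behavioral_report <- function(fit) {
  stopifnot(inherits(fit, "behavioral_fit"))
  pr <- fit$spec$priors
  do.call(rbind, lapply(seq_along(fit$spec$effects), function(k) {
    nm <- fit$spec$effects[k]
    m <- fit$beta[, , k]
    pooled <- as.numeric(m)
    ci <- credible_interval(pooled)
    if (nm == "intercept") {
      bf <- NA_real_; label <- NA_character_
    } else {
      b <- savage_dickey_bf(pooled, stats::dnorm(0, 0, pr$fixed_sd))
      bf <- as.numeric(b)
      label <- as.character(classify_evidence(bf))
    }
    data.frame(outcome = fit$spec$outcome, effect = nm,
               estimate = mean(pooled), se = stats::sd(pooled), bf10 = bf,
               ci_lower = ci["lower"], ci_upper = ci["upper"],
               rhat = split_rhat(m), label = label, row.names = NULL)
  }))
}

#' Simulate decisions directly from a behavioral mixed-effects model
#'
#' Generates covariates resembling the competitive task (integer score
#' differences, time remaining within the deadline levels), standardizes
#' them internally, and draws the outcome from the specified logit or
#' log-normal model. Used for calibration and null-recovery checks of the
#' behavioral fitting route.
#'
#' @param outcome `"accuracy"` or `"rt"`.
#' @param beta numeric length-6 fixed-effect vector in the order
#'   intercept, score_diff_z, score_diff_z^2, time_remaining_z,
#'   time_remaining_z^2, interaction.
#' @param n_participants,n_per number of participants and decisions each.
#' @param tau random-intercept sd.
#' @param sigma residual sd of log-RT in log-ms (RT model only).
#' @param seed integer seed.
#' @return data.frame shaped like a prepared decisions table (covariates
#'   standardized, `excluded = FALSE`).
#' @export
simulate_behavioral_data <- function(outcome = c("accuracy", "rt"), beta,
                                     n_participants = 20L, n_per = 250L,
                                     tau = 0.3, sigma = 0.4, seed = 1L) {
  outcome <- match.arg(outcome)
  stopifnot(length(beta) == 6L)
  set.seed(seed)
  n <- n_participants * n_per
  pid <- rep(seq_len(n_participants), each = n_per)
  score_diff <- pmin(pmax(round(stats::rnorm(n, 0, 4)), -12), 12)
  deadline <- sample(c(5, 10, 20, 40), n, replace = TRUE)
  time_remaining <- stats::runif(n, 0, deadline)
  sdz <- as.numeric(scale(score_diff))
  trz <- as.numeric(scale(time_remaining))
  X <- cbind(1, sdz, sdz^2, trz, trz^2, sdz * trz)
  u <- stats::rnorm(n_participants, 0, tau)
  eta <- drop(X %*% beta) + u[pid]
  d <- data.frame(
    participant_id = pid,
    deadline_condition_s = deadline,
    score_diff = score_diff,
    time_remaining_s = time_remaining,
    score_diff_z = sdz, time_remaining_z = trz,
    interaction_z = sdz * trz,
    excluded = FALSE)
  if (outcome == "accuracy") {
    d$correct <- stats::rbinom(n, 1, stats::plogis(eta))
    d$rt_s <- stats::rlnorm(n, log(0.9), 0.3)  # filler column
  } else {
    d$rt_s <- exp(stats::rnorm(n, eta, sigma)) / 1000  # eta in log-ms
    d$correct <- stats::rbinom(n, 1, 0.77)
  }
  d
}

#' Descriptive behavioral summary
#'
#' Accuracy, mean response time in milliseconds, and win rate (ties count
#' against, as one of three distinct outcomes), overall and broken down by
#' deadline condition and by starting score difference.
#'
#' @param records decisions table (excluded rows dropped if flagged).
#' @param episodes episodes table with `outcome` (needed for win rates).
#' @return A list of data.frames: `overall`, `by_deadline`, `by_start_diff`.
#' @export
summarize_behavior <- function(records, episodes = NULL) {
  keep <- if ("excluded" %in% names(records)) !records$excluded else
    rep(TRUE, nrow(records))
  d <- records[keep, , drop = FALSE]
  win_rate <- function(out) if (length(out)) mean(out == "win") else NA_real_
  overall <- data.frame(
    n_decisions = nrow(d),
    accuracy = mean(as.numeric(d$correct)),
    mean_rt_ms = mean(d$rt_s) * 1000,
    win_rate = if (!is.null(episodes)) {
      ep <- episodes[!as.logical(episodes$is_practice %||% 0), , drop = FALSE]
      win_rate(ep$outcome)
    } else NA_real_)
  by_group <- function(var, evar) {
    acc <- tapply(as.numeric(d$correct), d[[var]], mean)
    rt <- tapply(d$rt_s, d[[var]], mean) * 1000
    g <- data.frame(level = as.numeric(names(acc)), accuracy = as.numeric(acc),
                    mean_rt_ms = as.numeric(rt))
    if (!is.null(episodes)) {
      wr <- tapply(episodes$outcome, episodes[[evar]], win_rate)
      g$win_rate <- as.numeric(wr[as.character(g$level)])
    }
    g
  }
  list(overall = overall,
       by_deadline = by_group("deadline_condition_s", "deadline_condition_s"),
       by_start_diff = by_group("start_diff", "start_diff"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
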