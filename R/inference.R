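# Hierarchical posterior sampling for the regression LBA, a fast
# per-participant maximum-likelihood mode, and the reporting statistics
# (Savage-Dickey Bayes factors, evidence labels, credible intervals).

# data-informed heuristic center for one participant's parameter vector
.heuristic_theta <- function(trials) {
  min_rt <- min(trials$rt_s)
  med_rt <- stats::median(trials$rt_s)
  t0 <- min(max(0.1, 0.6 * min_rt), 1, min_rt - 0.02)
  acc <- mean(as.numeric(trials$correct))
  vdiff <- stats::qnorm(min(max(acc, 0.55), 0.98)) * sqrt(2)
  b4 <- 1.2 + vdiff / 2
  v_inc <- b4 - vdiff
  b0 <- max(0.3, (med_rt - t0) * b4 * 0.8)
  participant_vector(A = 0.5, t0 = t0, v_incorrect = v_inc,
                     b0 = b0, b1 = 0, b2 = 0, b3 = 0,
                     b4 = b4, b5 = 0, b6 = 0, b7 = 0)
}

.jitter_theta <- function(theta, trials, scale = 1) {
  nm <- participant_parameter_names()
  sds <- c(A = 0.15, t0 = 0.03, v_incorrect = 0.25,
           b0 = 0.2, b1 = 0.02, b2 = 0.02, b3 = 0.02,
           b4 = 0.25, b5 = 0.03, b6 = 0.02, b7 = 0.02) * scale
  out <- theta + stats::rnorm(length(nm), 0, sds[nm])
  out[["A"]] <- max(out[["A"]], 0.01)
  out[["b0"]] <- max(out[["b0"]], 0.05)
  out[["t0"]] <- min(max(out[["t0"]], 0.1), 1, min(trials$rt_s) - 0.01)
  out
}

.pop_par_names <- function() {
  nm <- participant_parameter_names()
  c(paste0("mu_", nm), paste0("sigma_", nm))
}

#' Sample the hierarchical regression-LBA posterior
#'
#' Blocked differential-evolution MCMC over the joint posterior of all
#' per-participant 11-parameter vectors and the population
#' location/scale hyperparameters. Within each sweep every participant's
#' block is updated by a DE proposal (accepted against that participant's
#' likelihood plus their population prior), then each parameter's
#' `(mu, sigma)` pair is updated against the participant draws and the
#' weakly informative hyperprior. Gradient-free throughout.
#'
#' @param prepared prepared decisions ([prepare_decisions()]), or a list of
#'   per-participant trial data.frames.
#' @param settings list: `chains` (>= 8 recommended), `iterations`
#'   (post-warmup sweeps kept), `warmup`, `seed`, optional `eps` jitter,
#'   `thin_theta` (thinning for individual-level storage, default 5), and
#'   `init` (`"mle"`, the default, starts every chain at a jittered
#'   per-participant maximum-likelihood fit; `"heuristic"` uses cheap
#'   data summaries instead).
#' @param population_init optional [population_model()] used to center the
#'   initialization (only with `init = "heuristic"`; MLE initialization
#'   centers the hyperparameters on the fitted ensemble).
#' @param hyperprior from [default_hyperprior()].
#' @return An object of class `lba_posterior`: list with arrays
#'   `mu` and `sigma` (`iterations x chains x 11`), `theta`
#'   (`kept x chains x n_participants x 11`), acceptance rates, settings,
#'   and participant ids.
#' @export
sample_posterior <- function(prepared, settings = list(),
                             population_init = NULL,
                             hyperprior = default_hyperprior()) {
  s <- utils::modifyList(list(chains = 24L, iterations = 500L,
                              warmup = 500L, seed = 1L, eps = 1e-4,
                              thin_theta = 5L, init = "mle"), settings)
  if (s$chains < 8L) stop("need at least 8 chains (>= 2 for diagnostics, more for DE proposals)",
                          call. = FALSE)
  set.seed(s$seed)
  trials_by_p <- if (is.data.frame(prepared)) {
    ids <- unique(prepared$participant_id)
    stats::setNames(lapply(ids, function(i) participant_trials(prepared, i)),
                    ids)
  } else prepared
  sizes <- vapply(trials_by_p, function(tr) NROW(tr), integer(1))
  if (any(sizes == 0L)) {
    stop("participants with no retained trials cannot be fitted: ",
         paste(names(trials_by_p)[sizes == 0L], collapse = ", "),
         " (drop participants screened out by the accuracy rule first)",
         call. = FALSE)
  }
  n_p <- length(trials_by_p)
  nm <- participant_parameter_names()
  K <- length(nm)

  # initialization: per-participant centers (MLE or data heuristic),
  # jittered per chain, with capped retries until every participant block
  # has finite loglik
  theta <- array(NA_real_, c(s$chains, n_p, K),
                 dimnames = list(NULL, names(trials_by_p), nm))
  ll <- matrix(NA_real_, s$chains, n_p)
  centers <- matrix(NA_real_, n_p, K, dimnames = list(NULL, nm))
  if (is.matrix(s$init)) {
    stopifnot(nrow(s$init) == n_p, ncol(s$init) == K)
    centers[] <- s$init[, nm]
  } else {
    for (p in seq_len(n_p)) {
      tr <- trials_by_p[[p]]
      centers[p, ] <- if (identical(s$init, "mle")) {
        mle_fit(tr, n_starts = 2L)$theta
      } else .heuristic_theta(tr)
    }
  }
  for (p in seq_len(n_p)) {
    tr <- trials_by_p[[p]]
    center <- centers[p, ]
    for (ch in seq_len(s$chains)) {
      ok <- FALSE
      for (attempt in 1:100) {
        cand <- .jitter_theta(center, tr, scale = 1)
        l <- participant_loglik(cand, tr)
        if (is.finite(l)) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("initialization error: no finite starting point for participant ",
             names(trials_by_p)[p], call. = FALSE)
      }
      theta[ch, p, ] <- cand
      ll[ch, p] <- l
    }
  }
  lower <- c(A = 0, t0 = 0.1, v_incorrect = -Inf, b0 = 0,
             b1 = -Inf, b2 = -Inf, b3 = -Inf, b4 = -Inf,
             b5 = -Inf, b6 = -Inf, b7 = -Inf)[nm]
  upper <- c(A = Inf, t0 = 1, v_incorrect = Inf, b0 = Inf,
             b1 = Inf, b2 = Inf, b3 = Inf, b4 = Inf,
             b5 = Inf, b6 = Inf, b7 = Inf)[nm]
  if (is.matrix(s$init) || identical(s$init, "mle")) {
    mu0 <- colMeans(centers)
    sg0 <- pmax(apply(centers, 2, stats::sd), 0.02)
    if (anyNA(sg0)) sg0[is.na(sg0)] <- 0.1  # single participant
  } else {
    if (is.null(population_init)) population_init <- default_population()
    mu0 <- population_init$mu
    sg0 <- pmax(population_init$sigma, 0.05)
  }
  mu <- matrix(rep(mu0, each = s$chains), s$chains, K,
               dimnames = list(NULL, nm))
  mu <- mu + matrix(stats::rnorm(s$chains * K, 0, 0.05), s$chains, K)
  mu <- sweep(sweep(mu, 2, pmin(upper - 1e-3, 1e6), pmin),
              2, pmax(lower + 1e-3, -1e6), pmax)
  sg <- matrix(rep(sg0, each = s$chains), s$chains, K) *
    matrix(exp(stats::rnorm(s$chains * K, 0, 0.2)), s$chains, K)
  colnames(sg) <- nm

  # log density of participant values under the population; x, m, sd_ may be
  # vectors over parameters (k = NULL) or over participants (scalar k).
  # Only A, t0 and b0 are truncated, so renormalization touches only those.
  trunc_idx <- which(is.finite(lower) | is.finite(upper))
  pop_logdens <- function(x, m, sd_, k = NULL) {
    if (is.null(k)) {
      if (any(x < lower | x > upper)) return(-Inf)
      out <- dnorm(x, m, sd_, log = TRUE)
      zc <- pnorm(upper[trunc_idx], m[trunc_idx], sd_[trunc_idx]) -
        pnorm(lower[trunc_idx], m[trunc_idx], sd_[trunc_idx])
      sum(out) - sum(log(pmax(zc, .DENSITY_FLOOR)))
    } else {
      z <- pnorm(upper[k], m, sd_) - pnorm(lower[k], m, sd_)
      out <- dnorm(x, m, sd_, log = TRUE) - log(pmax(z, .DENSITY_FLOOR))
      out[x < lower[k] | x > upper[k]] <- -Inf
      out
    }
  }
  hyper_ld <- function(m, sd_, k) {
    if (sd_ <= 0) return(-Inf)
    if (m < lower[k] || m > upper[k]) return(-Inf)
    .dtnorm_log(m, hyperprior$centers[[nm[k]]], hyperprior$spread[[nm[k]]],
                lower[k], upper[k]) +
      stats::dnorm(sd_, 0, hyperprior$scale_sd[[nm[k]]], log = TRUE) + log(2)
  }

  total <- s$warmup + s$iterations
  keep_theta <- ceiling(s$iterations / s$thin_theta)
  out_mu <- array(NA_real_, c(s$iterations, s$chains, K),
                  dimnames = list(NULL, NULL, nm))
  out_sg <- out_mu
  out_theta <- array(NA_real_, c(keep_theta, s$chains, n_p, K),
                     dimnames = list(NULL, NULL, names(trials_by_p), nm))
  acc_theta <- 0; acc_hyper <- 0; kth <- 0L

  # cached population-prior value per (chain, participant)
  prior_cur <- matrix(NA_real_, s$chains, n_p)
  refresh_prior <- function() {
    for (ch in seq_len(s$chains)) {
      for (p in seq_len(n_p)) {
        prior_cur[ch, p] <<- sum(pop_logdens(theta[ch, p, ],
                                             mu[ch, ], sg[ch, ]))
      }
    }
  }
  refresh_prior()

  for (it in seq_len(total)) {
    # participant blocks: full-vector DE proposals, mixed with
    # random-subset proposals that move along the A/b0/t0/drift ridge
    for (p in seq_len(n_p)) {
      tr <- trials_by_p[[p]]
      for (ch in seq_len(s$chains)) {
        u <- stats::runif(1)
        if (u < 0.5) {
          idx <- sample.int(K, 2L)
          prop <- theta[ch, p, ]
          prop[idx] <- .de_proposal(theta[, p, ], ch, idx, s$eps)
        } else if (u < 0.75) {
          idx <- sample.int(K, 4L)
          prop <- theta[ch, p, ]
          prop[idx] <- .de_proposal(theta[, p, ], ch, idx, s$eps)
        } else {
          prop <- .de_proposal(theta[, p, ], ch, seq_len(K), s$eps)
        }
        names(prop) <- nm
        if (prop[["A"]] < 0 || prop[["b0"]] < 0 ||
            prop[["t0"]] < 0.1 || prop[["t0"]] > 1) next
        prior_prop <- sum(pop_logdens(prop, mu[ch, ], sg[ch, ]))
        if (!is.finite(prior_prop)) next
        l_prop <- participant_loglik(prop, tr)
        if (!is.finite(l_prop)) next
        if (log(stats::runif(1)) <
            (l_prop + prior_prop) - (ll[ch, p] + prior_cur[ch, p])) {
          theta[ch, p, ] <- prop
          ll[ch, p] <- l_prop
          prior_cur[ch, p] <- prior_prop
          acc_theta <- acc_theta + 1
        }
      }
    }
    # hyperparameter blocks: (mu_k, sigma_k) jointly per parameter
    for (k in seq_len(K)) {
      hstate <- cbind(mu[, k], sg[, k])
      for (ch in seq_len(s$chains)) {
        prop <- .de_proposal(hstate, ch, 1:2, s$eps)
        if (prop[2] <= 0) next
        cur <- sum(pop_logdens(theta[ch, , k], mu[ch, k], sg[ch, k], k)) +
          hyper_ld(mu[ch, k], sg[ch, k], k)
        new <- sum(pop_logdens(theta[ch, , k], prop[1], prop[2], k)) +
          hyper_ld(prop[1], prop[2], k)
        if (is.finite(new) && log(stats::runif(1)) < new - cur) {
          mu[ch, k] <- prop[1]; sg[ch, k] <- prop[2]
          hstate[ch, ] <- prop
          acc_hyper <- acc_hyper + 1
        }
      }
    }
    refresh_prior()
    # migration: cyclically permute the full states of a few random chains
    # (symmetric proposal on the product space, always accepted); stuck
    # chains inherit fresh difference vectors from elsewhere in the ensemble
    if (stats::runif(1) < 0.1) {
      sel <- sample.int(s$chains, 3L)
      perm <- c(sel[-1], sel[1])
      theta[sel, , ] <- theta[perm, , , drop = FALSE]
      mu[sel, ] <- mu[perm, , drop = FALSE]
      sg[sel, ] <- sg[perm, , drop = FALSE]
      ll[sel, ] <- ll[perm, , drop = FALSE]
      prior_cur[sel, ] <- prior_cur[perm, , drop = FALSE]
    }
    if (it > s$warmup) {
      i <- it - s$warmup
      out_mu[i, , ] <- mu
      out_sg[i, , ] <- sg
      if (i %% s$thin_theta == 0L || i == s$iterations) {
        kth <- min(kth + 1L, keep_theta)
        out_theta[kth, , , ] <- theta
      }
    }
  }
  structure(list(
    mu = out_mu, sigma = out_sg, theta = out_theta,
    participant_ids = names(trials_by_p),
    accept = c(theta = acc_theta / (total * s$chains * n_p),
               hyper = acc_hyper / (total * s$chains * K)),
    settings = s, hyperprior = hyperprior
  ), class = "lba_posterior")
}

#' @export
print.lba_posterior <- function(x, ...) {
  cat(sprintf(
    "Hierarchical LBA posterior: %d chains x %d iterations, %s participants\n",
    dim(x$mu)[2], dim(x$mu)[1], length(x$participant_ids)))
  cat(sprintf("acceptance: participant blocks %.2f, hyper blocks %.2f\n",
              x$accept["theta"], x$accept["hyper"]))
  invisible(x)
}

#' Pooled posterior draws of one population-level parameter
#'
#' @param fit an `lba_posterior` object.
#' @param parameter one of the 11 parameter names, e.g. `"b1"`.
#' @param what `"mu"` (location) or `"sigma"` (scale).
#' @param pooled if `FALSE`, return the `iterations x chains` matrix.
#' @return Numeric vector of pooled draws (or the matrix).
#' @export
population_draws <- function(fit, parameter, what = c("mu", "sigma"),
                             pooled = TRUE) {
  what <- match.arg(what)
  m <- fit[[what]][, , parameter]
  if (pooled) as.numeric(m) else m
}

#' Convergence summary for the population locations
#'
#' @param fit an `lba_posterior` object.
#' @return data.frame with parameter, posterior mean/sd, and split R-hat of
#'   the location draws.
#' @export
population_summary <- function(fit) {
  nm <- dimnames(fit$mu)[[3]]
  do.call(rbind, lapply(nm, function(k) {
    m <- fit$mu[, , k]
    data.frame(parameter = k, mean = mean(m), sd = stats::sd(m),
               rhat = split_rhat(m))
  }))
}

#' Maximum-likelihood fit for a single participant
#'
#' Multi-start bounded quasi-Newton maximization of
#' [participant_loglik()]; the fast route for parameter-recovery checks.
#' Infeasible regions (any trial's threshold offset driven nonpositive,
#' `t0` at or above the fastest response) are handled by a large finite
#' penalty so the optimizer stays in bounds.
#'
#' @param trials one participant's retained trials (see
#'   [participant_trials()]); 100+ trials recommended.
#' @param n_starts number of jittered starting points.
#' @return List with `theta` (named 11-vector), `loglik`, `converged`
#'   (logical: at least one start converged), `n_trials`.
#' @export
mle_fit <- function(trials, n_starts = 5L) {
  stopifnot(nrow(trials) >= 1L)
  nm <- participant_parameter_names()
  min_rt <- min(trials$rt_s)
  lower <- c(A = 1e-3, t0 = 0.1, v_incorrect = -5,
             b0 = 1e-3, b1 = -2, b2 = -2, b3 = -2,
             b4 = -5, b5 = -2, b6 = -2, b7 = -2)[nm]
  upper <- c(A = 5, t0 = min(1, min_rt - 1e-3), v_incorrect = 8,
             b0 = 8, b1 = 2, b2 = 2, b3 = 2,
             b4 = 10, b5 = 2, b6 = 2, b7 = 2)[nm]
  if (upper[["t0"]] <= lower[["t0"]]) {
    stop("fastest response time leaves no room for t0 >= 0.1 s",
         call. = FALSE)
  }
  neg_ll <- function(par) {
    names(par) <- nm
    l <- participant_loglik(par, trials)
    if (!is.finite(l)) 1e10 else -l
  }
  center <- .heuristic_theta(trials)
  center[["t0"]] <- min(center[["t0"]], upper[["t0"]])
  best <- NULL
  any_conv <- FALSE
  for (st in seq_len(n_starts)) {
    start <- if (st == 1L) center else .jitter_theta(center, trials)
    start <- pmin(pmax(start, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      stats::optim(start, neg_ll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  theta <- best$par
  names(theta) <- nm
  list(theta = theta, loglik = -best$value, converged = any_conv,
       n_trials = nrow(trials))
}

#' Savage-Dickey Bayes factor for a point null at zero
#'
#' `BF10 = p(0 | prior) / p(0 | posterior)`, with the posterior ordinate
#' estimated by a Gaussian kernel density (Silverman's rule bandwidth)
#' evaluated at zero. When the posterior has essentially no resolvable mass
#' at zero the BF is capped at `cap` and flagged via
#' `attr(, "capped")`.
#'
#' @param draws pooled posterior draws of the tested parameter (>= 1000
#'   recommended).
#' @param prior_density function returning the prior density at a point, or
#'   a single number giving the prior ordinate at zero.
#' @param bw kernel bandwidth (default Silverman's rule,
#'   [stats::bw.nrd0()]).
#' @param cap upper cap for the reported BF.
#' @return BF10 (numeric scalar, attribute `capped`).
#' @export
savage_dickey_bf <- function(draws, prior_density, bw = NULL, cap = 1e6) {
  draws <- as.numeric(draws)
  p0 <- if (is.function(prior_density)) prior_density(0) else prior_density
  if (!is.finite(p0) || p0 <= 0) {
    stop("prior density at 0 must be positive for a Savage-Dickey ratio",
         call. = FALSE)
  }
  if (is.null(bw)) bw <- stats::bw.nrd0(draws)
  if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(draws), 1e-8)
  post0 <- mean(stats::dnorm(0, mean = draws, sd = bw))
  capped <- FALSE
  bf <- p0 / post0
  if (!is.finite(bf) || bf > cap) { bf <- cap; capped <- TRUE }
  structure(bf, capped = capped)
}

#' Evidence-strength label for a Bayes factor
#'
#' Conventional bins: 1-3 anecdotal, 3-10 moderate, 10-30 strong, 30-100
#' very strong, above 100 extreme; Bayes factors below 1 are classified on
#' the reciprocal scale (evidence of absence, same strength words).
#'
#' @param bf10 Bayes factor for the effect versus the point null (> 0).
#' @return Character label; `attr(, "direction")` is `"presence"` or
#'   `"absence"`.
#' @export
classify_evidence <- function(bf10) {
  bf10 <- as.numeric(bf10)
  if (!is.finite(bf10) || bf10 <= 0) {
    stop("Bayes factor must be a positive number", call. = FALSE)
  }
  direction <- if (bf10 >= 1) "presence" else "absence"
  r <- max(bf10, 1 / bf10)
  label <- if (r > 100) "extreme" else if (r > 30) "very strong" else
    if (r > 10) "strong" else if (r > 3) "moderate" else "anecdotal"
  structure(label, direction = direction)
}

#' Equal-tailed credible interval
#'
#' @param draws posterior draws (>= 100 recommended).
#' @param level interval mass (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(as.numeric(draws), c(a, 1 - a), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Per-effect evidence report for a hierarchical LBA fit
#'
#' For each regression coefficient's population location: posterior mean and
#' sd, Savage-Dickey BF10 against zero (prior ordinate from the
#' location hyperprior), 95% credible interval, split R-hat, and the
#' conventional evidence label.
#'
#' @param fit an `lba_posterior` object.
#' @param effects parameter names to report (default the six regression
#'   slopes).
#' @return data.frame, one row per effect.
#' @export
evidence_report <- function(fit, effects = c("b1", "b2", "b3",
                                             "b5", "b6", "b7")) {
  hp <- fit$hyperprior
  do.call(rbind, lapply(effects, function(k) {
    m <- fit$mu[, , k]
    pooled <- as.numeric(m)
    prior0 <- stats::dnorm(0, hp$centers[[k]], hp$spread[[k]])
    bf <- savage_dickey_bf(pooled, prior0)
    ci <- credible_interval(pooled)
    data.frame(effect = k, estimate = mean(pooled), sd = stats::sd(pooled),
               bf10 = as.numeric(bf), ci_lower = ci["lower"],
               ci_upper = ci["upper"], rhat = split_rhat(m),
               label = as.character(classify_evidence(bf)),
               row.names = NULL)
  }))
}
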