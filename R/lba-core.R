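#' Construct and validate a set of LBA trial parameters
#'
#' Bundles the parameters governing one decision trial of the Linear
#' Ballistic Accumulator: evidence starts uniformly on \[0, A\], accumulates
#' linearly at a rate drawn (per trial, per accumulator) from a normal
#' distribution with mean `v[k]` and standard deviation `sv`, and a response
#' is made when one accumulator reaches the raw threshold `b = A + B`.
#' Response time is the crossing time plus the nondecision time `t0`.
#'
#' The task modeled here has exactly two response alternatives (left/right),
#' so `v` must have length 2.
#'
#' @param A maximum start point (evidence units, >= 0).
#' @param B threshold offset above the start-point range (evidence units,
#'   > 0); the raw threshold is `b = A + B`.
#' @param t0 nondecision time in seconds (>= 0).
#' @param v numeric length-2 vector of mean drift rates (evidence units per
#'   second), one per accumulator.
#' @param sv common drift-rate standard deviation (> 0; fixed to 1 in this
#'   study's model).
#'
#' @return An object of class `lba_params` with fields `A`, `B`, `b`, `t0`,
#'   `v`, `sv`.
#' @export
#' @examples
#' p <- lba_params(A = 0.5, B = 0.5, t0 = 0.2, v = c(2, 0.5))
#' p$b  # 1.0
lba_params <- function(A, B, t0, v, sv = 1) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(B), length(B) == 1L, is.finite(B),
            is.numeric(t0), length(t0) == 1L, is.finite(t0),
            is.numeric(v), length(v) == 2L, all(is.finite(v)),
            is.numeric(sv), length(sv) == 1L, is.finite(sv))
  if (A < 0) stop("A must be >= 0", call. = FALSE)
  if (B <= 0) stop("B must be > 0", call. = FALSE)
  if (t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  if (sv <= 0) stop("sv must be > 0", call. = FALSE)
  structure(
    list(A = A, B = B, b = A + B, t0 = t0, v = as.numeric(v), sv = sv),
    class = "lba_params"
  )
}

#' @export
print.lba_params <- function(x, ...) {
  cat(sprintf(
    "LBA parameters: A = %.4g, B = %.4g (b = %.4g), t0 = %.4g s, v = (%.4g, %.4g), sv = %.4g\n",
    x$A, x$B, x$b, x$t0, x$v[1], x$v[2], x$sv))
  invisible(x)
}

# clamp standard-normal arguments before pnorm/dnorm to keep the tails from
# overflowing into 0/1 exactly and breaking downstream logs
.clamp_z <- function(z, lim = 38) pmin(pmax(z, -lim), lim)

# smallest density we report before taking logs
.DENSITY_FLOOR <- 1e-300

.check_fp_args <- function(t, A, b, sv) {
  if (any(t < 0)) stop("decision time t must be >= 0", call. = FALSE)
  if (A < 0) stop("A must be >= 0", call. = FALSE)
  if (A > b) stop("invalid parameters: A exceeds raw threshold b", call. = FALSE)
  if (sv <= 0) stop("sv must be > 0", call. = FALSE)
}

#' Single-accumulator first-passage CDF
#'
#' Probability that one LBA accumulator — start uniform on \[0, A\], drift
#' normal with mean `v_mean` and sd `sv` — has crossed the raw threshold `b`
#' by decision time `t`. The distribution is defective: its limit as
#' `t -> Inf` is `pnorm(v_mean / sv)`, the probability of a positive drift,
#' because a negative-drift accumulator never finishes.
#'
#' Uses the standard closed form for the uniform-start/normal-drift racer;
#' for `A = 0` it reduces to `pnorm((v_mean - b / t) / sv)`, the crossing
#' probability of a fixed start at 0.
#'
#' @param t decision time in seconds (so response time minus `t0`); may be a
#'   vector.
#' @param A,b,v_mean,sv accumulator parameters (see [lba_params()]; `b` is
#'   the raw threshold).
#' @return Vector of crossing probabilities, one per element of `t`.
#' @export
lba_fp_cdf <- function(t, A, b, v_mean, sv = 1) {
  .check_fp_args(t, A, b, sv)
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos]
  if (A < 1e-12) {
    out[pos] <- stats::pnorm(.clamp_z((v_mean - b / tt) / sv))
  } else {
    ts <- tt * sv
    z1 <- .clamp_z((b - A - tt * v_mean) / ts)
    z2 <- .clamp_z((b - tt * v_mean) / ts)
    out[pos] <- 1 +
      ((b - A - tt * v_mean) / A) * stats::pnorm(z1) -
      ((b - tt * v_mean) / A) * stats::pnorm(z2) +
      (ts / A) * (stats::dnorm(z1) - stats::dnorm(z2))
  }
  pmin(pmax(out, 0), 1)
}

#' Single-accumulator first-passage density
#'
#' Density (per second) of the crossing time of one LBA accumulator at
#' decision time `t`; the time-derivative of [lba_fp_cdf()]. Zero at `t = 0`
#' and nonnegative everywhere.
#'
#' @inheritParams lba_fp_cdf
#' @return Vector of densities.
#' @export
lba_fp_pdf <- function(t, A, b, v_mean, sv = 1) {
  .check_fp_args(t, A, b, sv)
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos]
  if (A < 1e-12) {
    z <- .clamp_z((v_mean - b / tt) / sv)
    out[pos] <- stats::dnorm(z) * b / (sv * tt^2)
  } else {
    ts <- tt * sv
    z1 <- .clamp_z((b - A - tt * v_mean) / ts)
    z2 <- .clamp_z((b - tt * v_mean) / ts)
    out[pos] <- (1 / A) * (
      -v_mean * stats::pnorm(z1) + sv * stats::dnorm(z1) +
        v_mean * stats::pnorm(z2) - sv * stats::dnorm(z2))
  }
  pmax(out, 0)
}

#' Defective density of a two-accumulator race
#'
#' Joint density that accumulator `winner` crosses the threshold at decision
#' time `t` while the other accumulator has not yet crossed:
#' `f_winner(t) * (1 - F_other(t))`. Integrating over `t` gives the choice
#' probability for that response, so the density is "defective" — the two
#' response integrals sum to the probability that at least one drift is
#' positive, not to 1.
#'
#' @param t decision time in seconds (vectorized).
#' @param winner index of the winning accumulator (1 or 2).
#' @param params an [lba_params()] object.
#' @return Vector of defective densities.
#' @export
lba_defective_density <- function(t, winner, params) {
  stopifnot(inherits(params, "lba_params"))
  if (!(winner %in% c(1L, 2L))) {
    stop("winner must be accumulator index 1 or 2", call. = FALSE)
  }
  loser <- 3L - as.integer(winner)
  f <- lba_fp_pdf(t, params$A, params$b, params$v[winner], params$sv)
  Fo <- lba_fp_cdf(t, params$A, params$b, params$v[loser], params$sv)
  f * (1 - Fo)
}

#' Choice probability of one response
#'
#' Probability that accumulator `winner` wins the race, obtained by adaptive
#' quadrature of [lba_defective_density()] over decision time on
#' `(0, Inf)` (the defective CDF approaches its limit only polynomially, so
#' the semi-infinite transformation of [stats::integrate()] is used rather
#' than a finite cutoff). The two choice probabilities sum to
#' `1 - pnorm(-v[1]/sv) * pnorm(-v[2]/sv)` (1 minus the probability that
#' both drifts are negative, in which case no response is ever made).
#'
#' @param params an [lba_params()] object.
#' @param winner index of the response (1 or 2).
#' @return A probability in \[0, 1\].
#' @export
lba_choice_probability <- function(params, winner) {
  stopifnot(inherits(params, "lba_params"))
  f <- function(tt) lba_defective_density(tt, winner, params)
  # integrate over knots spanning the crossing-time scale: sharply peaked
  # densities (small sv relative to drift) occupy a narrow band that the
  # initial nodes of a single wide adaptive rule can miss entirely
  t_scale <- params$b / max(abs(params$v), params$sv, 0.1)
  knots <- t_scale * c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 3, 5, 10)
  res <- tryCatch({
    pieces <- vapply(seq_len(length(knots) - 1L), function(i) {
      stats::integrate(f, knots[i], knots[i + 1L], rel.tol = 1e-10,
                       abs.tol = 1e-13, subdivisions = 500L)$value
    }, numeric(1))
    tail <- stats::integrate(f, knots[length(knots)], Inf, rel.tol = 1e-10,
                             abs.tol = 1e-13, subdivisions = 1000L)
    sum(pieces) + tail$value
  }, error = function(e) stop("choice-probability quadrature failed: ",
                              conditionMessage(e), call. = FALSE))
  if (!is.finite(res)) {
    stop("choice-probability quadrature returned a non-finite value",
         call. = FALSE)
  }
  min(max(res, 0), 1)
}

#' Simulate LBA race trials
#'
#' Draws `n` independent trials from the race: start points uniform on
#' \[0, A\] and drift rates normal `(v[k], sv)` per accumulator. Drift
#' vectors in which both drifts are nonpositive are redrawn (no-response
#' trials are not emitted). The response time is `t0` plus the winning
#' crossing time.
#'
#' @param params an [lba_params()] object.
#' @param n number of trials.
#' @return A data.frame with columns `response` (1 or 2) and `rt` (seconds,
#'   strictly greater than `t0`).
#' @export
simulate_lba_trials <- function(params, n = 1L) {
  stopifnot(inherits(params, "lba_params"), n >= 1)
  n <- as.integer(n)
  drift1 <- stats::rnorm(n, params$v[1], params$sv)
  drift2 <- stats::rnorm(n, params$v[2], params$sv)
  bad <- drift1 <= 0 & drift2 <= 0
  guard <- 0L
  while (any(bad)) {
    k <- sum(bad)
    drift1[bad] <- stats::rnorm(k, params$v[1], params$sv)
    drift2[bad] <- stats::rnorm(k, params$v[2], params$sv)
    bad <- drift1 <= 0 & drift2 <= 0
    guard <- guard + 1L
    if (guard > 10000L) stop("drift redraw did not terminate", call. = FALSE)
  }
  start1 <- stats::runif(n, 0, params$A)
  start2 <- stats::runif(n, 0, params$A)
  t1 <- ifelse(drift1 > 0, (params$b - start1) / drift1, Inf)
  t2 <- ifelse(drift2 > 0, (params$b - start2) / drift2, Inf)
  response <- ifelse(t1 <= t2, 1L, 2L)
  rt <- params$t0 + pmin(t1, t2)
  data.frame(response = response, rt = rt)
}

#' Simulate a single decision trial
#'
#' One draw from [simulate_lba_trials()] scored against the true stimulus
#' direction.
#'
#' @param params an [lba_params()] object whose accumulator 1 is "left" and
#'   accumulator 2 is "right".
#' @param true_direction 1 or 2, the stimulus direction.
#' @return A list with `response`, `rt`, and `correct`.
#' @export
simulate_lba_trial <- function(params, true_direction) {
  stopifnot(true_direction %in% c(1L, 2L))
  d <- simulate_lba_trials(params, 1L)
  list(response = d$response[1], rt = d$rt[1],
       correct = d$response[1] == as.integer(true_direction))
}

#' Log-likelihood of one observed decision
#'
#' Log of the (unnormalized) defective density of the race evaluated at the
#' observed decision time `rt - t0` for the observed response. Following
#' standard practice for this model the density is not renormalized by the
#' probability of at least one positive drift. Observations with
#' `rt <= t0` are impossible under the parameters and return `-Inf`.
#'
#' @param rt observed response time in seconds (vectorized).
#' @param response observed response index (1 or 2, vectorized or scalar).
#' @param params an [lba_params()] object.
#' @return Vector of log densities (with `-Inf` sentinels), floored at
#'   `log(1e-300)`... in the sense that positive decision times never map
#'   below that floor; impossible times map to `-Inf` exactly.
#' @export
lba_trial_loglik <- function(rt, response, params) {
  stopifnot(inherits(params, "lba_params"))
  n <- max(length(rt), length(response))
  rt <- rep_len(rt, n); response <- rep_len(as.integer(response), n)
  t <- rt - params$t0
  out <- rep(-Inf, n)
  ok <- t > 0
  for (w in 1:2) {
    sel <- ok & response == w
    if (any(sel)) {
      dens <- lba_defective_density(t[sel], w, params)
      out[sel] <- log(pmax(dens, .DENSITY_FLOOR))
    }
  }
  out
}
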