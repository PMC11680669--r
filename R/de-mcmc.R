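# Gradient-free differential-evolution MCMC (DE-MC): each chain proposes
# jumps along the difference of two other randomly chosen chains, scaled by
# gamma, plus a small uniform jitter. No likelihood gradients are needed,
# which suits the LBA defective density. Occasional gamma = 1 proposals
# allow mode jumping.

.de_gamma <- function(d, p_full = 0.1) {
  if (stats::runif(1) < p_full) 1 else 2.38 / sqrt(2 * d)
}

.de_proposal <- function(state, chain, idx_pars, eps) {
  n_chains <- nrow(state)
  # two distinct chains other than `chain`, without the setdiff allocation
  o <- sample.int(n_chains - 1L, 2L)
  o[o >= chain] <- o[o >= chain] + 1L
  d <- length(idx_pars)
  g <- .de_gamma(d)
  state[chain, idx_pars] +
    g * (state[o[1], idx_pars] - state[o[2], idx_pars]) +
    stats::runif(d, -eps, eps)
}

#' Differential-evolution MCMC for a generic log posterior
#'
#' Full-vector DE-MC over `n_chains` interacting chains. Intended for
#' low-to-moderate dimension targets (toy calibration problems, marginal
#' checks); the hierarchical LBA and behavioral models use dedicated blocked
#' samplers built on the same proposal.
#'
#' @param log_post function taking a numeric parameter vector, returning a
#'   log posterior density (`-Inf` allowed).
#' @param init numeric matrix `n_chains x d` of starting points (every row
#'   must have finite log posterior).
#' @param iterations post-warmup iterations to keep.
#' @param warmup iterations discarded from the front.
#' @param eps half-width of the uniform proposal jitter.
#' @param seed integer seed (optional; caller may also seed externally).
#' @return A list with `draws` (array `iterations x n_chains x d`), `lp`
#'   (matrix `iterations x n_chains`), and `accept_rate`.
#' @export
de_mcmc <- function(log_post, init, iterations, warmup = iterations,
                    eps = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  init <- as.matrix(init)
  n_chains <- nrow(init); d <- ncol(init)
  if (n_chains < 4L) stop("DE-MC needs at least 4 chains", call. = FALSE)
  state <- init
  lp <- apply(state, 1, log_post)
  if (any(!is.finite(lp))) {
    stop("initialization error: some chains start at -Inf log posterior",
         call. = FALSE)
  }
  total <- warmup + iterations
  draws <- array(NA_real_, c(iterations, n_chains, d))
  lp_out <- matrix(NA_real_, iterations, n_chains)
  acc <- 0L
  for (it in seq_len(total)) {
    for (ch in seq_len(n_chains)) {
      prop <- .de_proposal(state, ch, seq_len(d), eps)
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp[ch]) {
        state[ch, ] <- prop
        lp[ch] <- lp_prop
        acc <- acc + 1L
      }
    }
    if (it > warmup) {
      draws[it - warmup, , ] <- state
      lp_out[it - warmup, ] <- lp
    }
  }
  dimnames(draws) <- list(NULL, NULL, colnames(init))
  list(draws = draws, lp = lp_out,
       accept_rate = acc / (total * n_chains))
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half and the classical between/within variance
#' comparison is applied to the resulting half-chains. Values near 1
#' indicate convergence. Chains with zero total variance (constant draws)
#' return exactly 1, treated as converged-degenerate.
#'
#' @param draws matrix of draws for one scalar parameter, `iterations x
#'   chains` (or an `iterations x chains x 1` array).
#' @return The split R-hat value (>= 1 up to numerical tolerance).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(drop(draws))
  n <- nrow(draws); m <- ncol(draws)
  if (m < 2L) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (n < 4L) stop("R-hat needs at least 4 draws per chain", call. = FALSE)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  mns <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (W <= .Machine$double.eps * max(abs(mns), 1)^2) return(1)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}
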