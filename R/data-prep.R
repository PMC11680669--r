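# Exclusion rules and covariate construction: raw decision tables in,
# model-ready tables out. Rows are flagged, never deleted.

#' Flag trials excluded by the response-time and practice rules
#'
#' Decisions with `rt_s <= 0.250` (too quick: "250 ms or fewer"), with
#' `rt_s >= 5.0` (too slow: "5 seconds or longer"; both boundaries
#' inclusive), and practice-episode decisions are flagged. All rows are
#' retained.
#'
#' @param records decisions data.frame with at least `rt_s` (and optionally
#'   `is_practice`).
#' @param rt_min_s,rt_max_s inclusive response-time cutoffs in seconds.
#' @return `records` with logical `excluded` and character
#'   `exclusion_reason` columns (reason `NA` where retained); existing flags
#'   are recomputed, so the operation is idempotent.
#' @export
exclude_trials <- function(records, rt_min_s = 0.250, rt_max_s = 5.0) {
  if (!"rt_s" %in% names(records)) {
    stop("records lack an 'rt_s' column", call. = FALSE)
  }
  if (anyNA(records$rt_s)) stop("rt_s contains missing values", call. = FALSE)
  practice <- if ("is_practice" %in% names(records)) {
    as.logical(records$is_practice)
  } else rep(FALSE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  reason[records$rt_s >= rt_max_s] <- "rt_too_slow"
  reason[records$rt_s <= rt_min_s] <- "rt_too_fast"
  reason[practice] <- "practice"
  prior <- if ("exclusion_reason" %in% names(records)) {
    keep <- records$exclusion_reason %in% "low_accuracy"
    ifelse(keep & is.na(reason), "low_accuracy", reason)
  } else reason
  records$excluded <- !is.na(prior)
  records$exclusion_reason <- prior
  records
}

#' Flag all decisions of participants below the accuracy cutoff
#'
#' A participant whose overall accuracy on non-practice trials (computed
#' before any response-time exclusion) is strictly below `min_accuracy` has
#' every row flagged with reason `"low_accuracy"`. Participants at exactly
#' the cutoff are retained.
#'
#' @param records decisions data.frame with `participant_id`, `correct`
#'   (and optionally `is_practice`).
#' @param min_accuracy accuracy cutoff (default 0.55).
#' @return `records` with `excluded` / `exclusion_reason` updated.
#' @export
exclude_participants <- function(records, min_accuracy = 0.55) {
  stopifnot(all(c("participant_id", "correct") %in% names(records)))
  practice <- if ("is_practice" %in% names(records)) {
    as.logical(records$is_practice)
  } else rep(FALSE, nrow(records))
  scored <- records[!practice, , drop = FALSE]
  acc <- tapply(as.numeric(scored$correct), scored$participant_id, mean)
  low <- names(acc)[acc < min_accuracy]
  hit <- as.character(records$participant_id) %in% low
  if (!"exclusion_reason" %in% names(records)) {
    records$excluded <- FALSE
    records$exclusion_reason <- NA_character_
  }
  # the participant screen takes precedence over trial-level reasons
  records$exclusion_reason[hit] <- "low_accuracy"
  records$excluded <- !is.na(records$exclusion_reason)
  records
}

#' Standardize the trial-level covariates
#'
#' Z-scores `score_diff` and `time_remaining_s` over the retained
#' (non-excluded) decisions pooled across participants, or with supplied
#' constants (e.g. the generator's reference scaling, for recovery
#' analyses where the generating and estimated coefficients must share a
#' scale). The interaction is the product of the two standardized terms.
#'
#' @param records decisions data.frame that has been through the exclusion
#'   operations (rows with `excluded = TRUE` do not contribute to the
#'   constants and receive `NA` covariates).
#' @param scaling `NULL` (derive constants from retained rows, sd with
#'   denominator n−1) or a list as returned by [default_scaling()].
#' @return `records` with columns `score_diff_z`, `time_remaining_z`,
#'   `interaction_z` added and the constants in
#'   `attr(, "scaling")`.
#' @export
standardize_covariates <- function(records, scaling = NULL) {
  stopifnot(all(c("score_diff", "time_remaining_s") %in% names(records)))
  keep <- if ("excluded" %in% names(records)) !records$excluded else
    rep(TRUE, nrow(records))
  if (is.null(scaling)) {
    sd_sd <- stats::sd(records$score_diff[keep])
    tr_sd <- stats::sd(records$time_remaining_s[keep])
    if (!sum(keep) || !is.finite(sd_sd) || !is.finite(tr_sd) ||
        sd_sd == 0 || tr_sd == 0) {
      stop("degenerate covariates: zero variance among retained decisions",
           call. = FALSE)
    }
    scaling <- list(
      score_diff = list(mean = mean(records$score_diff[keep]), sd = sd_sd),
      time_remaining = list(mean = mean(records$time_remaining_s[keep]),
                            sd = tr_sd))
  }
  records$score_diff_z <- NA_real_
  records$time_remaining_z <- NA_real_
  records$score_diff_z[keep] <-
    .standardize_with(records$score_diff[keep], scaling$score_diff)
  records$time_remaining_z[keep] <-
    .standardize_with(records$time_remaining_s[keep], scaling$time_remaining)
  records$interaction_z <- records$score_diff_z * records$time_remaining_z
  attr(records, "scaling") <- scaling
  records
}

#' Full preparation pipeline
#'
#' Participant accuracy screen, then trial-level response-time/practice
#' flags, then covariate standardization — the order the study's exclusion
#' description implies.
#'
#' @inheritParams exclude_trials
#' @inheritParams exclude_participants
#' @inheritParams standardize_covariates
#' @return The flagged, standardized decisions data.frame; exclusion
#'   tallies in `attr(, "exclusion_tally")`, constants in
#'   `attr(, "scaling")`.
#' @export
prepare_decisions <- function(records, rt_min_s = 0.250, rt_max_s = 5.0,
                              min_accuracy = 0.55, scaling = NULL) {
  if (!nrow(records)) stop("empty decisions table", call. = FALSE)
  out <- exclude_participants(records, min_accuracy)
  out <- exclude_trials(out, rt_min_s, rt_max_s)
  tally <- table(out$exclusion_reason, useNA = "no")
  out <- standardize_covariates(out, scaling)
  attr(out, "exclusion_tally") <- c(
    as.list(tally),
    list(n_total = nrow(out), n_excluded = sum(out$excluded),
         fraction_excluded = mean(out$excluded)))
  out
}

#' Retained decisions of one participant, ready for the likelihood
#'
#' @param prepared output of [prepare_decisions()].
#' @param id participant identifier.
#' @return data.frame of that participant's retained trials with the
#'   standardized covariates and a logical `correct`.
#' @export
participant_trials <- function(prepared, id) {
  d <- prepared[prepared$participant_id == id & !prepared$excluded, ,
                drop = FALSE]
  d$correct <- as.logical(d$correct)
  d
}
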