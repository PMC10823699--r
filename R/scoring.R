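#' Indifference point implied by one delay series
#'
#' The staircase is a bisection: after the final titration trial the
#' offer that *would* be shown on a hypothetical next trial is the
#' midpoint of the last bracketing interval, and is taken as the
#' indifference point. For the default design it equals
#' `500 + sum(s_t * 500 / 2^t)` over the six trials, with `s_t = +1`
#' when the future option was chosen and `-1` otherwise, so every
#' estimate is an odd multiple of `500/64` strictly inside `(0, 1000)`.
#'
#' @param choices Character vector of `"present"` / `"future"` tokens,
#'   one per titration trial of the series, in presentation order.
#' @param config A [task_config()].
#' @return The indifference point in dollars.
#' @export
#' @examples
#' indifference_point(rep("future", 6), task_config())   # 992.1875
#' indifference_point(rep("present", 6), task_config())  # 7.8125
indifference_point <- function(choices, config) {
  stopifnot(inherits(config, "dd_task_config"))
  if (length(choices) != config$trials_per_delay)
    stop_domain("malformed series: expected ", config$trials_per_delay,
                " choices, got ", length(choices))
  if (!all(choices %in% c("present", "future")))
    stop_domain("malformed series: invalid choice token")
  s <- ifelse(choices == "future", 1, -1)
  steps <- config$initial_present / 2^seq_along(s)
  config$initial_present + sum(s * steps)
}

#' Per-delay discount rate from an indifference point
#'
#' Inverts the hyperbolic value function at the point of indifference:
#' if an immediate `indifference_point` matches `future_amount` at
#' delay `D`, then `k = (future_amount / indifference_point - 1) / D`
#' per day. Strictly positive because staircase estimates never touch
#' the interval bounds.
#'
#' @param indifference_point Immediate amount in dollars, strictly
#'   between 0 and `future_amount`.
#' @param delay_days Delay in days (> 0).
#' @param future_amount The constant delayed amount.
#' @return Discount rate per day; vectorized.
#' @export
#' @examples
#' k_from_indifference(500, 30, 1000)  # 1/30
k_from_indifference <- function(indifference_point, delay_days,
                                future_amount = 1000) {
  if (any(indifference_point <= 0) || any(indifference_point >= future_amount))
    stop_domain("indifference point must lie strictly in (0, future_amount)")
  if (any(delay_days <= 0))
    stop_domain("delay_days must be positive")
  (future_amount / indifference_point - 1) / delay_days
}

#' Score one session
#'
#' Converts a completed session into the task's outcome measure: the
#' per-delay indifference points and discount rates, their arithmetic
#' mean `k`, its natural log `ln_k`, and the catch-trial validity
#' decision. The order of operations is average-then-log: `k` is the
#' mean of the seven per-delay rates and `ln_k = log(k)`. Participants
#' at or below 50% catch accuracy are flagged invalid.
#'
#' @param session A `dd_session` from [run_session()].
#' @param config The [task_config()] the session was run under.
#' @return An object of class `dd_score` with fields `participant_id`,
#'   `profile` (data frame of `delay_days`, `indifference_point`,
#'   `k_d`), `k`, `ln_k`, `catch_correct`, `catch_total`, `valid`.
#' @export
#' @examples
#' patient <- dd_agent("deterministic_hyperbolic", k_true = 0.01)
#' score_session(run_session(patient, task_config(), seed = 1), task_config())
score_session <- function(session, config) {
  stopifnot(inherits(session, "dd_session"), inherits(config, "dd_task_config"))
  score_trials(session$trials, config, participant_id = session$participant_id)
}

# Shared worker: score a per-trial table (from a live session or a
# session-log CSV). Catch correctness is read from the `correct` column
# when present, else derived from choice vs correct_option.
score_trials <- function(trials, config, participant_id) {
  tit <- trials[!trials$is_catch, , drop = FALSE]
  if (nrow(tit) != length(config$delays) * config$trials_per_delay ||
      anyNA(tit$choice))
    stop_domain("malformed session for ", participant_id,
                ": missing or extra titration choices")
  tit <- tit[order(tit$delay_days, tit$global_index), , drop = FALSE]
  profile <- do.call(rbind, lapply(split(tit, tit$delay_days), function(d) {
    ip <- indifference_point(d$choice, config)
    data.frame(delay_days = d$delay_days[1],
               indifference_point = ip,
               k_d = k_from_indifference(ip, d$delay_days[1],
                                         config$future_amount))
  }))
  profile <- profile[order(profile$delay_days), , drop = FALSE]
  rownames(profile) <- NULL

  catch <- trials[trials$is_catch, , drop = FALSE]
  if (nrow(catch) > 0 && anyNA(catch$choice))
    stop_domain("malformed session for ", participant_id,
                ": missing catch-trial choices")
  correct <- if (nrow(catch) == 0) logical(0)
    else if (!is.null(catch$correct) && !anyNA(catch$correct)) as.logical(catch$correct)
    else catch$choice == catch$correct_option
  catch_correct <- sum(correct)
  catch_total <- nrow(catch)

  k <- mean(profile$k_d)
  structure(list(participant_id = participant_id,
                 profile = profile,
                 k = k,
                 ln_k = log(k),
                 catch_correct = as.integer(catch_correct),
                 catch_total = as.integer(catch_total),
                 valid = catch_total == 0 || catch_correct / catch_total > 0.5),
            class = "dd_score")
}

#' @export
print.dd_score <- function(x, ...) {
  cat(sprintf("Discounting score for %s: k = %.6g per day, ln(k) = %.3f\n",
              x$participant_id, x$k, x$ln_k))
  cat(sprintf("  catch accuracy %d/%d -> %s\n", x$catch_correct, x$catch_total,
              if (x$valid) "valid" else "excluded (<= 50%)"))
  invisible(x)
}

#' Flatten scores to a table
#'
#' One row per participant with `k`, `ln_k`, catch counts, the validity
#' flag, and the per-delay `(delay, indifference point, k_d)` triples in
#' wide columns.
#'
#' @param scores A `dd_score` or list of them.
#' @return A data frame.
#' @export
scores_table <- function(scores) {
  if (inherits(scores, "dd_score")) scores <- list(scores)
  do.call(rbind, lapply(scores, function(s) {
    row <- data.frame(participant_id = s$participant_id,
                      k = s$k, ln_k = s$ln_k,
                      catch_correct = s$catch_correct,
                      catch_total = s$catch_total,
                      valid = s$valid)
    for (i in seq_len(nrow(s$profile))) {
      row[[paste0("delay_", i)]] <- s$profile$delay_days[i]
      row[[paste0("indifference_", i)]] <- s$profile$indifference_point[i]
      row[[paste0("k_d_", i)]] <- s$profile$k_d[i]
    }
    row
  }))
}

#' Partition scores by catch-trial validity
#'
#' Applies the exclusion rule: participants whose catch accuracy is at
#' or below 50% are excluded; order is preserved in both partitions.
#'
#' @param scores A data frame with a logical `valid` column (e.g. from
#'   [scores_table()]), or a list of `dd_score` objects.
#' @return A list with elements `retained` and `excluded`.
#' @export
apply_exclusions <- function(scores) {
  if (is.data.frame(scores)) {
    list(retained = scores[scores$valid, , drop = FALSE],
         excluded = scores[!scores$valid, , drop = FALSE])
  } else {
    valid <- vapply(scores, `[[`, logical(1), "valid")
    list(retained = scores[valid], excluded = scores[!valid])
  }
}
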