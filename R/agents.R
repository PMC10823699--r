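#' Simulated responders for the delay-discounting task
#'
#' Agents turn a presented trial into a choice token. Three kinds are
#' provided:
#' \describe{
#'   \item{`deterministic_hyperbolic`}{Always picks the option with the
#'     higher hyperbolic present value `A / (1 + k * D)`; exact ties go
#'     to the future option.}
#'   \item{`logistic_hyperbolic`}{Picks the future option with
#'     probability `plogis(inverse_temperature * (V_future -
#'     V_present))`, the standard softmax choice rule; at
#'     `inverse_temperature = 0` choices are coin flips, and as it grows
#'     the agent converges to the deterministic discounter.}
#'   \item{`inattentive`}{Picks uniformly at random on titration trials.}
#' }
#' All kinds answer catch trials correctly with probability
#' `1 - catch_error_rate`.
#'
#' The task's scoring assumes no particular choice model; the
#' hyperbolic form here is the standard model for this family of
#' monetary-choice tasks and supplies the ground truth for parameter
#' recovery. See the package vignette for why this assumption is
#' flagged.
#'
#' @param kind Agent kind, see Details.
#' @param k_true True discount rate per day (> 0); required by the two
#'   hyperbolic kinds.
#' @param inverse_temperature Non-negative choice-noise scale for the
#'   logistic kind, in units of 1/dollars of value difference.
#' @param catch_error_rate Probability in `[0, 1]` of answering a catch
#'   trial incorrectly. Defaults to 0, or 0.5 for inattentive agents.
#' @return An object of class `dd_agent`.
#' @export
#' @examples
#' dd_agent("deterministic_hyperbolic", k_true = 0.01)
#' dd_agent("logistic_hyperbolic", k_true = 0.01, inverse_temperature = 0.05)
dd_agent <- function(kind = c("deterministic_hyperbolic",
                              "logistic_hyperbolic",
                              "inattentive"),
                     k_true = NULL,
                     inverse_temperature = NULL,
                     catch_error_rate = NULL) {
  kind <- match.arg(kind)
  if (is.null(catch_error_rate))
    catch_error_rate <- if (kind == "inattentive") 0.5 else 0
  if (catch_error_rate < 0 || catch_error_rate > 1)
    stop_domain("catch_error_rate must lie in [0, 1]")
  if (kind %in% c("deterministic_hyperbolic", "logistic_hyperbolic")) {
    if (is.null(k_true) || k_true <= 0)
      stop_domain("hyperbolic agents require k_true > 0")
  }
  if (kind == "logistic_hyperbolic") {
    if (is.null(inverse_temperature) || inverse_temperature < 0)
      stop_domain("logistic agents require inverse_temperature >= 0")
  }
  structure(list(kind = kind, k_true = k_true,
                 inverse_temperature = inverse_temperature,
                 catch_error_rate = catch_error_rate),
            class = "dd_agent")
}

#' @export
print.dd_agent <- function(x, ...) {
  cat("Simulated responder:", x$kind, "\n")
  if (!is.null(x$k_true))
    cat(sprintf("  k_true = %g per day (ln k = %.3f)\n", x$k_true, log(x$k_true)))
  if (!is.null(x$inverse_temperature))
    cat(sprintf("  inverse temperature = %g\n", x$inverse_temperature))
  cat(sprintf("  catch error rate = %g\n", x$catch_error_rate))
  invisible(x)
}

#' Hyperbolic present value of a delayed amount
#'
#' `V = amount / (1 + k * delay)`: the subjective value of `amount`
#' received after `delay` days under hyperbolic discounting with rate
#' `k` per day. Equals `amount` when `k = 0` or `delay = 0` and
#' decreases strictly in both `k` and `delay` otherwise.
#'
#' @param amount Amount in dollars (>= 0).
#' @param k Discount rate per day (>= 0).
#' @param delay Delay in days (>= 0).
#' @return Subjective value in dollars; vectorized over its arguments.
#' @export
#' @examples
#' hyperbolic_value(1000, 0.01, 30)  # 1000 / 1.3
hyperbolic_value <- function(amount, k, delay) {
  if (any(amount < 0) || any(k < 0) || any(delay < 0))
    stop_domain("hyperbolic_value() requires non-negative inputs")
  amount / (1 + k * delay)
}

#' Query an agent for a choice on one trial
#'
#' Applies the agent's choice rule to a fully specified trial. On
#' titration trials the return token is `"present"` or `"future"`; on
#' catch trials it is `"a"` or `"b"`, chosen correctly with probability
#' `1 - catch_error_rate`. Stochastic agents draw from the current RNG
#' stream; [run_session()] seeds that stream per session so choices are
#' reproducible.
#'
#' @param agent A [dd_agent()].
#' @param trial A single-trial list or one-row data frame from
#'   [build_schedule()] with `present_offer` resolved.
#' @return A choice token.
#' @export
agent_choice <- function(agent, trial) {
  stopifnot(inherits(agent, "dd_agent"))
  trial <- as.list(trial)
  if (isTRUE(trial$is_catch)) {
    wrong <- stats::runif(1) < agent$catch_error_rate
    other <- c(a = "b", b = "a")
    return(if (wrong) other[[trial$correct_option]] else trial$correct_option)
  }
  if (is.na(trial$present_offer) || is.na(trial$future_offer) ||
      is.na(trial$delay_days))
    stop_domain("malformed trial: unresolved offer or delay")
  switch(agent$kind,
    deterministic_hyperbolic = {
      v_future <- hyperbolic_value(trial$future_offer, agent$k_true,
                                   trial$delay_days)
      # tie at exact indifference breaks to the future option
      if (trial$present_offer > v_future) "present" else "future"
    },
    logistic_hyperbolic = {
      v_future <- hyperbolic_value(trial$future_offer, agent$k_true,
                                   trial$delay_days)
      p_future <- stats::plogis(agent$inverse_temperature *
                                  (v_future - trial$present_offer))
      if (stats::runif(1) < p_future) "future" else "present"
    },
    inattentive = if (stats::runif(1) < 0.5) "future" else "present"
  )
}
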