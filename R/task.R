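#' Catch-trial specification
#'
#' A catch trial offers two dated amounts where one option strictly
#' dominates the other (at least as much money, no later, with at least
#' one strict inequality). Inattentive responders are detected by their
#' accuracy on these trials.
#'
#' @param a_amount,a_delay Amount (dollars) and delay (days) of option A.
#' @param b_amount,b_delay Amount and delay of option B.
#' @param correct Which option dominates, `"a"` or `"b"`.
#' @return An object of class `dd_catch_spec`.
#' @export
#' @examples
#' catch_spec(1000, 0, 500, 1825, correct = "a")
catch_spec <- function(a_amount, a_delay, b_amount, b_delay,
                       correct = c("a", "b")) {
  correct <- match.arg(correct)
  if (min(a_amount, b_amount) < 0 || min(a_delay, b_delay) < 0)
    stop_domain("catch-trial amounts and delays must be non-negative")
  dom <- function(x_amt, x_del, y_amt, y_del) {
    x_amt >= y_amt && x_del <= y_del && (x_amt > y_amt || x_del < y_del)
  }
  a_dom <- dom(a_amount, a_delay, b_amount, b_delay)
  b_dom <- dom(b_amount, b_delay, a_amount, a_delay)
  if (identical(a_dom, b_dom))
    stop_domain("exactly one catch-trial option must strictly dominate")
  if ((correct == "a") != a_dom)
    stop_domain("`correct` must name the dominating option")
  structure(list(a_amount = a_amount, a_delay = a_delay,
                 b_amount = b_amount, b_delay = b_delay,
                 correct = correct),
            class = "dd_catch_spec")
}

#' Default catch trials
#'
#' Four dominant-option attention checks used by the default task
#' design; each pairs a strictly better dated amount against a strictly
#' worse one.
#'
#' @return A list of four [catch_spec()] objects.
#' @export
default_catch_trials <- function() {
  list(catch_spec(1000, 0,    500,  1825, correct = "a"),
       catch_spec(500,  3650, 1000, 14,   correct = "b"),
       catch_spec(1000, 30,   250,  365,  correct = "a"),
       catch_spec(100,  1095, 1000, 7,    correct = "b"))
}

#' Configure the adaptive delay-discounting task
#'
#' Defines the titration design: a fixed future amount offered at each
#' of several delays, against a present amount that starts at
#' `initial_present` and is adjusted by a halving rule after every
#' choice. The default design presents $1,000 at seven delays (two
#' weeks to ten years), six titration trials per delay, plus four catch
#' trials interleaved at fixed positions -- 46 trials in all.
#'
#' @param future_amount Constant delayed amount in dollars.
#' @param initial_present Present-amount anchor for the first trial of
#'   every delay series; also sets the step sizes
#'   `initial_present / 2^t`.
#' @param delays Strictly increasing delays in days. The defaults encode
#'   two weeks, one month, six months, one year, three years, five
#'   years, and ten years with month = 30 and year = 365 days.
#' @param trials_per_delay Number of titration trials per delay series.
#' @param catch_trials List of [catch_spec()] objects.
#' @param catch_positions 1-based positions of the catch trials in the
#'   global trial order; must be distinct and within the total length.
#' @return An object of class `dd_task_config`.
#' @export
#' @examples
#' config <- task_config()
#' config$total_trials  # 46
task_config <- function(future_amount = 1000,
                        initial_present = 500,
                        delays = c(14, 30, 182, 365, 1095, 1825, 3650),
                        trials_per_delay = 6,
                        catch_trials = default_catch_trials(),
                        catch_positions = c(12, 23, 34, 45)) {
  if (!(future_amount > initial_present && initial_present > 0))
    stop_domain("need future_amount > initial_present > 0")
  if (length(delays) < 1 || any(delays <= 0) || is.unsorted(delays, strictly = TRUE))
    stop_domain("`delays` must be strictly increasing and positive")
  if (trials_per_delay < 1)
    stop_domain("`trials_per_delay` must be at least 1")
  if (!all(vapply(catch_trials, inherits, logical(1), "dd_catch_spec")))
    stop_domain("`catch_trials` must be a list of catch_spec() objects")
  total <- length(delays) * trials_per_delay + length(catch_trials)
  if (length(catch_positions) != length(catch_trials))
    stop_domain("`catch_positions` must match `catch_trials` in length")
  if (anyDuplicated(catch_positions))
    stop_domain("overlapping catch_positions")
  if (length(catch_positions) &&
      (min(catch_positions) < 1 || max(catch_positions) > total))
    stop_domain("catch_positions outside 1..", total)
  structure(list(future_amount = future_amount,
                 initial_present = initial_present,
                 delays = delays,
                 trials_per_delay = trials_per_delay,
                 catch_trials = catch_trials,
                 catch_positions = as.integer(catch_positions),
                 total_trials = as.integer(total)),
            class = "dd_task_config")
}

#' @export
print.dd_task_config <- function(x, ...) {
  cat("Delay-discounting task design\n")
  cat(sprintf("  future amount : $%s (constant)\n", format(x$future_amount)))
  cat(sprintf("  present anchor: $%s\n", format(x$initial_present)))
  cat(sprintf("  delays (days) : %s\n", paste(x$delays, collapse = ", ")))
  cat(sprintf("  %d titration trials per delay + %d catch trials = %d total\n",
              x$trials_per_delay, length(x$catch_trials), x$total_trials))
  invisible(x)
}

#' Build the deterministic trial schedule
#'
#' Lays out the global trial order: delay series run contiguously in
#' increasing-delay order, with catch trials inserted at the configured
#' global positions. Titration offers other than the anchor are
#' resolved at run time by [run_session()], so `present_offer` is `NA`
#' except on the first trial of each series.
#'
#' @param config A [task_config()].
#' @return A data frame with one row per trial: `global_index`,
#'   `is_catch`, `delay_days`, `within_delay_index`, `present_offer`,
#'   `future_offer`, and for catch trials the two options and the
#'   correct token.
#' @export
#' @examples
#' nrow(build_schedule(task_config()))  # 46
build_schedule <- function(config) {
  stopifnot(inherits(config, "dd_task_config"))
  total <- config$total_trials
  is_catch <- logical(total)
  is_catch[config$catch_positions] <- TRUE

  sched <- data.frame(global_index = seq_len(total),
                      is_catch = is_catch,
                      delay_days = NA_real_,
                      within_delay_index = NA_integer_,
                      present_offer = NA_real_,
                      future_offer = NA_real_,
                      option_a_amount = NA_real_, option_a_delay = NA_real_,
                      option_b_amount = NA_real_, option_b_delay = NA_real_,
                      correct_option = NA_character_)

  tit_rows <- which(!is_catch)
  sched$delay_days[tit_rows] <- rep(config$delays, each = config$trials_per_delay)
  sched$within_delay_index[tit_rows] <- rep(seq_len(config$trials_per_delay),
                                            times = length(config$delays))
  sched$future_offer[tit_rows] <- config$future_amount
  sched$present_offer[tit_rows[sched$within_delay_index[tit_rows] == 1]] <-
    config$initial_present

  for (i in seq_along(config$catch_trials)) {
    row <- config$catch_positions[i]
    ct <- config$catch_trials[[i]]
    sched$option_a_amount[row] <- ct$a_amount
    sched$option_a_delay[row]  <- ct$a_delay
    sched$option_b_amount[row] <- ct$b_amount
    sched$option_b_delay[row]  <- ct$b_delay
    sched$correct_option[row]  <- ct$correct
  }
  sched
}

#' Titrate the present offer after a choice
#'
#' Implements the halving rule of the staircase: ahead of titration
#' trial `next_within_delay_index` (counted within its delay series),
#' the change amount is `initial_present / 2^(count - 1)` with `count`
#' the index of that upcoming trial. Choosing the present option lowers
#' the next present offer by the change amount; choosing the future
#' option raises it.
#'
#' @param current_offer Present offer shown on the just-completed trial.
#' @param choice `"present"` or `"future"`.
#' @param next_within_delay_index Index (2-based) of the upcoming trial
#'   within its delay series; `trials_per_delay + 1` is allowed and
#'   yields the hypothetical next offer used as the indifference point.
#' @param config A [task_config()].
#' @return The next present offer, strictly inside
#'   `(0, future_amount)`.
#' @export
#' @examples
#' update_present_offer(500, "present", 2, task_config())  # 250
#' update_present_offer(500, "future", 2, task_config())   # 750
update_present_offer <- function(current_offer, choice,
                                 next_within_delay_index, config) {
  stopifnot(inherits(config, "dd_task_config"))
  if (!choice %in% c("present", "future"))
    stop_domain("invalid choice token: ", choice)
  idx <- next_within_delay_index
  if (idx < 2 || idx > config$trials_per_delay + 1)
    stop_domain("invalid titration step: next_within_delay_index = ", idx)
  if (!(current_offer > 0 && current_offer < config$future_amount))
    stop_domain("corrupted session: present offer ", current_offer,
                " outside (0, ", config$future_amount, ")")
  change <- config$initial_present / 2^(idx - 1)
  new <- if (choice == "present") current_offer - change else current_offer + change
  if (!(new > 0 && new < config$future_amount))
    stop_domain("corrupted session: updated offer ", new,
                " outside (0, ", config$future_amount, ")")
  new
}

#' Run one simulated session of the task
#'
#' Walks the trial schedule in order, querying the agent for a choice
#' on every trial and titrating the present offer independently within
#' each delay series. All randomness (logistic choice noise, catch
#' errors, inattentive responding) is drawn from one seeded stream in
#' trial order, so identical `(agent, config, seed)` triples reproduce
#' the session exactly.
#'
#' @param agent A [dd_agent()].
#' @param config A [task_config()].
#' @param seed Integer seed for the session's private RNG stream.
#' @param participant_id Identifier stored in the record.
#' @return An object of class `dd_session`: the resolved trial table
#'   (with the recorded `choice` and, for catch trials, `correct`),
#'   the seed, and the configuration fingerprint.
#' @export
#' @examples
#' patient <- dd_agent("deterministic_hyperbolic", k_true = 0.01)
#' session <- run_session(patient, task_config(), seed = 1)
#' head(session$trials)
run_session <- function(agent, config, seed, participant_id = "P001") {
  stopifnot(inherits(agent, "dd_agent"), inherits(config, "dd_task_config"))
  sched <- build_schedule(config)
  sched$choice <- NA_character_
  sched$correct <- NA
  offers <- setNames(rep(config$initial_present, length(config$delays)),
                     as.character(config$delays))
  with_seed(seed, {
    for (row in seq_len(nrow(sched))) {
      tr <- sched[row, ]
      if (tr$is_catch) {
        choice <- agent_choice(agent, as.list(tr))
        if (!choice %in% c("a", "b"))
          stop_domain("protocol error: agent returned '", choice,
                      "' on a catch trial")
        sched$choice[row] <- choice
        sched$correct[row] <- choice == tr$correct_option
      } else {
        offer <- offers[[as.character(tr$delay_days)]]
        sched$present_offer[row] <- offer
        tr$present_offer <- offer
        choice <- agent_choice(agent, as.list(tr))
        if (!choice %in% c("present", "future"))
          stop_domain("protocol error: agent returned '", choice,
                      "' on a titration trial")
        sched$choice[row] <- choice
        if (tr$within_delay_index < config$trials_per_delay) {
          offers[[as.character(tr$delay_days)]] <-
            update_present_offer(offer, choice, tr$within_delay_index + 1L,
                                 config)
        }
      }
    }
  })
  structure(list(participant_id = participant_id,
                 trials = sched,
                 seed = as.integer(seed),
                 config_fingerprint = config_fingerprint(config)),
            class = "dd_session")
}

#' @export
print.dd_session <- function(x, ...) {
  cat(sprintf("Delay-discounting session for %s (seed %d): %d trials, %d catch\n",
              x$participant_id, x$seed, nrow(x$trials), sum(x$trials$is_catch)))
  invisible(x)
}
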